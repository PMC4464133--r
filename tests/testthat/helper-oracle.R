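# Independent brute-force oracle for Nei-Gojobori site and difference
# counting, written directly from the definition with plain string loops.
# It shares nothing with the package implementation except the genetic code
# table itself.

.oracle_code <- Biostrings::getGeneticCode("11")

oracle_translate <- function(codon) unname(.oracle_code[[codon]])

oracle_sense_codons <- function() {
  names(.oracle_code)[.oracle_code != "*"]
}

oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  S <- 0
  for (p in 1:3) {
    syn <- 0
    nonstop <- 0
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      if (oracle_translate(mut) == "*") next
      nonstop <- nonstop + 1
      if (oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
    }
    if (nonstop > 0) S <- S + syn / nonstop
  }
  c(S = S, N = 3 - S)
}

oracle_diffs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  k <- length(pos)
  if (k == 0) {
    return(c(Sd = 0, Nd = 0))
  }
  perms <- switch(k,
    list(1),
    list(1:2, 2:1),
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  )
  sds <- numeric(0)
  nds <- numeric(0)
  for (pm in perms) {
    cur <- a
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (i in pm) {
      nxt <- cur
      substr(nxt, pos[i], pos[i]) <- substr(b, pos[i], pos[i])
      if (oracle_translate(nxt) == "*") {
        ok <- FALSE
        break
      }
      if (oracle_translate(cur) == oracle_translate(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      sds <- c(sds, sd)
      nds <- c(nds, nd)
    }
  }
  if (length(sds)) c(Sd = mean(sds), Nd = mean(nds)) else c(Sd = NA_real_, Nd = NA_real_)
}
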