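# ggplot2 views of the main result types.

#' Box-style plot of per-group dN/dS percentile summaries
#'
#' One crossbar per group showing median and quartiles, with whiskers to the
#' group minimum and maximum and a dashed line at dN/dS = 1 (the
#' purifying/neutral boundary).
#'
#' @param object A `remp_group_summary` from [group_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.remp_group_summary <- function(object, ...) {
  object <- as_tibble(object)
  object$group <- if (all(c("family", "phylum") %in% names(object))) {
    paste(object$family, object$phylum, sep = " / ")
  } else {
    do.call(paste, object[intersect(c("family", "phylum", "group"), names(object))])
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$min, ymax = .data$max),
      width = 0.25, linewidth = 0.3
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$p25, ymax = .data$p75),
      fill = "grey85", width = 0.6, linewidth = 0.3
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = "dN/dS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-codon synonymous-substitution profile plot
#'
#' @param object A `remp_sd_profile` from [sd_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.remp_sd_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$column, .data$sd)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "aligned codon position", y = "mean Sd per pair") +
    ggplot2::theme_minimal()
}

#' Column identity profile plot with motif tier thresholds
#'
#' @param object A `remp_identity_profile` from [identity_profile()].
#' @param t1,t2 Tier thresholds drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.remp_identity_profile <- function(object, t1 = 0.60, t2 = 0.75, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$column, .data$identity)) +
    ggplot2::geom_col(width = 1, fill = "grey60") +
    ggplot2::geom_hline(yintercept = c(t1, t2), linetype = c("dotted", "dashed")) +
    ggplot2::labs(x = "alignment column", y = "identity") +
    ggplot2::theme_minimal()
}
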