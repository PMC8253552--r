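#' @export
print.rots_fit <- function(x, ...) {
  cat("Reproducibility-optimized differential test\n")
  cat(sprintf("  features: %d   samples: %d (%s) vs %d (%s)\n",
              nrow(x$table), x$n_samples[1], x$conditions[1],
              x$n_samples[2], x$conditions[2]))
  cat(sprintf("  optimum: alpha = (%g, %g), k = %d, Z = %.2f, R = %.3f\n",
              x$alpha[1], x$alpha[2], x$k, x$Z, x$R))
  if ("FDR" %in% names(x$table)) {
    cat(sprintf("  features with FDR < 0.05: %d\n", sum(x$table$FDR < 0.05)))
  }
  invisible(x)
}

#' Tidy the per-feature results of a fitted test
#'
#' @param x A `rots_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per feature, ordered by rank: `feature_id`,
#'   `d`, `rank`, `mean_diff`, `log2FC`, and (when the FDR stage was run)
#'   `pvalue` and `FDR`.
#' @export
tidy.rots_fit <- function(x, ...) {
  arrange(x$table, .data$rank)
}

#' One-row summary of the optimization
#'
#' @param x A `rots_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: optimized `alpha1`, `alpha2`, `k`, the
#'   reproducibility z-score `Z`, bootstrap reproducibility `R`, resampling
#'   depth `B`, permutation count `n_perm`, and the number of features with
#'   FDR below 0.05 (`n_significant`, NA when FDR was skipped).
#' @export
glance.rots_fit <- function(x, ...) {
  tibble(
    alpha1 = x$alpha[1], alpha2 = x$alpha[2], k = x$k,
    Z = x$Z, R = x$R, B = x$B, n_perm = x$n_perm,
    n_features = nrow(x$table),
    n_significant = if ("FDR" %in% names(x$table))
      sum(x$table$FDR < 0.05) else NA_integer_
  )
}

#' Volcano-style overview of a fitted test
#'
#' @param object A `rots_fit` object.
#' @param fdr_threshold Features below this FDR are highlighted.
#' @param ... Unused.
#' @return A ggplot: log2 fold-change against the test statistic, colored by
#'   significance.
#' @export
autoplot.rots_fit <- function(object, fdr_threshold = 0.05, ...) {
  tab <- object$table
  if (!"FDR" %in% names(tab)) tab$FDR <- NA_real_
  tab$significant <- !is.na(tab$FDR) & tab$FDR < fdr_threshold
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2FC, y = .data$d,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = paste0("FDR < ", fdr_threshold)) +
    ggplot2::labs(x = "log2 fold-change", y = expression(d[alpha])) +
    ggplot2::theme_minimal()
}
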