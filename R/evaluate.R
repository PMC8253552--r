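# Evaluation against synthetic truth and against matched expression data.

#' Score detected peaks against synthetic truth
#'
#' Overlaps the significant detected peaks (FDR below the threshold) with
#' the labeled truth peaks. A true differential peak counts as detected if
#' any significant peak overlaps it by at least 1 bp (`criterion = "1bp"`)
#' or by at least 25% of the true peak's length (`criterion = "frac25"`);
#' each true peak is counted at most once. False positives are significant
#' peaks overlapping no true differential peak under the same criterion.
#'
#' @param detected Tibble with `chrom`, `start`, `end` and `FDR` (e.g. from
#'   [differential_peaks()]).
#' @param truth Truth tibble from [simulate_benchmark()] (with coordinates,
#'   `label`, `category`).
#' @param fdr_threshold Significance cut-off (default 0.05).
#' @param criterion `"1bp"` or `"frac25"`.
#' @return A list of class `detection_report`: `by_category` (tibble of
#'   per-category true-positive counts and category sizes), `n_true_positive`,
#'   `n_false_positive`, `n_significant`, `fdr_threshold`, `criterion`.
#' @export
evaluate_detection <- function(detected, truth, fdr_threshold = 0.05,
                               criterion = c("1bp", "frac25")) {
  criterion <- match.arg(criterion)
  if (!"FDR" %in% names(detected)) abort("`detected` needs an FDR column.")
  check_peaks(truth)
  sig <- filter(detected, .data$FDR < fdr_threshold)
  if (length(intersect(unique(truth$chrom), unique(detected$chrom))) == 0 &&
      nrow(detected) > 0) {
    abort("Detected peaks and truth share no chromosome names.")
  }
  truth_gr <- peaks_to_granges(truth, keep_mcols = FALSE)
  sig_gr <- if (nrow(sig) > 0) peaks_to_granges(sig, keep_mcols = FALSE) else
    GenomicRanges::GRanges()

  hits <- GenomicRanges::findOverlaps(truth_gr, sig_gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (criterion == "frac25") {
    ov <- GenomicRanges::pintersect(truth_gr[S4Vectors::queryHits(hits)],
                                    sig_gr[S4Vectors::subjectHits(hits)])
    frac <- GenomicRanges::width(ov) /
      GenomicRanges::width(truth_gr[S4Vectors::queryHits(hits)])
    hits <- hits[frac >= 0.25]
  }
  truth_hit <- rep(FALSE, nrow(truth))
  truth_hit[unique(S4Vectors::queryHits(hits))] <- TRUE

  is_diff <- truth$label == "differential"
  # significant peaks overlapping no true differential peak
  sig_hit_diff <- rep(FALSE, nrow(sig))
  diff_hits <- hits[is_diff[S4Vectors::queryHits(hits)]]
  sig_hit_diff[unique(S4Vectors::subjectHits(diff_hits))] <- TRUE

  by_category <- truth |>
    filter(.data$label == "differential") |>
    mutate(detected = truth_hit[is_diff]) |>
    group_by(category = .data$category) |>
    summarise(n_true = n(), n_detected = sum(.data$detected),
              .groups = "drop") |>
    arrange(.data$category)

  structure(list(
    by_category = by_category,
    n_true_positive = sum(truth_hit & is_diff),
    n_false_positive = sum(!sig_hit_diff),
    n_significant = nrow(sig),
    fdr_threshold = fdr_threshold,
    criterion = criterion
  ), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("Detection report (overlap: %s, FDR < %g)\n",
              x$criterion, x$fdr_threshold))
  cat(sprintf("  significant peaks: %d  true positives: %d  false positives: %d\n",
              x$n_significant, x$n_true_positive, x$n_false_positive))
  print(x$by_category)
  invisible(x)
}

#' @export
tidy.detection_report <- function(x, ...) x$by_category

#' Per-category detection bar chart
#'
#' @param object A `detection_report`.
#' @param ... Unused.
#' @return A ggplot of detected differential peaks per intensity category,
#'   with the category size as the ideal reference line.
#' @export
autoplot.detection_report <- function(object, ...) {
  ggplot2::ggplot(object$by_category,
                  ggplot2::aes(x = factor(.data$category), y = .data$n_detected)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$n_true),
                        data = object$by_category[1, ], linetype = 2) +
    ggplot2::labs(x = "intensity category (% difference)",
                  y = "detected differential peaks") +
    ggplot2::theme_minimal()
}

#' ROC curve over the truth labels
#'
#' Sweeps a score threshold over the binary label differential versus
#' non-differential and computes the receiver operating characteristic with
#' trapezoidal AUC (delegated to pROC). Peaks missing from `scores` are
#' imputed with the minimum score.
#'
#' @param scores Tibble with `peak_id` and a `score` column (larger = more
#'   differential; use the test statistic or `1 - FDR`).
#' @param truth Truth tibble (`peak_id`, `label`).
#' @return A list of class `roc_report`: `points` (tibble `fpr`, `tpr`,
#'   monotone in both axes) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  lab <- truth$label == "differential"
  if (length(unique(lab)) < 2) {
    abort("Truth contains a single class; ROC undefined.")
  }
  sc <- scores$score[match(truth$peak_id, scores$peak_id)]
  sc[is.na(sc)] <- min(sc, na.rm = TRUE)
  r <- pROC::roc(response = lab, predictor = sc, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  points <- tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  structure(list(points = points, auc = as.numeric(pROC::auc(r))),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
tidy.roc_report <- function(x, ...) x$points

#' @export
autoplot.roc_report <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Annotate peaks to their nearest gene
#'
#' Assigns each peak the gene minimizing the distance from the peak midpoint
#' to the gene's transcription start site on the same chromosome; a TSS
#' lying inside the peak gives distance 0. Exact distance ties resolve to
#' the lexicographically smallest `gene_id`. Peaks on chromosomes without
#' genes get `NA`.
#'
#' @param peaks Peak tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Tibble with `gene_id`, `chrom`, `tss` (and optionally
#'   `strand`).
#' @return The peak tibble with `gene_id` and `distance` columns appended.
#' @export
annotate_nearest_gene <- function(peaks, genes) {
  if (nrow(genes) == 0) abort("Gene table is empty.")
  if (anyDuplicated(genes$gene_id)) abort("gene_id must be unique.")
  if (any(genes$tss < 0)) abort("TSS positions must be >= 0.")
  out <- peaks
  out$gene_id <- NA_character_
  out$distance <- NA_real_
  for (chr in unique(peaks$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    pi <- which(peaks$chrom == chr)
    if (nrow(g) == 0 || length(pi) == 0) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    for (i in pi) {
      s <- peaks$start[i]; e <- peaks$end[i]
      mid <- floor((s + e) / 2)
      inside <- g$tss >= s & g$tss < e
      if (any(inside)) {
        out$gene_id[i] <- min(g$gene_id[inside])
        out$distance[i] <- 0
      } else {
        dist <- abs(mid - g$tss)
        dmin <- min(dist)
        out$gene_id[i] <- min(g$gene_id[dist == dmin])
        out$distance[i] <- dmin
      }
    }
  }
  out
}

#' Correlation of peak and expression fold-changes over top-N cut-offs
#'
#' Ranks the differential peaks by FDR, and for each top-N cut-off (N = 100,
#' 200, ... by default) computes the Pearson correlation between the log10
#' fold-change of differential binding and the log10 fold-change of the
#' expression of the nearest gene. When several top peaks annotate to one
#' gene, the gene contributes the average of their log10 fold-changes.
#'
#' @param ranked_peaks Differential table with `peak_id`, `FDR`, and
#'   `log2FC` (or `log10_fc`); typically [differential_peaks()] output
#'   passed through [annotate_nearest_gene()] (needs `gene_id`).
#' @param expression_fc Tibble with `gene_id` and `log10_fc` (or `fc`, which
#'   is log10-transformed).
#' @param grid_step,max_n Cut-off grid: `grid_step`, `2*grid_step`, ... up
#'   to `max_n` (defaults 100 and 2000).
#' @return A list of class `correlation_curve`: tibble `curve` with columns
#'   `top_n`, `r` (NA when fewer than 3 genes contribute) and `n_genes`.
#' @export
fc_correlation <- function(ranked_peaks, expression_fc, grid_step = 100,
                           max_n = 2000) {
  if (!"gene_id" %in% names(ranked_peaks)) {
    abort("`ranked_peaks` needs a gene_id column; run annotate_nearest_gene() first.")
  }
  if (!"FDR" %in% names(ranked_peaks)) abort("`ranked_peaks` needs an FDR column.")
  pk <- ranked_peaks
  if (!"log10_fc" %in% names(pk)) {
    if (!"log2FC" %in% names(pk)) abort("Need a log2FC or log10_fc column.")
    pk$log10_fc <- pk$log2FC * log10(2)
  }
  ex <- expression_fc
  if (!"log10_fc" %in% names(ex)) {
    if (!"fc" %in% names(ex)) abort("Expression table needs log10_fc or fc.")
    ex$log10_fc <- log10(ex$fc)
  }
  pk <- arrange(pk, .data$FDR, dplyr::desc(abs(.data$log10_fc)), .data$peak_id)
  pk <- filter(pk, !is.na(.data$gene_id))
  grid <- seq(grid_step, max_n, by = grid_step)
  rows <- purrr::map(grid, function(N) {
    top <- slice_head(pk, n = min(N, nrow(pk)))
    per_gene <- top |>
      group_by(.data$gene_id) |>
      summarise(peak_fc = mean(.data$log10_fc), .groups = "drop") |>
      inner_join(select(ex, "gene_id", expr_fc = "log10_fc"), by = "gene_id")
    r <- if (nrow(per_gene) >= 3 &&
             sd(per_gene$peak_fc) > 0 && sd(per_gene$expr_fc) > 0) {
      cor(per_gene$peak_fc, per_gene$expr_fc)
    } else NA_real_
    tibble(top_n = N, r = r, n_genes = nrow(per_gene))
  })
  structure(list(curve = bind_rows(rows)), class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("Peak-to-expression fold-change correlation\n")
  print(x$curve)
  invisible(x)
}

#' @export
tidy.correlation_curve <- function(x, ...) x$curve

#' @export
autoplot.correlation_curve <- function(object, ...) {
  ggplot2::ggplot(filter(object$curve, !is.na(.data$r)),
                  ggplot2::aes(x = .data$top_n, y = .data$r)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "top N differential peaks", y = "Pearson r") +
    ggplot2::theme_minimal()
}
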