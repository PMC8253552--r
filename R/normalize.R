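#' Median-of-ratios count normalization
#'
#' Per-sample size factors by the median-of-ratios method: for each feature
#' the geometric mean across samples is computed; a sample's size factor is
#' the median, over features with a positive geometric mean, of that
#' sample's count divided by the geometric mean; normalized counts are the
#' raw counts divided by the size factor. The computation is delegated to
#' `DESeq2::estimateSizeFactorsForMatrix()`, the reference implementation of
#' this estimator, which is robust to outliers and to imbalance in the
#' number of enriched regions between conditions.
#'
#' @param counts Count tibble (feature id column + numeric sample columns)
#'   or matrix.
#' @return A list with `size_factors` (tibble: `sample_id`, `size_factor`)
#'   and `normalized` (tibble in the input layout, counts divided by size
#'   factors). Non-sample columns of the input (coordinates, ids) are
#'   carried through unchanged.
#' @export
median_of_ratios <- function(counts) {
  m <- as_count_matrix(counts)
  gm_pos <- rowSums(m == 0) == 0   # log geometric mean finite iff no zeros
  if (!any(gm_pos)) {
    abort("No feature has positive counts in every sample; size factors undefined.")
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(m)
  norm <- sweep(m, 2, sf, "/")
  normalized <- if (is.data.frame(counts)) {
    out <- as_tibble(counts)
    for (s in colnames(m)) out[[s]] <- norm[, s]
    out
  } else {
    as_tibble(norm, rownames = "feature_id")
  }
  list(
    size_factors = tibble(sample_id = colnames(m), size_factor = unname(sf)),
    normalized = normalized
  )
}
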