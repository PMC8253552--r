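#' Differential peak calling from a count matrix
#'
#' The downstream half of the differential peak calling workflow: optional
#' median-of-ratios normalization, reproducibility-optimized test fit, and a
#' ranked differential peak table. Upstream, candidate peaks are built with
#' [merge_peaks()] and counted with [count_reads()]; synthetic benchmarks
#' produced by [simulate_benchmark()] plug in directly. Normalization can be
#' switched off when the samples are already on a common scale (as in the
#' synthetic benchmark, where every replicate derives from the same read
#' pool).
#'
#' @inheritParams rots
#' @param normalize Apply [median_of_ratios()] before testing (default TRUE).
#' @param fdr_threshold Threshold used for the `significant` column
#'   (default 0.05).
#' @return A tibble ordered by rank with peak coordinates (when available),
#'   `d`, `mean_diff`, `log2FC`, `pvalue`, `FDR` and `significant`. The
#'   fitted `rots_fit` is attached as attribute `"fit"` and the size factors
#'   (when normalizing) as `"size_factors"`.
#' @export
differential_peaks <- function(counts, design, config = rots_config(),
                               normalize = TRUE, fdr_threshold = 0.05,
                               seed = NULL) {
  coords <- extract_coords(counts)
  if (normalize) {
    nm <- median_of_ratios(counts)
    mat_in <- nm$normalized
    sf <- nm$size_factors
  } else {
    mat_in <- counts
    sf <- NULL
  }
  fit <- rots(mat_in, design, config = config, seed = seed)
  tab <- tidy(fit)
  if (!is.null(coords)) {
    tab <- left_join(coords, tab, by = c(peak_id = "feature_id"))
    tab <- arrange(tab, .data$rank)
  } else {
    tab <- rename(tab, peak_id = "feature_id")
  }
  tab <- mutate(tab, significant = .data$FDR < fdr_threshold)
  attr(tab, "fit") <- fit
  attr(tab, "size_factors") <- sf
  tab
}

# Pull peak_id + coordinates out of a counts table; parses "chrom:start-end"
# ids when explicit coordinate columns are absent. NULL when unavailable.
extract_coords <- function(counts) {
  if (!is.data.frame(counts)) return(NULL)
  id_col <- intersect(c("peak_id", "feature_id"), names(counts))[1]
  if (all(c("chrom", "start", "end") %in% names(counts)) && !is.na(id_col)) {
    out <- as_tibble(counts[, c(id_col, "chrom", "start", "end")])
    names(out)[1] <- "peak_id"
    return(out)
  }
  if (is.na(id_col)) return(NULL)
  ids <- as.character(counts[[id_col]])
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  if (any(vapply(m, length, integer(1)) != 4)) return(NULL)
  tibble(
    peak_id = ids,
    chrom = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4))
  )
}

#' Write a differential peak table to disk
#'
#' Writes the full table as TSV and the significant peaks as a BED file
#' whose score column is \eqn{-10 \log_{10} \mathrm{FDR}} capped at 1000;
#' both outputs are coordinate-sorted and written atomically.
#'
#' @param tab Result of [differential_peaks()].
#' @param tsv,bed Output paths (`NULL` skips the file).
#' @param fdr_threshold FDR cut-off defining the BED's significant set.
#' @return Invisibly, the input table.
#' @export
write_differential <- function(tab, tsv = NULL, bed = NULL,
                               fdr_threshold = 0.05) {
  has_coords <- all(c("chrom", "start", "end") %in% names(tab))
  if (!is.null(tsv)) {
    out <- if (has_coords) arrange(tab, .data$chrom, .data$start, .data$end) else tab
    write_tsv_atomic(out, tsv)
  }
  if (!is.null(bed)) {
    if (!has_coords) abort("BED output needs chrom/start/end columns.")
    sig <- filter(tab, .data$FDR < fdr_threshold)
    sig <- arrange(sig, .data$chrom, .data$start, .data$end)
    bed_tab <- tibble(
      chrom = sig$chrom, start = sig$start, end = sig$end,
      name = sig$peak_id,
      score = round(pmin(1000, -10 * log10(pmax(sig$FDR, 1e-100)))),
      strand = "."
    )
    write_atomic(function(tmp) {
      readr::write_tsv(bed_tab, tmp, col_names = FALSE, progress = FALSE)
    }, bed)
  }
  invisible(tab)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("Count file not found: ", path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tb) < 3) abort("Count matrix needs an id column and at least two samples.")
  tb
}

#' Read a sample-to-condition design table
#'
#' Expects TSV with two columns, `sample_id` and `condition` (header
#' optional).
#'
#' @param path TSV path.
#' @return Tibble with `sample_id` and `condition`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(paste0("Design file not found: ", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  tb <- if (has_header) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                    progress = FALSE)
  }
  if (ncol(tb) != 2) {
    abort(paste0("Design file ", path, " must have exactly 2 columns ",
                 "(sample_id, condition), found ", ncol(tb), "."))
  }
  names(tb) <- c("sample_id", "condition")
  mutate(tb, sample_id = as.character(.data$sample_id),
         condition = as.character(.data$condition))
}
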