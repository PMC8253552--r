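# Peak input and candidate-peak construction.
#
# Peaks travel through the package as tibbles with 0-based half-open
# coordinates (`chrom`, `start`, `end`, plus any extra columns); conversion
# to/from GRanges (1-based closed) happens at the boundary of every
# interval operation.

#' Convert a peak tibble to GRanges
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param keep_mcols Carry non-coordinate columns across as metadata columns.
#' @return A `GRanges` (1-based closed coordinates).
#' @export
peaks_to_granges <- function(peaks, keep_mcols = TRUE) {
  check_peaks(peaks)
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  if (keep_mcols) {
    extra <- setdiff(names(peaks), c("chrom", "start", "end"))
    if (length(extra) > 0) {
      S4Vectors::mcols(gr) <- as.data.frame(peaks[extra])
    }
  }
  gr
}

#' Convert a GRanges to a peak tibble
#'
#' @param gr A `GRanges`.
#' @return Tibble with 0-based half-open `chrom`, `start`, `end` plus any
#'   metadata columns.
#' @export
granges_to_peaks <- function(gr) {
  tb <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc) > 0) tb <- bind_cols(tb, as_tibble(as.data.frame(mc)))
  tb
}

check_peaks <- function(peaks) {
  if (!is.data.frame(peaks) || !all(c("chrom", "start", "end") %in% names(peaks))) {
    abort("Peaks must be a data frame with columns `chrom`, `start`, `end`.")
  }
  if (any(peaks$start < 0)) abort("Peak starts must be >= 0.")
  bad <- which(peaks$end <= peaks$start)
  if (length(bad) > 0) {
    abort(paste0("Peak end must exceed start (row ", bad[1], ")."))
  }
  invisible(peaks)
}

#' Read peak calls from BED or narrowPeak files
#'
#' @param path Path to a BED3+ or narrowPeak (BED6+4) file.
#' @param format `"auto"` (by file extension), `"bed"` or `"narrowPeak"`.
#' @return A peak tibble (`chrom`, `start`, `end`, 0-based half-open),
#'   sorted by position; narrowPeak columns (`name`, `score`, `strand`,
#'   `signalValue`, `pValue`, `qValue`, `peak`) are preserved when present.
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Peak file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  }
  gr <- tryCatch(
    {
      if (format == "narrowPeak") {
        rtracklayer::import(path, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric",
                                          peak = "integer"))
      } else {
        rtracklayer::import(path, format = "BED")
      }
    },
    error = function(e) {
      abort(paste0("Failed to parse ", path, ": ", conditionMessage(e)))
    }
  )
  tb <- granges_to_peaks(gr)
  bad <- which(tb$end <= tb$start)
  if (length(bad) > 0) {
    abort(paste0("Invalid interval (end <= start) at data line ", bad[1],
                 " of ", path))
  }
  arrange(tb, .data$chrom, .data$start, .data$end)
}

#' Merge per-sample peak calls into candidate peaks
#'
#' Takes the union of the intervals across all inputs and merges overlapping
#' or book-ended intervals on the same chromosome into single candidate
#' peaks, the way a candidate peak list is compiled from sample-level peak
#' calls before differential testing.
#'
#' @param peaks A peak tibble, or a list of peak tibbles; additional peak
#'   tibbles may be passed via `...`.
#' @param ... Further peak tibbles.
#' @return A sorted, non-overlapping peak tibble with a `peak_id` column
#'   (`chrom:start-end`).
#' @export
merge_peaks <- function(peaks, ...) {
  sets <- if (is.data.frame(peaks)) list(peaks) else peaks
  sets <- c(sets, list(...))
  if (length(sets) == 0) abort("No peak sets supplied.")
  grl <- lapply(sets, peaks_to_granges, keep_mcols = FALSE)
  all_gr <- do.call(c, grl)
  if (length(all_gr) == 0) abort("Union of peak sets is empty.")
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr))
  tb <- granges_to_peaks(merged)
  tb <- arrange(tb, .data$chrom, .data$start, .data$end)
  mutate(tb, peak_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
         .before = 1)
}
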