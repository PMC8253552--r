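#' Count reads or fragments over candidate peaks
#'
#' Builds a peak-by-sample count matrix from coordinate-sorted, indexed BAM
#' files. In `fragment` mode (paired-end ATAC-seq), each properly paired
#' template — the interval from the leftmost mate start to the rightmost
#' mate end — is counted once for every peak it overlaps by at least 1 bp.
#' In `read` mode every passing read is counted once per overlapping peak.
#' Reads below the mapping-quality threshold, duplicates, and secondary or
#' supplementary alignments are excluded (configurable).
#'
#' @param peaks Peak tibble (e.g. from [merge_peaks()]); a `peak_id` column
#'   is added when absent.
#' @param bams Character vector of BAM paths; names become sample ids
#'   (basenames without extension otherwise).
#' @param mode `"fragment"` (paired-end templates) or `"read"`.
#' @param mapq Minimum mapping quality (default 15).
#' @param exclude_duplicates,exclude_secondary Filtering toggles, both on by
#'   default.
#' @return Tibble with `peak_id`, `chrom`, `start`, `end`, then one integer
#'   column per sample.
#' @export
count_reads <- function(peaks, bams, mode = c("fragment", "read"), mapq = 15,
                        exclude_duplicates = TRUE, exclude_secondary = TRUE) {
  mode <- match.arg(mode)
  check_peaks(peaks)
  if (!"peak_id" %in% names(peaks)) {
    peaks <- mutate(peaks,
      peak_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
      .before = 1)
  }
  ids <- names(bams) %||% sub("\\.bam$", "", basename(bams), ignore.case = TRUE)
  for (bam in bams) {
    if (!file.exists(bam)) abort(paste0("BAM not found: ", bam))
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      abort(paste0("BAM index (.bai) missing for ", bam))
    }
  }
  gr <- peaks_to_granges(peaks, keep_mcols = FALSE)
  counts <- matrix(0L, nrow = length(gr), ncol = length(bams))
  colnames(counts) <- ids
  for (i in seq_along(bams)) {
    counts[, i] <- count_one_bam(gr, bams[i], mode, mapq,
                                 exclude_duplicates, exclude_secondary)
  }
  bind_cols(select(peaks, "peak_id", "chrom", "start", "end"),
            as_tibble(counts))
}

count_one_bam <- function(gr, bam, mode, mapq, exclude_duplicates,
                          exclude_secondary) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isProperPair = if (mode == "fragment") TRUE else NA,
    isDuplicate = if (exclude_duplicates) FALSE else NA,
    isSecondaryAlignment = if (exclude_secondary) FALSE else NA,
    isSupplementaryAlignment = if (exclude_secondary) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq)
  hdr_seqs <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  missing_contigs <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                             hdr_seqs)
  if (length(missing_contigs) > 0) {
    warn(paste0("Contigs absent from ", basename(bam), " header (zero counts): ",
                paste(missing_contigs, collapse = ", ")))
  }
  if (mode == "fragment") {
    aln <- GenomicAlignments::readGAlignmentPairs(bam, param = param)
    frags <- GenomicRanges::granges(aln, on.discordant.seqnames = "drop")
  } else {
    frags <- GenomicRanges::granges(GenomicAlignments::readGAlignments(bam, param = param))
  }
  GenomicRanges::countOverlaps(gr, frags, minoverlap = 1L, ignore.strand = TRUE)
}
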