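# Shared fixture builders and independent oracles.

# Two-group count matrix with optional spiked features in the second group.
make_counts <- function(n_features = 100, n1 = 5, n2 = 5, mu = 100, size = 3,
                        spike_idx = integer(), spike_shift = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnbinom(n_features * (n1 + n2), mu = mu, size = size),
              nrow = n_features)
  if (length(spike_idx) > 0) {
    m[spike_idx, (n1 + 1):(n1 + n2)] <- m[spike_idx, (n1 + 1):(n1 + n2)] +
      spike_shift
  }
  rownames(m) <- sprintf("f%04d", seq_len(n_features))
  colnames(m) <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  m
}

make_design <- function(n1 = 5, n2 = 5) {
  data.frame(
    sample_id = c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2))),
    condition = rep(c("grpA", "grpB"), c(n1, n2))
  )
}

# Textbook pooled-variance two-sample t statistic, computed feature-wise
# with base-R loops — independent of the package's vectorized engine.
oracle_t <- function(m, n1) {
  apply(m, 1, function(x) {
    x1 <- x[1:n1]
    x2 <- x[(n1 + 1):length(x)]
    sp2 <- ((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
      (length(x1) + length(x2) - 2)
    (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / length(x1) + 1 / length(x2)))
  })
}

# Write a tiny BED file and return its path.
write_bed <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), character(1)),
             path)
  path
}

peak_tbl <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = start, end = end, ...)
}

# Build an indexed BAM from alignment records. Each record is a list with
# qname, chrom, pos (1-based leftmost), cigar, and for paired records mpos
# and tlen. Returns the BAM path.
make_bam <- function(records, contigs = c(chr1 = 10000L),
                     paired = TRUE, mapq = 60) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- vapply(records, function(r) {
    if (paired) {
      flag1 <- 99L   # paired, proper, mate reverse, first
      flag2 <- 147L  # paired, proper, reverse, second
      len <- r$mate_pos + r$read_len - r$pos
      paste(
        paste(r$qname, flag1, r$chrom, r$pos, mapq,
              paste0(r$read_len, "M"), "=", r$mate_pos, len,
              strrep("A", r$read_len), "*", sep = "\t"),
        paste(r$qname, flag2, r$chrom, r$mate_pos, mapq,
              paste0(r$read_len, "M"), "=", r$pos, -len,
              strrep("A", r$read_len), "*", sep = "\t"),
        sep = "\n")
    } else {
      paste(r$qname, 0L, r$chrom, r$pos, mapq, paste0(r$read_len, "M"),
            "*", 0, 0, strrep("A", r$read_len), "*", sep = "\t")
    }
  }, character(1))
  # records must be emitted coordinate-sorted for asBam(sort = FALSE)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam, tempfile())
  Rsamtools::indexBam(sorted)
  sorted
}

scaled_bench_cfg <- function(seed = NULL) {
  bench_config(n_peaks = 2000, n_differential = 1000, n_categories = 10,
               n_per_category = 100, seed = seed)
}
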