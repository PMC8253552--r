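#' Configuration of the synthetic differential-peak benchmark
#'
#' The benchmark emulates a downsampling-based ChIP-seq simulation: a
#' reference condition of candidate peaks with negative-binomial read
#' counts; a treatment condition in which "true differential" peaks lose a
#' category-specific fraction of their reads; five replicates per condition
#' obtained by randomly thinning 10–30% of the reads; and a multiplicative
#' log-normal biological-noise layer.
#'
#' @param n_peaks Number of candidate peaks (default 20000).
#' @param n_differential Number of true differential peaks (default 10000);
#'   must equal `n_categories * n_per_category` and not exceed `n_peaks`.
#' @param n_categories Number of intensity categories (default 10); category
#'   `c` means a `10*c`% difference in signal intensity between conditions.
#' @param n_per_category Differential peaks per category (default 1000).
#' @param n_replicates Replicates per condition (default 5).
#' @param replicate_thinning Range of the per-replicate random thinning
#'   fraction (default `c(0.10, 0.30)`).
#' @param noise_sigma Log-scale SD of the multiplicative biological-noise
#'   factor (default 0.25; 0 disables the layer).
#' @param count_mean,count_dispersion Negative-binomial mean and size of the
#'   per-peak reference read counts (defaults 500 and 2, emulating deep
#'   coverage over enriched regions with strong biological overdispersion).
#' @param width_meanlog,width_sdlog,width_min Log-normal peak-width model
#'   (defaults log(1500), 0.5, 200 bp — broad-mark-like peaks).
#' @param gap_mean Mean inter-peak gap in bp (default 2000).
#' @param genome_length Optional total length of the synthetic chromosome;
#'   an error is raised when the peaks cannot fit. `NULL` sizes the genome
#'   to the layout.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `bench_config`.
#' @export
bench_config <- function(n_peaks = 20000, n_differential = 10000,
                         n_categories = 10, n_per_category = 1000,
                         n_replicates = 5,
                         replicate_thinning = c(0.10, 0.30),
                         noise_sigma = 0.25,
                         count_mean = 500, count_dispersion = 2,
                         width_meanlog = log(1500), width_sdlog = 0.5,
                         width_min = 200, gap_mean = 2000,
                         genome_length = NULL, seed = NULL) {
  if (n_differential != n_categories * n_per_category) {
    abort("n_differential must equal n_categories * n_per_category.")
  }
  if (n_differential > n_peaks) abort("n_differential cannot exceed n_peaks.")
  if (length(replicate_thinning) != 2 ||
      any(replicate_thinning < 0 | replicate_thinning >= 1) ||
      replicate_thinning[1] > replicate_thinning[2]) {
    abort("replicate_thinning must be an increasing pair in [0, 1).")
  }
  if (noise_sigma < 0) abort("noise_sigma must be >= 0.")
  structure(as.list(environment()), class = "bench_config")
}

#' Simulate the reference condition of the benchmark
#'
#' Lays out non-overlapping peaks on a synthetic chromosome (`chrS`) with
#' log-normal widths and exponential gaps and draws a negative-binomial
#' read count per peak.
#'
#' @param cfg A [bench_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A list with `peaks` (peak tibble with `peak_id`) and `counts`
#'   (integer vector of per-peak reference read counts).
#' @export
simulate_reference <- function(cfg, seed = cfg$seed) {
  with_seed_if(seed, {
    widths <- pmax(cfg$width_min,
                   round(rlnorm(cfg$n_peaks, cfg$width_meanlog, cfg$width_sdlog)))
    gaps <- round(rexp(cfg$n_peaks, 1 / cfg$gap_mean)) + 100
    starts <- cumsum(gaps + c(0, widths[-cfg$n_peaks]))
    ends <- starts + widths
    if (!is.null(cfg$genome_length) && ends[cfg$n_peaks] > cfg$genome_length) {
      abort(paste0("Peak layout needs ", ends[cfg$n_peaks],
                   " bp but genome_length is ", cfg$genome_length, "."))
    }
    peaks <- tibble(
      peak_id = sprintf("peak_%05d", seq_len(cfg$n_peaks)),
      chrom = "chrS", start = as.integer(starts), end = as.integer(ends)
    )
    counts <- rnbinom(cfg$n_peaks, mu = cfg$count_mean,
                      size = cfg$count_dispersion)
    list(peaks = peaks, counts = counts)
  })
}

#' Assign truth labels and intensity categories
#'
#' Uniformly partitions the peaks into `n_differential` true differential
#' peaks — split evenly across the intensity categories (10%, 20%, ...,
#' 100% difference by default) — and non-differential peaks. All
#' differential peaks lose signal in the treatment condition.
#'
#' @param peaks Peak tibble from [simulate_reference()].
#' @param cfg A [bench_config()].
#' @param seed Optional seed.
#' @return Truth tibble: `peak_id`, `label` (`"differential"` /
#'   `"non_differential"`), `category` (percent difference, `NA` for
#'   non-differential) and `direction` (`"treatment"` for differential
#'   peaks, `NA` otherwise).
#' @export
assign_truth <- function(peaks, cfg, seed = cfg$seed) {
  if (nrow(peaks) != cfg$n_peaks) {
    abort("Number of peaks does not match cfg$n_peaks.")
  }
  with_seed_if(seed, {
    diff_idx <- sample.int(cfg$n_peaks, cfg$n_differential)
    label <- rep("non_differential", cfg$n_peaks)
    label[diff_idx] <- "differential"
    category <- rep(NA_integer_, cfg$n_peaks)
    if (cfg$n_differential > 0) {
      cats <- rep(seq_len(cfg$n_categories) * (100 %/% cfg$n_categories),
                  each = cfg$n_per_category)
      category[diff_idx] <- sample(cats)
    }
    tibble(
      peak_id = peaks$peak_id,
      label = label,
      category = category,
      direction = ifelse(label == "differential", "treatment", NA_character_)
    )
  })
}

#' Downsample differential peaks to build the treatment condition
#'
#' For a differential peak in intensity category `c`, each reference read is
#' retained independently with probability `1 - c/100` (binomial thinning);
#' non-differential peaks keep their reference counts unchanged.
#'
#' @param reference_counts Integer vector of reference counts.
#' @param truth Truth tibble from [assign_truth()].
#' @param seed Optional seed.
#' @return Integer vector of treatment counts.
#' @export
downsample_treatment <- function(reference_counts, truth, seed = NULL) {
  if (length(reference_counts) != nrow(truth)) {
    abort("Counts and truth table have different lengths.")
  }
  with_seed_if(seed, {
    out <- as.integer(reference_counts)
    is_diff <- truth$label == "differential"
    if (any(is_diff)) {
      keep_p <- 1 - truth$category[is_diff] / 100
      out[is_diff] <- rbinom(sum(is_diff), reference_counts[is_diff], keep_p)
    }
    out
  })
}

#' Thin a condition into simulated biological replicates
#'
#' Each replicate draws a thinning fraction uniformly from
#' `cfg$replicate_thinning` and retains each read independently with the
#' complementary probability (binomial thinning at count level, the exact
#' distributional equivalent of subsampling reads).
#'
#' @param counts Integer vector of per-peak counts for one condition.
#' @param cfg A [bench_config()].
#' @param seed Optional seed.
#' @return Integer matrix, peaks by `cfg$n_replicates`.
#' @export
make_replicates <- function(counts, cfg, seed = NULL) {
  with_seed_if(seed, {
    out <- matrix(0L, length(counts), cfg$n_replicates)
    for (r in seq_len(cfg$n_replicates)) {
      f <- runif(1, cfg$replicate_thinning[1], cfg$replicate_thinning[2])
      out[, r] <- rbinom(length(counts), counts, 1 - f)
    }
    out
  })
}

#' Add a multiplicative biological-noise layer
#'
#' Multiplies every count by an independent log-normal factor with log-scale
#' SD `cfg$noise_sigma` and rounds to integer. `noise_sigma = 0` leaves the
#' counts untouched.
#'
#' @param counts Integer vector or matrix of counts.
#' @param cfg A [bench_config()].
#' @param seed Optional seed.
#' @return Counts with noise applied, same shape as the input.
#' @export
add_noise <- function(counts, cfg, seed = NULL) {
  if (cfg$noise_sigma == 0) return(counts)
  with_seed_if(seed, {
    fac <- rlnorm(length(counts), meanlog = 0, sdlog = cfg$noise_sigma)
    out <- round(counts * fac)
    storage.mode(out) <- "integer"
    out
  })
}

#' Generate the full synthetic differential-peak benchmark
#'
#' Runs the complete generator: reference simulation, truth assignment,
#' treatment downsampling, replicate thinning for both conditions, and the
#' biological-noise layer. All randomness flows from the single seed.
#'
#' @param cfg A [bench_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A list with `counts` (tibble: `peak_id`, coordinates, and
#'   `ref_1..ref_R`, `treat_1..treat_R` sample columns), `truth` (the truth
#'   tibble, including coordinates), `peaks` and `design` (sample-to-
#'   condition tibble).
#' @export
simulate_benchmark <- function(cfg = bench_config(), seed = cfg$seed) {
  with_seed_if(seed, {
    ref <- simulate_reference(cfg, seed = NULL)
    truth <- assign_truth(ref$peaks, cfg, seed = NULL)
    treat <- downsample_treatment(ref$counts, truth, seed = NULL)
    rep_ref <- make_replicates(ref$counts, cfg, seed = NULL)
    rep_treat <- make_replicates(treat, cfg, seed = NULL)
    rep_ref <- add_noise(rep_ref, cfg, seed = NULL)
    rep_treat <- add_noise(rep_treat, cfg, seed = NULL)
    colnames(rep_ref) <- paste0("ref_", seq_len(cfg$n_replicates))
    colnames(rep_treat) <- paste0("treat_", seq_len(cfg$n_replicates))
    counts <- bind_cols(ref$peaks, as_tibble(rep_ref), as_tibble(rep_treat))
    design <- tibble(
      sample_id = c(colnames(rep_ref), colnames(rep_treat)),
      condition = rep(c("reference", "treatment"), each = cfg$n_replicates)
    )
    list(
      counts = counts,
      truth = left_join(ref$peaks, truth, by = "peak_id"),
      peaks = ref$peaks,
      design = design
    )
  })
}

#' Write a simulated benchmark to disk
#'
#' Writes the count matrix TSV, the truth TSV, the design TSV, and a truth
#' BED (name = `peak_id|label|category`), all atomically.
#'
#' @param bench Result of [simulate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.tsv"),
    design = file.path(dir, "design.tsv"),
    truth_bed = file.path(dir, "truth.bed")
  )
  write_tsv_atomic(bench$counts, paths["counts"])
  write_tsv_atomic(bench$truth, paths["truth"])
  write_tsv_atomic(bench$design, paths["design"])
  bed <- tibble(
    chrom = bench$truth$chrom,
    start = bench$truth$start,
    end = bench$truth$end,
    name = paste(bench$truth$peak_id, bench$truth$label,
                 ifelse(is.na(bench$truth$category), ".",
                        bench$truth$category), sep = "|")
  )
  write_atomic(function(tmp) {
    readr::write_tsv(bed, tmp, col_names = FALSE, progress = FALSE)
  }, paths["truth_bed"])
  invisible(paths)
}
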