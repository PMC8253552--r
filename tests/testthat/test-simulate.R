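# The synthetic downsampling benchmark generator.

test_that("the default configuration carries the benchmark design numbers", {
  cfg <- bench_config()
  expect_equal(cfg$n_peaks, 20000)
  expect_equal(cfg$n_differential, 10000)
  expect_equal(cfg$n_categories, 10)
  expect_equal(cfg$n_per_category, 1000)
  expect_equal(cfg$n_replicates, 5)
  expect_equal(cfg$replicate_thinning, c(0.10, 0.30))
  expect_error(bench_config(n_differential = 999), "must equal")
  expect_error(bench_config(n_peaks = 100, n_differential = 1000,
                            n_per_category = 100), "exceed")
})

test_that("the reference layout is non-overlapping and seed-stable", {
  cfg <- bench_config(n_peaks = 10, n_differential = 0, n_categories = 10,
                      n_per_category = 0, seed = 4)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$peaks), 10)
  expect_true(all(ref$peaks$start[-1] >= ref$peaks$end[-10]))  # sorted, disjoint
  expect_identical(simulate_reference(cfg), ref)
  expect_error(simulate_reference(bench_config(n_peaks = 10, n_differential = 0,
                                               n_per_category = 0,
                                               genome_length = 1000, seed = 4)),
               "genome_length")
})

test_that("reference counts match the configured distribution moments", {
  cfg <- bench_config(seed = 12)
  ref <- simulate_reference(cfg)
  mu <- cfg$count_mean
  v <- mu + mu^2 / cfg$count_dispersion
  se <- sqrt(v / cfg$n_peaks)
  expect_lt(abs(mean(ref$counts) - mu), 3 * se)
})

test_that("truth assignment partitions peaks into exact categories", {
  cfg <- scaled_bench_cfg(seed = 9)
  ref <- simulate_reference(cfg)
  truth <- assign_truth(ref$peaks, cfg)
  expect_equal(sum(truth$label == "differential"), 1000)
  expect_equal(sum(truth$label == "non_differential"), 1000)
  histo <- table(truth$category)
  expect_equal(unname(c(histo)), rep(100, 10))
  expect_equal(as.integer(names(histo)), seq(10, 100, 10))
  expect_identical(assign_truth(ref$peaks, cfg), truth)

  cfg0 <- bench_config(n_peaks = 50, n_differential = 0, n_per_category = 0,
                       seed = 2)
  truth0 <- assign_truth(simulate_reference(cfg0)$peaks, cfg0)
  expect_true(all(truth0$label == "non_differential"))
})

test_that("treatment downsampling follows the retention probabilities", {
  truth <- tibble::tibble(
    peak_id = c("p1", "p2", "p3"),
    label = c("differential", "non_differential", "differential"),
    category = c(100L, NA, 50L),
    direction = c("treatment", NA, "treatment")
  )
  refc <- c(800L, 700L, 1000L)
  tr <- downsample_treatment(refc, truth, seed = 1)
  expect_equal(tr[1], 0L)      # category 100: retention 0
  expect_equal(tr[2], 700L)    # non-differential copied unchanged

  # category 50: empirical retention over 200 seeds within 3 SE of 0.5
  reps <- vapply(1:200, function(s) downsample_treatment(refc, truth, seed = s)[3],
                 integer(1))
  p_hat <- mean(reps) / 1000
  se <- sqrt(0.5 * 0.5 / (1000 * 200))
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("replicate thinning lands in the configured range", {
  cfg <- bench_config(n_peaks = 200, n_differential = 100, n_per_category = 10,
                      seed = 3)
  counts <- rep(1000L, 200)
  reps <- make_replicates(counts, cfg, seed = 21)
  expect_equal(ncol(reps), 5)
  totals <- colSums(reps) / sum(counts)
  # retention 1 - U(0.10, 0.30), up to binomial noise
  expect_true(all(totals > 0.69 & totals < 0.91))

  cfg0 <- bench_config(n_peaks = 200, n_differential = 100, n_per_category = 10,
                       replicate_thinning = c(0, 0), seed = 3)
  reps0 <- make_replicates(counts, cfg0, seed = 5)
  expect_true(all(reps0 == 1000L))
})

test_that("the noise layer has the configured log-scale spread", {
  cfg <- bench_config(noise_sigma = 0.25, seed = 1)
  x <- rep(10000L, 20000)
  noisy <- add_noise(x, cfg, seed = 8)
  lf <- log(noisy / x)
  # SE of a sample SD of n log-normal draws ~ sigma / sqrt(2 n)
  expect_lt(abs(sd(lf) - 0.25), 3 * 0.25 / sqrt(2 * 20000))
  cfg0 <- bench_config(noise_sigma = 0, seed = 1)
  expect_identical(add_noise(x, cfg0, seed = 8), x)
})

test_that("the full benchmark has the designed shape and is byte-stable", {
  cfg <- bench_config(n_peaks = 300, n_differential = 100, n_per_category = 10,
                      seed = 77)
  bench <- simulate_benchmark(cfg)
  expect_equal(nrow(bench$counts), 300)
  expect_equal(sum(grepl("^(ref|treat)_", names(bench$counts))), 10)
  expect_equal(nrow(bench$design), 10)
  expect_equal(sort(unique(bench$design$condition)),
               c("reference", "treatment"))

  d1 <- tempfile(); d2 <- tempfile()
  write_benchmark(simulate_benchmark(cfg), d1)
  write_benchmark(simulate_benchmark(cfg), d2)
  for (f in c("counts.tsv", "truth.tsv", "design.tsv", "truth.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("expected treatment/reference ratios decrease with category", {
  cfg <- scaled_bench_cfg(seed = 15)
  bench <- simulate_benchmark(cfg)
  ref_mean <- rowMeans(bench$counts[, paste0("ref_", 1:5)])
  trt_mean <- rowMeans(bench$counts[, paste0("treat_", 1:5)])
  ratio <- (trt_mean + 1) / (ref_mean + 1)
  obs <- tapply(ratio, bench$truth$category, mean)
  # expected retention 1 - c/100, identical for non-differential peaks
  expect_true(all(diff(obs[as.character(seq(10, 100, 10))]) < 0))
  nd <- bench$truth$label == "non_differential"
  expect_lt(abs(mean(ratio[nd]) - 1), 0.1)
})
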