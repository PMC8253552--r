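# Scoring against synthetic truth and against expression fold-changes.

make_truth <- function(n_diff = 4, n_nd = 4, width = 1000) {
  n <- n_diff + n_nd
  tibble::tibble(
    peak_id = sprintf("t%02d", 1:n),
    chrom = "chr1",
    start = (0:(n - 1)) * 2000L,
    end = (0:(n - 1)) * 2000L + width,
    label = rep(c("differential", "non_differential"), c(n_diff, n_nd)),
    category = c(rep(c(25L, 50L, 75L, 100L), length.out = n_diff),
                 rep(NA_integer_, n_nd))
  )
}

test_that("perfect detection recovers every category and no false positives", {
  truth <- make_truth()
  detected <- dplyr::mutate(truth[truth$label == "differential", 1:4],
                            FDR = 0.001)
  rep <- evaluate_detection(detected, truth, criterion = "1bp")
  expect_equal(rep$n_true_positive, 4)
  expect_equal(rep$n_false_positive, 0)
  expect_true(all(rep$by_category$n_detected == rep$by_category$n_true))
})

test_that("the 25% criterion requires a quarter of the true peak covered", {
  truth <- make_truth(n_diff = 1, n_nd = 1, width = 1000)
  # significant peak overlapping the 1000-bp true peak by exactly 100 bp
  detected <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                             FDR = 0.001)
  r1 <- evaluate_detection(detected, truth, criterion = "1bp")
  r25 <- evaluate_detection(detected, truth, criterion = "frac25")
  expect_equal(r1$n_true_positive, 1)
  expect_equal(r25$n_true_positive, 0)
  expect_equal(r25$n_false_positive, 1)
})

test_that("detection counts equal a brute-force all-pairs oracle", {
  set.seed(42)
  for (rep_i in 1:3) {
    starts <- sort(sample(seq(0, 100000, 50), 50))
    truth <- tibble::tibble(
      peak_id = sprintf("t%02d", 1:50), chrom = "chr1",
      start = starts, end = starts + sample(100:1500, 50, TRUE),
      label = sample(c("differential", "non_differential"), 50, TRUE),
      category = 50L
    )
    truth$category[truth$label == "non_differential"] <- NA_integer_
    ds <- sample(seq(0, 100000, 50), 30)
    detected <- tibble::tibble(
      chrom = "chr1", start = ds, end = ds + sample(100:1500, 30, TRUE),
      FDR = runif(30, 0, 0.1)
    )
    for (crit in c("1bp", "frac25")) {
      r <- evaluate_detection(detected, truth, fdr_threshold = 0.05,
                              criterion = crit)
      sig <- detected[detected$FDR < 0.05, ]
      ov <- function(ts, te, ps, pe) max(0, min(te, pe) - max(ts, ps))
      hit <- function(ts, te) {
        any(vapply(seq_len(nrow(sig)), function(j) {
          o <- ov(ts, te, sig$start[j], sig$end[j])
          if (crit == "1bp") o >= 1 else o >= 0.25 * (te - ts)
        }, logical(1)))
      }
      tp_oracle <- sum(vapply(which(truth$label == "differential"),
                              function(i) hit(truth$start[i], truth$end[i]),
                              logical(1)))
      fp_oracle <- sum(vapply(seq_len(nrow(sig)), function(j) {
        !any(vapply(which(truth$label == "differential"), function(i) {
          o <- ov(truth$start[i], truth$end[i], sig$start[j], sig$end[j])
          if (crit == "1bp") o >= 1 else
            o >= 0.25 * (truth$end[i] - truth$start[i])
        }, logical(1)))
      }, logical(1)))
      expect_equal(r$n_true_positive, tp_oracle)
      expect_equal(r$n_false_positive, fp_oracle)
    }
  }
})

test_that("frac25 detection is never more generous than 1bp", {
  cfg <- bench_config(n_peaks = 500, n_differential = 200, n_per_category = 20,
                      seed = 31)
  bench <- simulate_benchmark(cfg)
  detected <- dplyr::mutate(bench$peaks, FDR = runif(500, 0, 0.2))
  r1 <- evaluate_detection(detected, bench$truth, criterion = "1bp")
  r25 <- evaluate_detection(detected, bench$truth, criterion = "frac25")
  joined <- dplyr::left_join(r1$by_category, r25$by_category, by = "category")
  expect_true(all(joined$n_detected.y <= joined$n_detected.x))
})

test_that("ROC endpoints and AUC match the Mann-Whitney oracle", {
  truth <- make_truth(5, 5)
  perfect <- tibble::tibble(peak_id = truth$peak_id,
                            score = ifelse(truth$label == "differential", 2, 1))
  expect_equal(roc_curve(perfect, truth)$auc, 1)

  flat <- tibble::tibble(peak_id = truth$peak_id, score = rep(1, 10))
  expect_equal(roc_curve(flat, truth)$auc, 0.5)

  set.seed(17)
  truth20 <- make_truth(10, 10)
  sc <- tibble::tibble(peak_id = truth20$peak_id, score = rnorm(20))
  r <- roc_curve(sc, truth20)
  pos <- sc$score[truth20$label == "differential"]
  neg <- sc$score[truth20$label != "differential"]
  u <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(r$auc, u)
  # monotone transform leaves the AUC unchanged
  sc2 <- dplyr::mutate(sc, score = exp(3 * score))
  expect_equal(roc_curve(sc2, truth20)$auc, r$auc)
  # curve is monotone in both axes
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  expect_error(roc_curve(sc, dplyr::mutate(truth20, label = "differential")),
               "single class")
})

test_that("nearest-gene annotation follows midpoint distance with tie-breaks", {
  genes <- tibble::tibble(
    gene_id = c("geneB", "geneA", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    tss = c(1000L, 5000L, 300L),
    strand = c("+", "-", "+")
  )
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2", "p3", "p4"),
    chrom = c("chr1", "chr1", "chr1", "chr3"),
    start = c(900L, 2900L, 4000L, 10L),
    end = c(1100L, 3100L, 4200L, 50L)
  )
  ann <- annotate_nearest_gene(peaks, genes)
  expect_equal(ann$gene_id[1], "geneB")   # TSS inside peak
  expect_equal(ann$distance[1], 0)
  expect_equal(ann$gene_id[2], "geneA")   # equidistant (2000 both): smaller id
  expect_equal(ann$gene_id[3], "geneA")   # midpoint 4100: geneA at 900 bp
  expect_true(is.na(ann$gene_id[4]))      # no genes on chr3

  # brute-force oracle on a random toy set
  set.seed(3)
  g2 <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                       tss = sample(0:20000, 10))
  p2 <- tibble::tibble(peak_id = sprintf("p%02d", 1:30), chrom = "chr1",
                       start = sample(0:20000, 30))
  p2$end <- p2$start + sample(100:400, 30, TRUE)
  ann2 <- annotate_nearest_gene(p2, g2)
  for (i in seq_len(30)) {
    s <- p2$start[i]; e <- p2$end[i]; mid <- floor((s + e) / 2)
    dist <- ifelse(g2$tss >= s & g2$tss < e, 0, abs(mid - g2$tss))
    best <- min(g2$gene_id[dist == min(dist)])
    expect_equal(ann2$gene_id[i], best)
  }
})

test_that("fold-change correlation handles identity, averaging and the oracle", {
  # identical peak and gene fold-changes: r = 1 at every cutoff
  n <- 300
  set.seed(8)
  fc <- rnorm(n, 0, 0.5)
  pk <- tibble::tibble(
    peak_id = sprintf("p%03d", 1:n), FDR = seq(0.001, 0.3, length.out = n),
    log10_fc = fc, gene_id = sprintf("g%03d", 1:n)
  )
  ex <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), log10_fc = fc)
  cc <- fc_correlation(pk, ex, grid_step = 100, max_n = 300)
  expect_equal(cc$curve$r, rep(1, 3))
  expect_equal(cc$curve$top_n, c(100, 200, 300))

  # averaging on the log10 scale: fold-changes 2 and 8 average to sqrt(16)=4
  pk2 <- tibble::tibble(
    peak_id = c("p1", "p2", "p3", "p4"),
    FDR = c(0.01, 0.02, 0.03, 0.04),
    log10_fc = log10(c(2, 8, 3, 5)),
    gene_id = c("gA", "gA", "gB", "gC")
  )
  ex2 <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                        log10_fc = log10(c(4, 3, 5)))
  cc2 <- fc_correlation(pk2, ex2, grid_step = 4, max_n = 4)
  expect_equal(cc2$curve$r, 1)  # log10 mean of 2 and 8 equals log10(4)
  expect_equal(cc2$curve$n_genes, 3)

  # textbook Pearson oracle on a 12-gene table
  set.seed(5)
  pk3 <- tibble::tibble(
    peak_id = sprintf("q%02d", 1:12), FDR = sort(runif(12)),
    log10_fc = rnorm(12), gene_id = sprintf("h%02d", 1:12)
  )
  ex3 <- tibble::tibble(gene_id = sprintf("h%02d", 1:12), log10_fc = rnorm(12))
  cc3 <- fc_correlation(pk3, ex3, grid_step = 12, max_n = 12)
  x <- pk3$log10_fc; y <- ex3$log10_fc
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc3$curve$r, r_oracle)

  # fewer than 3 contributing genes: r is missing
  cc4 <- fc_correlation(pk2[1:2, ], ex2, grid_step = 2, max_n = 2)
  expect_true(is.na(cc4$curve$r))
})
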