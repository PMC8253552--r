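# rotspeaks

Differential peak detection for ATAC-seq and ChIP-seq, built around a
reproducibility-optimized test statistic, together with a downsampling-based
synthetic benchmark generator and evaluation utilities.

## The problem

Given per-sample peak calls and read counts for two biological conditions
(e.g. open chromatin before/after stimulation, or a histone mark in patients
vs. controls), which genomic regions are differentially enriched? Parametric
count models can be poorly calibrated for the broad, heterogeneous signals of
chromatin data. `rotspeaks` instead lets the data choose the test statistic:
it picks, from a family of t-type statistics, the one whose top-ranked
regions are most reproducible under resampling.

## The statistic

For a candidate peak *g* with normalized counts in conditions *i* and *j*:

```
d_alpha(g) = |x̄_g^i − x̄_g^j| / (alpha1 + alpha2 · s_g)
```

where `s_g` is the pooled two-sample standard error. `alpha = (0, 1)` is the
classical two-sample t magnitude; `alpha = (1, 0)` ranks by absolute mean
difference. The tuning maximizes the reproducibility z-score

```
Z_k(d_alpha) = ( R_k(d_alpha) − R_k^0(d_alpha) ) / s_k(d_alpha)
```

over `alpha` and the top-list size `k`, where `R_k` is the average fraction
of the top-*k* list shared between members of B stratified bootstrap pairs,
`R_k^0` is the same for label-permuted null pairs, and `s_k` is the bootstrap
standard deviation of the overlap. Significance is assessed by a
permutation-based false discovery rate at the optimized `alpha`.

Around the core test, the package provides the standard workflow: merging
per-sample BED/narrowPeak calls into candidate peaks, fragment/read counting
from indexed BAMs, median-of-ratios normalization, per-category detection
reports and ROC curves against synthetic truth, and nearest-gene
fold-change correlation against expression data.

## Worked example

Simulate the scaled synthetic benchmark (2000 candidate peaks, half of them
true differential peaks spread over ten intensity categories, five thinned
replicates per condition), call differential peaks, and score the calls
against the truth labels:

```r
library(rotspeaks)

cfg_b <- bench_config(n_peaks = 2000, n_differential = 1000,
                      n_per_category = 100, seed = 11)
bench <- simulate_benchmark(cfg_b)

tab <- differential_peaks(bench$counts, bench$design,
                          config = rots_config(B = 200, n_perm = 200, seed = 12),
                          normalize = FALSE)
glance(attr(tab, "fit"))
evaluate_detection(tab, bench$truth, criterion = "1bp")
```

which prints:

```
Detection report (overlap: 1bp, FDR < 0.05)
  significant peaks: 603  true positives: 566  false positives: 37
# A tibble: 10 × 3
   category n_true n_detected
      <dbl>  <int>      <int>
 1       10    100          0
 2       20    100          4
 3       30    100         11
 4       40    100         21
 5       50    100         63
 6       60    100         74
 7       70    100         96
 8       80    100         97
 9       90    100        100
10      100    100        100
```

Reading: the optimizer settled on a statistic with a strongly regularized
denominator (`alpha = (5, 1)`, `k = 500`, `Z ≈ 11`). Peaks whose signal
differs by 60–100% between conditions are detected almost completely, power
decays smoothly toward the 10% category, and only 37 of the 1000
non-differential peaks are called — the qualitative behaviour expected of a
well-calibrated differential caller on this benchmark.
`autoplot(evaluate_detection(...))`, `autoplot(attr(tab, "fit"))` and
`roc_curve()` visualize the same results.

A command-line surface wrapping the same functions ships at
`inst/cli/rotspeaks` (subcommands `merge`, `count`, `test`, `simulate`,
`evaluate`, `correlate`; every stochastic subcommand takes `--seed` and
writes a `provenance.json`).

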