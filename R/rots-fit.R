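#' Configuration for the reproducibility-optimized test
#'
#' @param B Number of bootstrap (and null) pairs used to score each grid
#'   cell. Default 1000.
#' @param K_grid Candidate top-list sizes. Default: the ladder 25, 50, 100,
#'   200, 300, 500, 750, 1000, 1500, 2000, 2500, 5000 truncated at half the
#'   number of features.
#' @param alpha_grid List of length-2 numeric vectors \code{c(alpha1, alpha2)}.
#'   Default: \code{alpha2 = 1} with \code{alpha1} in 0, 0.01, 0.02, 0.05,
#'   0.1, 0.15, 0.2, 0.3, 0.5, 1, 1.5, 2, 3, 5, plus the pure
#'   mean-difference ranking \code{c(1, 0)}.
#' @param n_perm Number of label permutations for the FDR estimate.
#'   Default 1000; at least 10.
#' @param seed Integer seed; a fixed seed makes the whole fit reproducible.
#' @return A list of class `rots_config`.
#' @export
rots_config <- function(B = 1000, K_grid = NULL, alpha_grid = NULL,
                        n_perm = 1000, seed = NULL) {
  if (B < 2) abort("B must be at least 2.")
  if (n_perm < 10) abort("n_perm below 10 gives unstable FDR estimates.")
  if (is.null(alpha_grid)) {
    alpha_grid <- c(
      lapply(c(0, 0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 1, 1.5, 2, 3, 5),
             function(a1) c(a1, 1)),
      list(c(1, 0))
    )
  }
  lapply(alpha_grid, check_alpha)
  structure(list(B = as.integer(B), K_grid = K_grid, alpha_grid = alpha_grid,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "rots_config")
}

default_k_grid <- function(n_features) {
  ladder <- c(25, 50, 100, 200, 300, 500, 750, 1000, 1500, 2000, 2500, 5000)
  k <- ladder[ladder <= n_features / 2]
  if (length(k) == 0) k <- max(1L, floor(n_features / 2))
  as.integer(k)
}

#' Fit the reproducibility-optimized differential test
#'
#' Tunes the t-type statistic family \eqn{d_\alpha} by maximizing the
#' reproducibility z-score \eqn{Z_k = (R_k - R_k^0)/s_k} over a grid of
#' statistic parameters \eqn{\alpha} and top-list sizes \eqn{k}. \eqn{R_k}
#' is the average fraction of the top-k list shared between the members of
#' `B` stratified bootstrap pairs; \eqn{R_k^0} is the same quantity for
#' label-permuted null pairs; \eqn{s_k} is the bootstrap standard deviation
#' of the per-pair overlaps. The observed statistic at the optimum is then
#' assigned permutation-based p-values and false discovery rates.
#'
#' @inheritParams rots_stat
#' @param config A [rots_config()]; `seed` here overrides the config seed
#'   when given.
#' @param seed Optional integer seed (convenience shortcut).
#' @param compute_fdr Set to `FALSE` to skip the permutation FDR stage.
#' @return An object of class `rots_fit`: use [tidy()] for the per-feature
#'   table, [glance()] for the optimization summary, and [autoplot()] for a
#'   volcano-style overview. Fields include `alpha`, `k`, `Z`, `R` (the
#'   optimized triple and its bootstrap reproducibility), the scored `grid`,
#'   and `table` with columns `feature_id`, `d`, `rank`, `mean_diff`,
#'   `log2FC`, `pvalue`, `FDR`.
#' @export
rots <- function(counts, design, config = rots_config(), seed = NULL,
                 compute_fdr = TRUE) {
  if (!inherits(config, "rots_config")) abort("`config` must come from rots_config().")
  if (!is.null(seed)) config$seed <- seed
  m <- as_count_matrix(counts)
  dg <- check_design(m, design)
  n <- nrow(m)
  K <- config$K_grid %||% default_k_grid(n)
  K <- sort(unique(as.integer(K)))
  if (any(K < 1 | K > n)) abort("All top-list sizes k must be in [1, n_features].")
  alphas <- config$alpha_grid

  with_seed_if(config$seed, {
    opt <- optimize_grid(m, dg, alphas, K, config$B)
    st <- stat_engine(m, dg$cols1, dg$cols2)
    d_obs <- stat_d_lenient(st, opt$alpha)
    res <- tibble(
      feature_id = rownames(m),
      d = d_obs,
      rank = rank_desc(d_obs),
      mean_diff = st$num_signed,
      log2FC = log2((st$mean1 + 0.5) / (st$mean2 + 0.5))
    )
    if (compute_fdr) {
      fd <- permutation_fdr(m, dg, opt$alpha, config$n_perm, d_obs)
      res$pvalue <- fd$pvalue
      res$FDR <- fd$fdr
    }
    structure(list(
      table = res,
      alpha = opt$alpha, k = opt$k, Z = opt$Z, R = opt$R,
      grid = opt$grid,
      conditions = dg$labels,
      n_samples = c(length(dg$cols1), length(dg$cols2)),
      B = config$B, n_perm = if (compute_fdr) config$n_perm else NA_integer_,
      seed = config$seed
    ), class = "rots_fit")
  })
}

# d_alpha that stays total under resampling: a zero denominator yields +Inf
# for a nonzero mean difference (ranks first) and 0 for the 0/0 case.
stat_d_lenient <- function(st, alpha) {
  denom <- alpha[1] + alpha[2] * st$s
  d <- st$num / denom
  zero <- denom == 0
  if (any(zero)) d[zero] <- ifelse(st$num[zero] > 0, Inf, 0)
  d
}

# Score every (alpha, k) grid cell with the same B bootstrap and null pairs
# and return the arg-max cell. Ties are resolved toward the first alpha and
# the smallest k, deterministically.
optimize_grid <- function(m, dg, alphas, K, B) {
  n <- nrow(m)
  n1 <- length(dg$cols1)
  ntot <- n1 + length(dg$cols2)
  plan <- draw_resampling_plan(dg$cols1, dg$cols2, B)
  n_a <- length(alphas)
  n_k <- length(K)

  pair_overlaps <- function(idx_a, idx_b) {
    # returns an (alpha x k) matrix of top-list overlaps for one pair
    st_a <- stat_engine(m, idx_a[seq_len(n1)], idx_a[(n1 + 1):ntot])
    st_b <- stat_engine(m, idx_b[seq_len(n1)], idx_b[(n1 + 1):ntot])
    out <- matrix(0, n_a, n_k)
    for (ai in seq_len(n_a)) {
      ra <- rank_desc(stat_d_lenient(st_a, alphas[[ai]]))
      rb <- rank_desc(stat_d_lenient(st_b, alphas[[ai]]))
      shared <- cumsum(tabulate(pmax(ra, rb), nbins = n))
      out[ai, ] <- shared[K] / K
    }
    out
  }

  R_boot <- array(0, c(B, n_a, n_k))
  R_null <- array(0, c(B, n_a, n_k))
  for (b in seq_len(B)) {
    R_boot[b, , ] <- pair_overlaps(plan$boot_a[, b], plan$boot_b[, b])
    R_null[b, , ] <- pair_overlaps(plan$null_a[, b], plan$null_b[, b])
  }

  grid <- tidyr::expand_grid(ai = seq_len(n_a), ki = seq_len(n_k))
  grid <- mutate(grid,
    alpha1 = vapply(.data$ai, function(i) alphas[[i]][1], numeric(1)),
    alpha2 = vapply(.data$ai, function(i) alphas[[i]][2], numeric(1)),
    k = K[.data$ki],
    r_boot = purrr::map2_dbl(.data$ai, .data$ki, ~ mean(R_boot[, .x, .y])),
    r_null = purrr::map2_dbl(.data$ai, .data$ki, ~ mean(R_null[, .x, .y])),
    s_k = purrr::map2_dbl(.data$ai, .data$ki, ~ sd(R_boot[, .x, .y])),
    z = purrr::map2_dbl(.data$ai, .data$ki, ~ z_score(R_boot[, .x, .y],
                                                      R_null[, .x, .y]))
  )
  eligible <- which(is.finite(grid$z))
  if (length(eligible) == 0) {
    abort("All (alpha, k) grid cells are degenerate; cannot optimize.")
  }
  best <- eligible[which.max(grid$z[eligible])]
  list(
    alpha = alphas[[grid$ai[best]]],
    k = grid$k[best],
    Z = grid$z[best],
    R = grid$r_boot[best],
    grid = select(grid, "alpha1", "alpha2", "k", "r_boot", "r_null", "s_k", "z")
  )
}

# Count, for each x, how many elements of `values` are >= x.
count_ge <- function(x, values) {
  sorted <- sort(values)
  length(values) - findInterval(x, sorted, left.open = TRUE)
}

# Permutation-based p-values and FDR at a fixed alpha. Null statistics come
# from n_perm random permutations of the condition labels. The pooled
# p-value is (1 + #{null >= d_g}) / (1 + n_perm * n). The FDR is the mean
# over permutations of the ratio #{null in perm >= d_g} / #{observed >= d_g},
# capped at 1 and made monotone non-decreasing along decreasing d.
permutation_fdr <- function(m, dg, alpha, n_perm, d_obs) {
  if (n_perm < 10) abort("n_perm below 10 gives unstable FDR estimates.")
  n <- nrow(m)
  n1 <- length(dg$cols1)
  all_cols <- c(dg$cols1, dg$cols2)
  ntot <- length(all_cols)
  null_pool <- numeric(0)
  null_list <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample(all_cols)
    st <- stat_engine(m, perm[seq_len(n1)], perm[(n1 + 1):ntot])
    null_list[[p]] <- stat_d_lenient(st, alpha)
  }
  null_pool <- unlist(null_list, use.names = FALSE)

  ge_null <- count_ge(d_obs, null_pool)      # pooled over permutations
  ge_obs <- count_ge(d_obs, d_obs)           # includes the feature itself
  pvalue <- (1 + ge_null) / (1 + n_perm * n)
  fdr <- pmin(1, (ge_null / n_perm) / ge_obs)

  ord <- order(-d_obs, seq_len(n), method = "radix")
  fdr[ord] <- rev(cummin(rev(fdr[ord])))
  list(pvalue = pvalue, fdr = fdr)
}
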