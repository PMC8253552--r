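#' Reproducibility-optimized t-type statistic family
#'
#' Computes the t-type statistic \eqn{d_\alpha(g) = |\bar{x}_g^i - \bar{x}_g^j| /
#' (\alpha_1 + \alpha_2 s_g)} for every feature (row) of a count matrix, where
#' \eqn{\bar{x}_g^i} and \eqn{\bar{x}_g^j} are the group means and \eqn{s_g}
#' is the pooled two-sample standard error
#' \eqn{\sqrt{s_p^2 (1/n_i + 1/n_j)}} with
#' \eqn{s_p^2 = ((n_i-1)s_i^2 + (n_j-1)s_j^2)/(n_i+n_j-2)}.
#' With \code{alpha = c(0, 1)} the statistic is the magnitude of the classical
#' equal-variance two-sample t statistic; with \code{alpha = c(1, 0)} it is
#' the absolute mean difference (a fold-change-like ranking on count data).
#'
#' @param counts Feature-by-sample data: a data frame whose first
#'   non-numeric column holds feature ids and whose numeric columns are
#'   samples, or a numeric matrix with rownames.
#' @param design Data frame with columns `sample_id` and `condition`
#'   (exactly two conditions, at least two samples each).
#' @param alpha Length-2 numeric \code{c(alpha1, alpha2)}; \code{alpha1 >= 0},
#'   \code{alpha2} in \{0, 1\}, not both zero.
#' @return A tibble with one row per feature: `feature_id`, `d` (the
#'   statistic), `rank` (1 = largest d; ties broken by input order),
#'   `mean_diff` (signed, condition i minus condition j in alphabetical
#'   order of condition labels), and `se` (pooled standard error).
#' @examples
#' m <- matrix(rpois(60, 20), nrow = 10,
#'             dimnames = list(paste0("p", 1:10), paste0("s", 1:6)))
#' design <- data.frame(sample_id = paste0("s", 1:6),
#'                      condition = rep(c("a", "b"), each = 3))
#' rots_stat(m, design, alpha = c(0, 1))
#' @export
rots_stat <- function(counts, design, alpha = c(0, 1)) {
  m <- as_count_matrix(counts)
  dg <- check_design(m, design)
  check_alpha(alpha)
  st <- stat_engine(m, dg$cols1, dg$cols2)
  d <- stat_d(st, alpha, feature_ids = rownames(m))
  tibble(
    feature_id = rownames(m),
    d = d,
    rank = rank_desc(d),
    mean_diff = st$num_signed,
    se = st$s
  )
}

check_alpha <- function(alpha) {
  if (length(alpha) != 2 || !is.numeric(alpha)) {
    abort("`alpha` must be a numeric vector c(alpha1, alpha2).")
  }
  if (alpha[1] < 0) abort("alpha1 must be non-negative.")
  if (!alpha[2] %in% c(0, 1)) abort("alpha2 must be 0 or 1.")
  if (alpha[1] == 0 && alpha[2] == 0) abort("alpha = (0, 0) is not allowed.")
  invisible(alpha)
}

# Per-feature group means, signed/absolute mean difference and pooled SE for
# a column split. `m` is features x samples; cols1/cols2 are column indices.
stat_engine <- function(m, cols1, cols2) {
  n1 <- length(cols1)
  n2 <- length(cols2)
  x1 <- m[, cols1, drop = FALSE]
  x2 <- m[, cols2, drop = FALSE]
  m1 <- unname(rowMeans(x1))
  m2 <- unname(rowMeans(x2))
  v1 <- unname(rowVars(x1, useNames = FALSE))
  v2 <- unname(rowVars(x2, useNames = FALSE))
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(mean1 = m1, mean2 = m2,
       num = abs(m1 - m2), num_signed = m1 - m2, s = s)
}

# d_alpha from a stat_engine result; errors on zero denominators, naming the
# first offending feature.
stat_d <- function(st, alpha, feature_ids = NULL) {
  denom <- alpha[1] + alpha[2] * st$s
  bad <- which(denom <= 0)
  if (length(bad) > 0) {
    id <- if (!is.null(feature_ids)) feature_ids[bad[1]] else paste0("row ", bad[1])
    abort(paste0("Zero denominator in d_alpha for feature ", id,
                 " (alpha1 = ", alpha[1], ", zero standard error)."))
  }
  st$num / denom
}

# Descending-d ranks with deterministic tie-break (stable: ties keep input
# order). Returns an integer permutation of 1..n.
rank_desc <- function(d) {
  ord <- order(-d, seq_along(d), method = "radix")
  r <- integer(length(d))
  r[ord] <- seq_along(d)
  r
}

#' Top-list reproducibility between two rankings
#'
#' The fraction of features appearing in the top `k` of both rankings:
#' \eqn{R_k = \#\{g : r_g \le k \text{ in both}\} / k}.
#'
#' @param ranks_a,ranks_b Either tibbles as returned by [rots_stat()] (with
#'   `feature_id` and `rank` columns) or bare integer rank vectors over the
#'   same features in the same order.
#' @param k Top-list size, between 1 and the number of features.
#' @return A single number in \[0, 1\].
#' @export
reproducibility <- function(ranks_a, ranks_b, k) {
  ra <- extract_ranks(ranks_a)
  rb <- extract_ranks(ranks_b)
  if (!is.null(names(ra)) && !is.null(names(rb))) {
    if (!setequal(names(ra), names(rb))) {
      abort("Rankings are over different feature sets.")
    }
    rb <- rb[names(ra)]
  } else if (length(ra) != length(rb)) {
    abort("Rankings are over different feature sets.")
  }
  if (k < 1 || k > length(ra)) abort("`k` must be between 1 and the number of features.")
  sum(ra <= k & rb <= k) / k
}

extract_ranks <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("feature_id", "rank") %in% names(x))) {
      abort("Ranking tables need `feature_id` and `rank` columns.")
    }
    setNames(as.integer(x$rank), x$feature_id)
  } else {
    setNames(as.integer(x), names(x))
  }
}

# Reproducibility z-score for one grid cell: Z = (mean(R_boot) - mean(R_null))
# / sd(R_boot). A zero-variance bootstrap distribution gives Z = 0 when the
# means agree and a signed infinity otherwise (excluded from optimization).
z_score <- function(r_boot, r_null) {
  if (length(r_boot) < 2 || length(r_null) < 2) {
    abort("Need at least two bootstrap and two null reproducibility values.")
  }
  num <- mean(r_boot) - mean(r_null)
  s <- sd(r_boot)
  if (s == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / s
}
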