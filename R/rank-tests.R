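# Rank-test engines. Small samples get exact two-sided p-values from
# the permutation distribution of the statistic computed on average
# (tie-adjusted) ranks: full enumeration of group assignments for the
# rank-sum test, a generating-function convolution over sign
# assignments for the signed-rank test. Large samples delegate to
# stats::wilcox.test (normal approximation with tie correction and
# continuity correction).

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided. Exact when the number of group assignments is small
#' enough to enumerate (all `choose(n+m, n)` assignments, valid under
#' ties because the statistic is computed on average ranks); otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration;
#'   default `NULL` enumerates when `choose(n+m, n) <= 2e5`.
#' @return List: `statistic` (U, the Mann-Whitney count for `x`),
#'   `p.value`, `method` (`"exact enumeration"` or
#'   `"normal approximation"`), `n` (group sizes).
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all observations tied: ranks are degenerate")
    return(list(statistic = n * m / 2, p.value = 1,
                method = "degenerate", n = c(n, m)))
  }
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  n_comb <- choose(n + m, n)
  do_exact <- if (is.null(exact)) n_comb <= 2e5 else exact
  if (do_exact) {
    idx <- utils::combn(n + m, n)
    u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    mid <- n * m / 2
    p <- mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
    list(statistic = u_obs, p.value = p, method = "exact enumeration",
         n = c(n, m))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    list(statistic = u_obs, p.value = wt$p.value,
         method = "normal approximation", n = c(n, m))
  }
}

# Exact null distribution of 2*V (doubled so tied average ranks become
# integers): generating-function convolution over sign assignments.
signed_rank_exact_p <- function(ranks2, v2_obs) {
  total <- sum(ranks2)
  prob <- numeric(total + 1L)   # support 0..total
  prob[1L] <- 1
  for (dr in ranks2) {
    shifted <- c(numeric(dr), prob[seq_len(total + 1L - dr)])
    prob <- (prob + shifted) / 2
  }
  support <- 0:total
  mid <- total / 2
  sum(prob[abs(support - mid) >= abs(v2_obs - mid) - 1e-9])
}

#' One-sample / paired Wilcoxon signed-rank test
#'
#' Two-sided, on differences `d` (zeros dropped, ranks of `|d|`
#' averaged under ties). Exact for up to 25 non-zero differences --
#' ties included, via the convolution of the tied-rank generating
#' function -- otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param d Numeric vector of differences.
#' @param exact As in [rank_sum_test()]; default exact when
#'   `sum(d != 0) <= 25`.
#' @return List: `statistic` (V, sum of positive-difference ranks),
#'   `p.value`, `method`, `n_nonzero`.
#' @export
signed_rank_test <- function(d, exact = NULL) {
  stopifnot(length(d) >= 1)
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    stop("all differences are zero: signed-rank test degenerate")
  }
  if (length(nz) < length(d)) {
    warning(length(d) - length(nz), " zero difference(s) dropped")
  }
  r <- rank(abs(nz))
  v_obs <- sum(r[nz > 0])
  do_exact <- if (is.null(exact)) length(nz) <= 25L else exact
  if (do_exact) {
    p <- signed_rank_exact_p(as.integer(round(2 * r)),
                             as.integer(round(2 * v_obs)))
    list(statistic = v_obs, p.value = min(p, 1),
         method = "exact enumeration", n_nonzero = length(nz))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(nz, exact = FALSE, correct = TRUE)
    )
    list(statistic = v_obs, p.value = wt$p.value,
         method = "normal approximation", n_nonzero = length(nz))
  }
}
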