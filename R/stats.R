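# Bootstrap inference and weighted summaries.

#' Bootstrap estimate, standard error and two-tailed p-value
#'
#' Resamples the data with replacement `n_boot` times and recomputes the
#' statistic. The two-tailed p-value against a null value is twice the
#' smaller of the fractions of resamples above and below the null, floored
#' at `1/n_boot` (a floor hit means "p below the bootstrap resolution").
#' Optional weights travel with the resampled elements, for trial-count
#' weighted session averages.
#'
#' @param x Vector, matrix or data frame; rows are the resampling unit.
#' @param statistic Function of (resampled x\[, weights\]) returning a
#'   scalar. Defaults to the (weighted) mean of a vector.
#' @param n_boot Number of resamples (default 10^4).
#' @param weights Optional per-row weights, resampled jointly with rows.
#' @param null Null value for the test (default 0).
#' @param seed Integer seed.
#' @return List: `estimate`, `se`, `p`, `n_boot`, `null`.
#' @export
bootstrap_stat <- function(x, statistic = NULL, n_boot = 10000,
                           weights = NULL, null = 0, seed = 1L) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (n == 0) stop("empty sample")
  take <- function(obj, idx) if (is.null(dim(obj))) obj[idx]
    else obj[idx, , drop = FALSE]
  if (is.null(statistic)) {
    statistic <- if (is.null(weights))
      function(d, ...) mean(d)
    else function(d, w) stats::weighted.mean(d, w)
  }
  call_stat <- function(idx) {
    if (is.null(weights)) statistic(take(x, idx))
    else statistic(take(x, idx), weights[idx])
  }
  set.seed(seed)
  est <- call_stat(seq_len(n))
  boots <- vapply(seq_len(n_boot),
                  function(i) call_stat(sample.int(n, n, replace = TRUE)), 0)
  ok <- is.finite(boots)
  if (!all(ok)) boots <- boots[ok]
  p_plus <- mean(boots > null) + 0.5 * mean(boots == null)
  p <- max(2 * min(p_plus, 1 - p_plus), 1 / n_boot)
  list(estimate = est, se = stats::sd(boots), p = min(p, 1),
       n_boot = n_boot, null = null)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Trial-count-weighted performance average
#'
#' Averages per-unit performance with weights proportional to the number of
#' trials each unit contributes: `P = sum(w_i * P_i)`, `w_i = n_i / sum(n)`.
#' When per-unit control performances are supplied, also returns the
#' weighted performance change `delta = sum(w_i * (P_i - P_control_i))`.
#'
#' @param n Trials per unit (e.g., per animal).
#' @param p Performance per unit (fraction correct).
#' @param p_control Optional per-unit control performance.
#' @return List with `p` and, if applicable, `delta`. Units with `n == 0`
#'   are excluded with a message.
#' @export
#' @examples
#' weighted_performance(c(10, 30), c(1.0, 0.5))$p  # 0.625
weighted_performance <- function(n, p, p_control = NULL) {
  stopifnot(length(n) == length(p))
  keep <- n > 0
  if (!all(keep)) {
    message(sprintf("weighted_performance: %d empty units excluded",
                    sum(!keep)))
    n <- n[keep]; p <- p[keep]
    if (!is.null(p_control)) p_control <- p_control[keep]
  }
  if (!length(n)) stop("no non-empty units")
  w <- n / sum(n)
  out <- list(p = sum(w * p))
  if (!is.null(p_control)) out$delta <- sum(w * (p - p_control))
  out
}
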