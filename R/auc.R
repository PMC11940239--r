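#' Rank-based AUC (Mann-Whitney statistic)
#'
#' The area under the ROC curve computed as the fraction of
#' (positive, negative) pairs in which the positive sample outscores the
#' negative one, ties counted 1/2 — the rank-sum identity, exact for any
#' score vector including heavy ties.
#'
#' @param scores numeric scores, larger = more case-like.
#' @param labels class labels, same length as scores.
#' @param positive the label counted as positive.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels, positive) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval of the median
#'
#' Resamples the values with replacement `n_bootstrap` times, takes the
#' median of each resample, and returns the (1-level)/2 and 1-(1-level)/2
#' percentiles. Uses the current RNG state.
#'
#' @param values nonempty numeric vector.
#' @param n_bootstrap number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @return named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, n_bootstrap = 1000, level = 0.95) {
  if (!length(values)) stop("bootstrap_ci: empty input")
  n <- length(values)
  meds <- vapply(
    seq_len(n_bootstrap),
    function(i) stats::median(values[sample.int(n, n, replace = TRUE)]),
    numeric(1)
  )
  alpha <- (1 - level) / 2
  ci <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = ci[1], upper = ci[2])
}

# Batched percentile bootstrap: one resample-index matrix applied to every
# column of `mat` (iterations x quantities), so per-feature CIs share draws
# and cost one pass. Returns a 2 x ncol matrix (lower, upper).
bootstrap_ci_matrix <- function(mat, n_bootstrap = 1000, level = 0.95) {
  n <- nrow(mat)
  idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), n_bootstrap, n)
  alpha <- (1 - level) / 2
  apply(mat, 2, function(v) {
    meds <- apply(idx, 1, function(i) stats::median(v[i]))
    stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
}
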