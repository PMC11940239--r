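# Independent brute-force oracles used to cross-check the package's
# statistics against first-principles implementations.

# BH step-up by direct application of the definition:
# q(i) = min_{j >= i} m * p_(j) / j on the ascending sort, mapped back.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[ord][i:m] / (i:m))
  }
  pmin(q_sorted, 1)[order(ord)]
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins, summing probabilities <= that of the observed table.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by trapezoidal integration of the empirical ROC curve, sweeping the
# threshold over the distinct scores (ties collapse into single ROC steps).
auc_trapezoid_oracle <- function(scores, labels, positive) {
  pos <- labels == positive
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled ranks to the first sample (tie-free data only).
wilcoxon_enum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(seq_len(n)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  min(1, 2 * min(p_less, p_greater))
}

# Welch t-test p from the textbook statistic and Satterthwaite df.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# Small logged/normalized tables built in code.
make_table <- function(values, state, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(features)) features <- sprintf("F%d", seq_len(ncol(values)))
  dimnames(values) <- list(samples, features)
  feature_table(values, state)
}
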