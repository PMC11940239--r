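#' Median-based sample normalization
#'
#' Divides each sample's abundances by that sample's median positive value,
#' then multiplies by the grand median of the sample medians so the output
#' stays on an intensity-like scale. Removes per-sample multiplicative
#' effects (injection volume, total signal): a sample that is a uniform
#' rescaling of another becomes identical to it.
#'
#' @param table a raw `feature_table`; every sample must have at least one
#'   positive value.
#' @param method `"median"` (default) or `"sum"` (total-signal
#'   normalization), or `"none"`.
#' @return a `feature_table` with state `normalized`.
#' @export
normalize_samples <- function(table, method = c("median", "sum", "none")) {
  method <- match.arg(method)
  stopifnot_state(table, "raw", "normalize_samples")
  x <- table$values
  if (method == "none") return(feature_table(x, "normalized"))
  size <- apply(x, 1, function(r) {
    pos <- r[!is.na(r) & r > 0]
    if (!length(pos)) return(NA_real_)
    if (method == "median") stats::median(pos) else sum(pos)
  })
  if (anyNA(size)) {
    stop("sample has no positive values: ", rownames(x)[which(is.na(size))[1]])
  }
  grand <- stats::median(size)
  out <- x / size * grand
  feature_table(out, "normalized")
}

#' Log-transform a normalized feature table
#'
#' Replaces each value by `log(value + pseudo)` in the requested base. The
#' default pseudo-count is half the smallest positive value in the table
#' when the table contains zeros (the usual remedy), and 0 otherwise, so the
#' transform is exact on strictly positive data. Monotone order of values is
#' preserved.
#'
#' @param table a normalized `feature_table`.
#' @param base logarithm base, 10 (default) or 2.
#' @param pseudo non-negative pseudo-count; `NULL` (default) uses half the
#'   minimum positive value when the table contains zeros, else 0.
#' @return a `feature_table` with state `logged`; the pseudo-count used is
#'   stored in attribute `"pseudo"`.
#' @export
log_transform <- function(table, base = 10, pseudo = NULL) {
  stopifnot_state(table, "normalized", "log_transform")
  x <- table$values
  if (is.null(pseudo)) {
    pos <- x[!is.na(x) & x > 0]
    if (!length(pos)) stop("table has no positive values to anchor the pseudo-count")
    pseudo <- if (any(x <= 0, na.rm = TRUE)) min(pos) / 2 else 0
  }
  if (pseudo < 0) stop("pseudo-count must be >= 0")
  if (any(x + pseudo <= 0, na.rm = TRUE)) {
    stop("value + pseudo <= 0: increase the pseudo-count")
  }
  out <- feature_table(log(x + pseudo, base = base), "logged")
  attr(out, "pseudo") <- pseudo
  attr(out, "log_base") <- base
  out
}

#' Autoscale (unit-variance scale) a logged feature table
#'
#' Mean-centers each metabolite column and divides by its sample standard
#' deviation (n - 1 denominator). Zero-variance columns are centered only
#' and flagged in attribute `"zero_variance"`. Pareto scaling (divide by the
#' square root of the SD) is available as an alternative.
#'
#' @param table a logged `feature_table`.
#' @param method `"auto"` (default), `"pareto"` or `"center"` (no division).
#' @return a `feature_table` with state `scaled`.
#' @export
autoscale <- function(table, method = c("auto", "pareto", "center")) {
  method <- match.arg(method)
  stopifnot_state(table, "logged", "autoscale")
  x <- table$values
  mu <- colMeans(x, na.rm = TRUE)
  s <- apply(x, 2, stats::sd, na.rm = TRUE)
  zero <- which(!is.na(s) & s == 0)
  div <- switch(method,
    auto = s,
    pareto = sqrt(s),
    center = rep(1, length(s))
  )
  div[div == 0 | is.na(div)] <- 1
  out <- sweep(sweep(x, 2, mu, `-`), 2, div, `/`)
  ft <- feature_table(out, "scaled")
  attr(ft, "zero_variance") <- colnames(x)[zero]
  ft
}

#' Preprocess a raw feature table
#'
#' The standard chain: sample normalization, log transformation, scaling.
#' Each step is independently switchable.
#'
#' @param table a raw `feature_table`.
#' @param normalization passed to [normalize_samples()].
#' @param log_base passed to [log_transform()].
#' @param pseudo passed to [log_transform()].
#' @param scaling passed to [autoscale()].
#' @return a `feature_table` with state `scaled`.
#' @export
preprocess <- function(table, normalization = "median", log_base = 10,
                       pseudo = NULL, scaling = "auto") {
  autoscale(
    log_transform(normalize_samples(table, normalization), log_base, pseudo),
    scaling
  )
}
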