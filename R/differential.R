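#' Per-metabolite fold change between two groups
#'
#' FC is the ratio of arithmetic mean abundances, numerator group over
#' denominator group, computed on normalized (pre-log) abundances;
#' log2fc = log2(fc). Metabolites whose denominator-group mean is zero get
#' an undefined-FC flag (NA) and a warning; they are excluded from volcano
#' annotation downstream.
#'
#' @param table a normalized `feature_table`.
#' @param groups factor or character vector of length nrow(table) with
#'   exactly two levels.
#' @param numerator the group forming the FC numerator; default the first
#'   level (the case group by the package's conventions).
#' @return data.frame with columns `metabolite`, `fc`, `log2fc`.
#' @export
fold_change <- function(table, groups, numerator = NULL) {
  stopifnot_state(table, "normalized", "fold_change")
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("fold_change requires exactly two groups")
  if (length(groups) != nrow(table$values)) stop("groups length must match samples")
  if (is.null(numerator)) numerator <- levels(groups)[1]
  if (!numerator %in% levels(groups)) stop("numerator '", numerator, "' not a group level")
  denominator <- setdiff(levels(groups), numerator)
  m1 <- colMeans(table$values[groups == numerator, , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(table$values[groups == denominator, , drop = FALSE], na.rm = TRUE)
  fc <- ifelse(m2 == 0, NA_real_, m1 / m2)
  if (anyNA(fc)) {
    warning(
      "undefined fold change (zero denominator mean) for: ",
      paste(colnames(table$values)[is.na(fc)], collapse = ", ")
    )
  }
  data.frame(
    metabolite = colnames(table$values),
    fc = fc, log2fc = log2(fc),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-metabolite two-sided Welch t-test
#'
#' Welch (unequal-variance) t-test on log-transformed values, the
#' variance-stabilized scale. A metabolite with zero variance in both groups
#' and identical means gets p = 1 by convention and is flagged in attribute
#' `"degenerate"`.
#'
#' @param table a logged `feature_table`.
#' @param groups two-level factor, each level with >= 2 samples.
#' @return named numeric vector of p-values.
#' @export
group_t_test <- function(table, groups) {
  stopifnot_state(table, "logged", "group_t_test")
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("group_t_test requires exactly two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples for a t-test")
  g1 <- groups == levels(groups)[1]
  x <- table$values
  degenerate <- logical(ncol(x))
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[g1, j]; b <- x[!g1, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # no within-group variation: p = 1 by convention when the means agree,
      # 0 in the perfect-separation limit
      if (mean(a) == mean(b)) {
        degenerate[j] <<- TRUE
        return(1)
      }
      return(0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, numeric(1))
  names(p) <- colnames(x)
  attr(p, "degenerate") <- colnames(x)[degenerate]
  p
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' q(i) = min over j >= i of (m * p(j) / j) after ascending sort, mapped
#' back to the input order and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return vector of q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold-change / t-test / FDR differential screen
#'
#' The volcano screen between two groups: fold change on normalized
#' abundances, Welch t-test on log-transformed abundances, BH-FDR across all
#' metabolites in the table, and threshold flags. Reusable for any two-group
#' contrast (case vs control, or the IBS-D vs IBS-C subtype contrast).
#'
#' @param table a `feature_table` in raw or normalized state; raw input is
#'   median-normalized first.
#' @param groups two-level factor over samples.
#' @param numerator FC numerator group; default the first level.
#' @param log2fc_threshold volcano fold-change gate on the log2 scale
#'   (default 1, i.e. FC >= 2 or <= 0.5).
#' @param p_threshold volcano significance gate (default 0.05).
#' @param log_base,pseudo passed to [log_transform()] for the test scale.
#' @return an object of class `differential_result`: a data.frame sorted by
#'   p ascending with columns `metabolite`, `fc`, `log2fc`, `p`, `q`,
#'   `neglog10p`, `passes_fc`, `passes_p`, `highlight`, plus attributes
#'   `log2fc_threshold`, `p_threshold`, `neglog10_p_threshold`, `contrast`.
#' @export
differential_analysis <- function(table, groups, numerator = NULL,
                                  log2fc_threshold = 1, p_threshold = 0.05,
                                  log_base = 10, pseudo = NULL) {
  if (inherits(table, "feature_table") && table$state == "raw") {
    table <- normalize_samples(table)
  }
  stopifnot_state(table, "normalized", "differential_analysis")
  groups <- as.factor(as.character(groups))
  fc <- fold_change(table, groups, numerator)
  logged <- log_transform(table, base = log_base, pseudo = pseudo)
  p <- group_t_test(logged, groups)
  res <- fc
  res$p <- unname(p[res$metabolite])
  res$q <- bh_fdr(res$p)
  res$neglog10p <- -log10(res$p)
  res$passes_fc <- !is.na(res$log2fc) &
    (res$log2fc >= log2fc_threshold | res$log2fc <= -log2fc_threshold)
  res$passes_p <- res$p < p_threshold
  res$highlight <- res$passes_fc & res$passes_p
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  num <- if (is.null(numerator)) levels(groups)[1] else numerator
  structure(
    res,
    class = c("differential_result", "data.frame"),
    log2fc_threshold = log2fc_threshold,
    p_threshold = p_threshold,
    neglog10_p_threshold = -log10(p_threshold),
    contrast = paste(num, "vs", setdiff(levels(groups), num))
  )
}

#' Annotated volcano table
#'
#' Re-annotates a differential result against (possibly new) thresholds and
#' returns the table sorted by p ascending. The -log10 of the p threshold
#' (the volcano's horizontal line) is carried in attribute
#' `"neglog10_p_threshold"` and printed in the header.
#'
#' @param diff a `differential_result`.
#' @param log2fc_threshold,p_threshold volcano gates; default those of
#'   `diff`.
#' @return a data.frame like `diff` with refreshed flags.
#' @export
volcano_table <- function(diff, log2fc_threshold = attr(diff, "log2fc_threshold"),
                          p_threshold = attr(diff, "p_threshold")) {
  stopifnot(inherits(diff, "differential_result"), nrow(diff) > 0)
  out <- as.data.frame(diff)
  out$passes_fc <- !is.na(out$log2fc) &
    (out$log2fc >= log2fc_threshold | out$log2fc <= -log2fc_threshold)
  out$passes_p <- out$p < p_threshold
  out$highlight <- out$passes_fc & out$passes_p
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "log2fc_threshold") <- log2fc_threshold
  attr(out, "p_threshold") <- p_threshold
  attr(out, "neglog10_p_threshold") <- -log10(p_threshold)
  out
}

#' @export
print.differential_result <- function(x, n = 10, ...) {
  cat(sprintf(
    "Differential screen: %s | gates |log2FC| >= %g, p < %g (-log10 = %.2f)\n",
    attr(x, "contrast"), attr(x, "log2fc_threshold"), attr(x, "p_threshold"),
    attr(x, "neglog10_p_threshold")
  ))
  cat(sprintf(
    "%d metabolites, %d highlighted\n\n", nrow(x), sum(x$highlight, na.rm = TRUE)
  ))
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))), ]
  df$fc <- signif(df$fc, 3); df$log2fc <- round(df$log2fc, 2)
  df$p <- signif(df$p, 2); df$q <- signif(df$q, 2)
  df$neglog10p <- round(df$neglog10p, 2)
  print(df, row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.differential_result <- function(object, ...) {
  cat(attr(object, "contrast"), "\n")
  cat("  metabolites:       ", nrow(object), "\n")
  cat("  pass |log2FC| gate:", sum(object$passes_fc, na.rm = TRUE), "\n")
  cat("  pass p gate:       ", sum(object$passes_p, na.rm = TRUE), "\n")
  cat("  highlighted:       ", sum(object$highlight, na.rm = TRUE), "\n")
  cat("  q < 0.05:          ", sum(object$q < 0.05, na.rm = TRUE), "\n")
  invisible(object)
}

#' Volcano plot of a differential screen
#'
#' log2 fold change against -log10 p, with the fold-change gates as vertical
#' lines and the p gate as a horizontal line; point size is proportional to
#' -log10 p, color encodes fold change, and highlighted metabolites are
#' labelled.
#'
#' @param x a `differential_result`.
#' @param label_highlighted label metabolites passing both gates.
#' @param ... passed to [graphics::plot()].
#' @export
plot.differential_result <- function(x, label_highlighted = TRUE, ...) {
  ok <- !is.na(x$log2fc)
  d <- as.data.frame(x)[ok, ]
  pal <- grDevices::colorRampPalette(c("#2166AC", "grey60", "#B2182B"))(101)
  sat <- pmax(pmin(d$log2fc, 2), -2)
  col <- pal[round((sat + 2) / 4 * 100) + 1]
  cex <- 0.5 + d$neglog10p / max(d$neglog10p, 1) * 1.8
  graphics::plot(
    d$log2fc, d$neglog10p, pch = 19, col = col, cex = cex,
    xlab = expression(log[2] ~ "fold change"),
    ylab = expression(-log[10] ~ italic(p)), ...
  )
  graphics::abline(v = c(-1, 1) * attr(x, "log2fc_threshold"), lty = 2, col = "grey40")
  graphics::abline(h = attr(x, "neglog10_p_threshold"), lty = 2, col = "grey40")
  if (label_highlighted && any(d$highlight)) {
    h <- d[d$highlight, ]
    graphics::text(h$log2fc, h$neglog10p, h$metabolite, pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Write a differential result to TSV
#'
#' @param diff a `differential_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(diff, path) {
  utils::write.table(as.data.frame(diff), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
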