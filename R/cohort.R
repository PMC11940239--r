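#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Probability-mass two-sided definition: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of tables no
#' more probable than the observed one. A zero row or column margin gives
#' p = 1 by convention.
#'
#' @param x a 2x2 matrix of non-negative counts, or the four cells `a, b, c,
#'   d` (row-wise) as separate arguments.
#' @param ... cells `b`, `c`, `d` when `x` is the scalar `a`.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(x, ...) {
  if (!is.matrix(x)) {
    cells <- c(x, ...)
    if (length(cells) != 4) stop("supply a 2x2 matrix or four cell counts")
    x <- matrix(cells, 2, 2, byrow = TRUE)
  }
  if (!all(dim(x) == c(2, 2))) stop("fisher_exact requires a 2x2 table")
  if (any(x < 0) || sum(x) == 0) stop("cells must be non-negative with at least one > 0")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) return(1)
  stats::fisher.test(x)$p.value
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration for small samples without ties; normal approximation
#' with tie and continuity correction otherwise.
#'
#' @param x,y nonempty numeric samples.
#' @return the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  suppressWarnings(stats::wilcox.test(x, y, correct = TRUE)$p.value)
}

#' Cohort characteristics table
#'
#' One row per variable: categorical variables are summarized as "N (%)" per
#' group and tested with Fisher's exact test; continuous variables as
#' "Mean (SD)" and tested with the Wilcoxon rank-sum test. A variable with a
#' single level across both groups is reported without a p-value and
#' flagged.
#'
#' @param metadata data.frame with one row per sample; must contain the
#'   grouping column.
#' @param group name of the two-level grouping column (default `"group"`).
#' @param variables variables to summarize; default every column except
#'   `sample_id`, the group column and `subtype`.
#' @return an object of class `cohort_table`: a data.frame with columns
#'   `variable`, `level`, per-group formatted summaries, `p`, `test`,
#'   `flag`.
#' @export
build_cohort_table <- function(metadata, group = "group", variables = NULL) {
  if (!group %in% names(metadata)) stop("grouping column '", group, "' not found")
  g <- as.factor(as.character(metadata[[group]]))
  if (nlevels(g) != 2) stop("cohort table requires exactly two groups")
  if (is.null(variables)) {
    variables <- setdiff(names(metadata), c("sample_id", group, "subtype"))
  }
  if (!length(variables)) stop("no variables to summarize")
  lv <- levels(g)
  rows <- list()
  for (v in variables) {
    col <- metadata[[v]]
    if (is.numeric(col)) {
      x1 <- col[g == lv[1]]; x2 <- col[g == lv[2]]
      p <- wilcoxon_rank_sum(x1, x2)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = "",
        g1 = sprintf("%.1f (%.1f)", mean(x1, na.rm = TRUE), stats::sd(x1, na.rm = TRUE)),
        g2 = sprintf("%.1f (%.1f)", mean(x2, na.rm = TRUE), stats::sd(x2, na.rm = TRUE)),
        p = p, test = "wilcoxon", flag = "", stringsAsFactors = FALSE
      )
    } else {
      f <- as.factor(as.character(col))
      tab <- table(f, g)
      if (nlevels(f) < 2) {
        p <- NA_real_; flag <- "single level; no test"
      } else {
        p <- stats::fisher.test(tab)$p.value
        flag <- ""
      }
      for (k in seq_len(nlevels(f))) {
        n1 <- tab[k, lv[1]]; n2 <- tab[k, lv[2]]
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = levels(f)[k],
          g1 = sprintf("%d (%.0f%%)", n1, 100 * n1 / sum(tab[, lv[1]])),
          g2 = sprintf("%d (%.0f%%)", n2, 100 * n2 / sum(tab[, lv[2]])),
          p = if (k == 1) p else NA_real_,
          test = if (k == 1) "fisher" else "", flag = if (k == 1) flag else "",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(lv, " (N = ", as.integer(table(g)[lv]), ")")
  structure(out, class = c("cohort_table", "data.frame"), groups = lv)
}

#' @export
print.cohort_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$p <- ifelse(is.na(df$p), "", sprintf("%.3f", df$p))
  hdr <- c("Characteristic", "Level", names(df)[3:4], "p")
  w <- pmax(nchar(hdr), apply(df[, c(1:4, 5)], 2, function(c) max(nchar(as.character(c)))))
  fmt <- paste0("%-", w[1], "s  %-", w[2], "s  %-", w[3], "s  %-", w[4], "s  %s\n")
  cat(do.call(sprintf, c(fmt, as.list(hdr))))
  for (i in seq_len(nrow(df))) {
    cat(sprintf(fmt, df$variable[i], df$level[i], df[i, 3], df[i, 4], df$p[i]))
  }
  if (any(nzchar(df$flag))) {
    cat("flags:", paste(unique(df$flag[nzchar(df$flag)]), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a cohort table as TSV and Markdown
#'
#' @param x a `cohort_table`.
#' @param path output TSV path; a Markdown rendering is written alongside
#'   with extension `.md`.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- sub("\\.tsv$", ".md", path)
  if (md == path) md <- paste0(path, ".md")
  pfmt <- ifelse(is.na(df$p), "", sprintf("%.3f", df$p))
  lines <- c(
    paste("| Characteristic | Level |", names(df)[3], "|", names(df)[4], "| p |"),
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s |", df$variable, df$level, df[[3]], df[[4]], pfmt)
  )
  writeLines(lines, md)
  invisible(path)
}
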