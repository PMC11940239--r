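#' Construct a metabolite feature table
#'
#' The central container of the pipeline: a samples-by-metabolites abundance
#' matrix together with a processing-state tag. The state records where the
#' table sits in the preprocessing chain (`raw` -> `normalized` -> `logged`
#' -> `scaled`) and is checked by every downstream operation so that, e.g.,
#' fold changes are never computed on log-scale values by accident.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#'   Row names are sample ids, column names metabolite names; both must be
#'   unique and non-empty.
#' @param state processing state, one of `"raw"`, `"normalized"`, `"logged"`,
#'   `"scaled"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, state = c("raw", "normalized", "logged", "scaled")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x metabolites)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have row names (sample ids) and column names (metabolite names)")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicated sample_id: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop("duplicated metabolite name: ", dup)
  }
  if (state %in% c("raw", "normalized") && any(values < 0, na.rm = TRUE)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative abundance at sample '%s', metabolite '%s' in a %s table",
      rownames(values)[idx[1]], colnames(values)[idx[2]], state
    ))
  }
  structure(
    list(values = values, state = state),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d metabolites, state = %s\n",
    nrow(x$values), ncol(x$values), x$state
  ))
  zv <- attr(x, "zero_variance")
  if (!is.null(zv) && length(zv)) {
    cat("  zero-variance metabolites (centered only):", length(zv), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample ids of a feature table
#' @param x a `feature_table`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' Metabolite names of a feature table
#' @param x a `feature_table`.
#' @return character vector of metabolite names.
#' @export
metabolite_names <- function(x) colnames(x$values)

stopifnot_state <- function(table, expected, op) {
  if (!inherits(table, "feature_table")) {
    stop(op, " expects a feature_table")
  }
  if (!table$state %in% expected) {
    stop(sprintf(
      "%s expects a table in state %s, got '%s'",
      op, paste(sQuote(expected), collapse = " or "), table$state
    ))
  }
  invisible(TRUE)
}

#' Read a feature table from CSV
#'
#' Expects a header row, a first column named `sample_id`, and numeric
#' abundance columns. Duplicate sample ids, non-numeric cells and negative
#' abundances are rejected with the offending row/column named.
#'
#' @param path path to a CSV file.
#' @param state processing state to tag the table with (default `"raw"`).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, state = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty feature table: ", path)
  if (names(df)[1] != "sample_id") {
    stop("first column must be 'sample_id', got '", names(df)[1], "'")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample_id: ", ids[duplicated(ids)][1])
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf(
        "non-numeric cell at row %d, column '%s'",
        if (is.na(bad)) 1L else bad, names(vals)[j]
      ))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  feature_table(m, state = state)
}

#' Write a feature table to CSV
#'
#' Row 1 is the header, column 1 the `sample_id`; abundances are written as
#' decimal floats at full precision so that write-then-read round-trips
#' exactly. The processing state is stored in a YAML sidecar
#' (`<path>.state.yaml`).
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @param sidecar write the state sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sidecar = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  # 17 significant digits round-trip IEEE doubles exactly
  chr <- apply(table$values, 2, function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  })
  chr <- matrix(chr, nrow = nrow(table$values))
  df <- data.frame(
    sample_id = rownames(table$values),
    chr,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  names(df)[-1] <- colnames(table$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    yaml::write_yaml(list(state = table$state), paste0(path, ".state.yaml"))
  }
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' @param path CSV with a `sample_id` column and a `group` column; any other
#'   columns are kept as covariates.
#' @return a data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (need in c("sample_id", "group")) {
    if (!need %in% names(df)) stop("metadata is missing required column '", need, "'")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in metadata: ", df$sample_id[duplicated(df$sample_id)][1])
  }
  df
}
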