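#' Configure an end-to-end pipeline run
#'
#' Collects paths, preprocessing switches, volcano thresholds, the RF
#' configuration, the contrast and the seed for [run_pipeline()].
#'
#' @param feature_table path to a raw feature-table CSV, or a
#'   `feature_table` object.
#' @param metadata path to a metadata CSV, or a data.frame with `sample_id`
#'   and `group` columns (plus `subtype` for the subtype contrast).
#' @param output_dir directory for artifacts (created if needed).
#' @param contrast `"group"` (case vs control) or `"subtype"` (IBS-D vs
#'   IBS-C within cases).
#' @param log2fc_threshold,p_threshold volcano gates.
#' @param normalization,log_base,pseudo,scaling preprocessing switches, see
#'   [preprocess()].
#' @param rf an [rf_config()]; its seed is overridden by `seed`.
#' @param run_rf run the Random Forest validation stage (default `TRUE`; it
#'   dominates the runtime).
#' @param seed master seed for the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_table, metadata, output_dir,
                            contrast = c("group", "subtype"),
                            log2fc_threshold = 1, p_threshold = 0.05,
                            normalization = "median", log_base = 10,
                            pseudo = NULL, scaling = "auto",
                            rf = rf_config(), run_rf = TRUE, seed = 1L) {
  contrast <- match.arg(contrast)
  if (log2fc_threshold <= 0 || p_threshold <= 0) stop("thresholds must be positive")
  structure(
    list(
      feature_table = feature_table, metadata = metadata,
      output_dir = output_dir, contrast = contrast,
      log2fc_threshold = log2fc_threshold, p_threshold = p_threshold,
      normalization = normalization, log_base = log_base,
      pseudo = pseudo, scaling = scaling,
      rf = rf, run_rf = isTRUE(run_rf), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening and validation pipeline
#'
#' Orchestrates preprocess -> differential screen -> Random Forest
#' validation -> cohort table, writing all artifacts plus a run manifest
#' (config, seed, package version, input hashes) to the output directory.
#' Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return named vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  input_hashes <- list()
  table <- pipeline_stage("read", {
    if (inherits(config$feature_table, "feature_table")) {
      config$feature_table
    } else {
      input_hashes$feature_table <- unname(tools::md5sum(config$feature_table))
      read_feature_table(config$feature_table)
    }
  })
  metadata <- pipeline_stage("read", {
    if (is.data.frame(config$metadata)) {
      config$metadata
    } else {
      input_hashes$metadata <- unname(tools::md5sum(config$metadata))
      read_sample_metadata(config$metadata)
    }
  })
  if (!all(rownames(table$values) %in% metadata$sample_id)) {
    stop("pipeline stage 'read' failed: samples missing from metadata")
  }
  metadata <- metadata[match(rownames(table$values), metadata$sample_id), ]

  # resolve the contrast before any computation
  if (config$contrast == "group") {
    groups <- metadata$group
    keep <- rep(TRUE, nrow(metadata))
    numerator <- "case"
    if (!"case" %in% groups) numerator <- sort(unique(groups))[1]
  } else {
    if (is.null(metadata$subtype) || all(is.na(metadata$subtype))) {
      stop("pipeline stage 'contrast' failed: metadata lacks subtype labels")
    }
    keep <- !is.na(metadata$subtype) & metadata$subtype != ""
    groups <- metadata$subtype[keep]
    if (length(unique(groups)) != 2) {
      stop("pipeline stage 'contrast' failed: subtype contrast needs exactly two subtypes")
    }
    numerator <- if ("IBS-D" %in% groups) "IBS-D" else sort(unique(groups))[1]
  }

  sub <- feature_table(table$values[keep, , drop = FALSE], table$state)

  normalized <- pipeline_stage("preprocess", normalize_samples(sub, config$normalization))
  scaled <- pipeline_stage("preprocess", autoscale(
    log_transform(normalized, config$log_base, config$pseudo), config$scaling
  ))

  diff <- pipeline_stage("differential", differential_analysis(
    normalized, groups, numerator = numerator,
    log2fc_threshold = config$log2fc_threshold, p_threshold = config$p_threshold,
    log_base = config$log_base, pseudo = config$pseudo
  ))
  paths <- c(differential = file.path(out, "differential.tsv"))
  write_differential(diff, paths[["differential"]])
  paths["volcano"] <- file.path(out, "volcano.png")
  grDevices::png(paths[["volcano"]], width = 800, height = 700)
  plot(diff)
  grDevices::dev.off()

  if (config$run_rf) {
    rf_cfg <- config$rf
    rf_cfg$seed <- config$seed
    rf <- pipeline_stage("rf_validation", rf_validate(scaled, groups,
      config = rf_cfg, positive = numerator
    ))
    rf_paths <- write_rf_validation(rf, out)
    paths["rf_iterations"] <- rf_paths[["iterations"]]
    paths["rf_importance"] <- rf_paths[["importance"]]
    paths["rf_summary"] <- rf_paths[["summary"]]
    paths["rf_figure"] <- file.path(out, "rf_validation.png")
    grDevices::png(paths[["rf_figure"]], width = 1000, height = 600)
    plot(rf)
    grDevices::dev.off()
  }

  cohort <- pipeline_stage("cohort_stats", build_cohort_table(metadata))
  paths["cohort"] <- file.path(out, "cohort_table.tsv")
  write_cohort_table(cohort, paths[["cohort"]])

  manifest <- list(
    package = "metaboscreen",
    version = as.character(utils::packageVersion("metaboscreen")),
    seed = config$seed, contrast = config$contrast,
    thresholds = list(
      log2fc = config$log2fc_threshold, p = config$p_threshold
    ),
    preprocessing = list(
      normalization = config$normalization, log_base = config$log_base,
      scaling = config$scaling
    ),
    rf = if (config$run_rf) list(
      n_iterations = config$rf$n_iterations, n_bootstrap = config$rf$n_bootstrap,
      train_fraction = config$rf$train_fraction, inner_folds = config$rf$inner_folds
    ) else NULL,
    input_hashes = input_hashes,
    artifacts = as.list(paths)
  )
  paths["manifest"] <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}
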