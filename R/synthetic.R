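#' Define a planted group effect for the synthetic generator
#'
#' A planted effect fixes the true log2 ratio of the case-group mean to the
#' control-group mean for one metabolite. Effects are planted
#' multiplicatively on the natural scale (case mean = control mean x
#' 2^log2fc), so a fold-change analysis recovers `log2fc` exactly in
#' expectation. A `log2fc` of 0 leaves the two groups identically
#' distributed.
#'
#' @param metabolite_name name of the affected metabolite.
#' @param log2fc finite real; log2 of the case/control mean ratio.
#' @param cv within-group coefficient of variation on the natural scale for
#'   this metabolite; `NULL` inherits the spec's `baseline_cv`.
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(metabolite_name, log2fc, cv = NULL) {
  if (!is.character(metabolite_name) || length(metabolite_name) != 1 || !nzchar(metabolite_name)) {
    stop("invalid planted effect: metabolite_name must be a non-empty string")
  }
  if (!is.numeric(log2fc) || length(log2fc) != 1 || !is.finite(log2fc)) {
    stop("invalid planted effect: log2fc must be a finite number")
  }
  if (!is.null(cv) && (!is.numeric(cv) || length(cv) != 1 || cv <= 0)) {
    stop("invalid planted effect: cv must be > 0")
  }
  structure(
    list(metabolite_name = metabolite_name, log2fc = log2fc, cv = cv),
    class = "planted_effect"
  )
}

#' Specify a synthetic case-control metabolomics dataset
#'
#' Full parameterization of the generator: dimensions, the baseline
#' log-normal abundance model, planted group effects, covariate marginals
#' and the seed. Identical spec + identical seed gives bit-identical output.
#'
#' Baseline model: each metabolite gets a natural-log location drawn once
#' uniformly from `baseline_log_mean_range`; within-group abundances are
#' log-normal with that location and a log-scale SD implied by
#' `baseline_cv` (sdlog = sqrt(log(1 + cv^2))). Features are independent by
#' default; setting `block_size > 1` with `rho > 0` imposes equicorrelated
#' log-scale blocks.
#'
#' @param n_case,n_control group sizes; their sum must be at least 4.
#' @param n_features number of metabolites (>= number of planted effects).
#' @param baseline_log_mean_range length-2 numeric, natural-log abundance
#'   location range. Default spans typical LC-MS intensities (1e4 to 1e6).
#' @param baseline_cv within-group coefficient of variation on the natural
#'   scale, shared by all metabolites without their own `cv`.
#' @param effects list of [planted_effect()] objects; names must be unique.
#' @param covariate_marginals per-covariate, per-group distribution
#'   summaries, as returned by [cohort_marginals()]; `NULL` for none.
#' @param missing_rate probability that an abundance cell is set missing
#'   (missing at random); default 0.
#' @param block_size,rho optional equicorrelation structure (defaults off).
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_case, n_control, n_features,
                           baseline_log_mean_range = log(c(1e4, 1e6)),
                           baseline_cv = 1.0,
                           effects = list(),
                           covariate_marginals = NULL,
                           missing_rate = 0,
                           block_size = 1L, rho = 0,
                           seed = 1L) {
  if (n_case < 1 || n_control < 1 || n_case + n_control < 4) {
    stop("invalid spec: n_case + n_control must be >= 4 with both groups non-empty")
  }
  if (n_features < max(1L, length(effects))) {
    stop("invalid spec: n_features must be >= max(1, number of effects)")
  }
  if (length(baseline_log_mean_range) != 2 ||
      baseline_log_mean_range[2] < baseline_log_mean_range[1]) {
    stop("invalid spec: baseline_log_mean_range must be an increasing length-2 interval")
  }
  if (baseline_cv <= 0) stop("invalid spec: baseline_cv must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid spec: missing_rate must be in [0,1)")
  if (length(effects)) {
    ok <- vapply(effects, inherits, logical(1), what = "planted_effect")
    if (!all(ok)) stop("invalid spec: effects must be planted_effect objects")
    nm <- vapply(effects, function(e) e$metabolite_name, character(1))
    if (anyDuplicated(nm)) stop("invalid spec: duplicated effect metabolite name '", nm[duplicated(nm)][1], "'")
  }
  structure(
    list(
      n_case = as.integer(n_case), n_control = as.integer(n_control),
      n_features = as.integer(n_features),
      baseline_log_mean_range = as.numeric(baseline_log_mean_range),
      baseline_cv = baseline_cv, effects = effects,
      covariate_marginals = covariate_marginals,
      missing_rate = missing_rate,
      block_size = as.integer(block_size), rho = rho,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Per-group covariate marginals of the study cohort
#'
#' Default demographic and clinical marginals of the emulated cohort: 44
#' cases and 69 controls; sex, age, body mass, height, BMI, diabetes and
#' hypertension with the published group summaries. Each element is either
#' `list(type = "binary", prop = c(case, control))` (probability of the
#' first level) or `list(type = "continuous", mean = c(case, control),
#' sd = c(case, control))`.
#'
#' @return a named list of marginal definitions.
#' @export
cohort_marginals <- function() {
  list(
    sex = list(type = "binary", levels = c("female", "male"),
               prop = c(case = 30 / 44, control = 38 / 69)),
    age = list(type = "continuous", mean = c(case = 52, control = 59),
               sd = c(case = 16, control = 13)),
    body_mass = list(type = "continuous", mean = c(case = 77, control = 77),
                     sd = c(case = 18, control = 15)),
    height = list(type = "continuous", mean = c(case = 168, control = 168),
                  sd = c(case = 10, control = 13)),
    bmi = list(type = "continuous", mean = c(case = 27.0, control = 27.7),
               sd = c(case = 5.4, control = 8.5)),
    dm = list(type = "binary", levels = c("yes", "no"),
              prop = c(case = 7 / 44, control = 9 / 69)),
    hypertension = list(type = "binary", levels = c("yes", "no"),
                        prop = c(case = 14 / 44, control = 32 / 69))
  )
}

#' Synthetic spec emulating the IBS mucosal-metabolome study design
#'
#' 44 cases vs 69 controls, 300 log-normal metabolites, and four planted
#' effects mirroring the study's reported discriminators: an
#' N-acetylneuraminic-acid-like feature (log2FC 1.63), a
#' 1-palmitoylglycerol-like feature (1.08), a
#' cis-4-hydroxycyclohexanecarboxylic-acid-like feature (-1.52), and a
#' glycine-like small-but-significant feature (0.6, below the volcano
#' fold-change gate). Covariates follow [cohort_marginals()].
#'
#' @param seed integer seed.
#' @param n_features number of metabolites (default 300).
#' @param effects planted effects; defaults as above.
#' @param ... passed through to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
ibs_study_spec <- function(seed = 1L, n_features = 300L,
                           effects = list(
                             planted_effect("Neu5Ac", 1.63),
                             planted_effect("1-palmitoylglycerol", 1.08),
                             planted_effect("cis-4-hydroxycyclohexanecarboxylic acid", -1.52),
                             planted_effect("glycine", 0.60)
                           ),
                           ...) {
  synthetic_spec(
    n_case = 44L, n_control = 69L, n_features = n_features,
    effects = effects, covariate_marginals = cohort_marginals(),
    seed = seed, ...
  )
}

#' Generate a synthetic feature table and matching metadata
#'
#' Draws a strictly positive (n_case + n_control) x n_features abundance
#' matrix under the spec's log-normal model, planting each effect so the
#' case-group mean equals the control-group mean times 2^log2fc, and a
#' metadata table with group labels (cases first), IBS-C/IBS-D subtypes
#' among cases, and covariates drawn from the spec's marginals.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `table` (a raw `feature_table`), `metadata`
#'   (data.frame) and `spec`.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_case + spec$n_control
  m <- spec$n_features
  group <- rep(c("case", "control"), c(spec$n_case, spec$n_control))

  feat_names <- paste0("M", sprintf("%03d", seq_len(m)))
  eff_names <- vapply(spec$effects, function(e) e$metabolite_name, character(1))
  # planted effects occupy the first columns under their own names
  if (length(eff_names)) feat_names[seq_along(eff_names)] <- eff_names

  mu <- stats::runif(m, spec$baseline_log_mean_range[1], spec$baseline_log_mean_range[2])
  sdlog <- rep(sqrt(log(1 + spec$baseline_cv^2)), m)
  shift <- numeric(m)
  for (k in seq_along(spec$effects)) {
    e <- spec$effects[[k]]
    shift[k] <- e$log2fc * log(2)
    if (!is.null(e$cv)) sdlog[k] <- sqrt(log(1 + e$cv^2))
  }

  z <- matrix(stats::rnorm(n * m), n, m)
  if (spec$block_size > 1 && spec$rho > 0) {
    # equicorrelated blocks on the log scale: z = sqrt(rho)*u_block + sqrt(1-rho)*z
    blocks <- rep(seq_len(ceiling(m / spec$block_size)), each = spec$block_size)[seq_len(m)]
    u <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
    z <- sqrt(spec$rho) * u[, blocks, drop = FALSE] + sqrt(1 - spec$rho) * z
  }
  logx <- sweep(z, 2, sdlog, `*`)
  logx <- sweep(logx, 2, mu, `+`)
  logx[group == "case", ] <- sweep(logx[group == "case", , drop = FALSE], 2, shift, `+`)
  x <- exp(logx)
  if (spec$missing_rate > 0) {
    x[stats::runif(length(x)) < spec$missing_rate] <- NA_real_
  }
  dimnames(x) <- list(sprintf("S%03d", seq_len(n)), feat_names)

  metadata <- data.frame(
    sample_id = rownames(x), group = group,
    stringsAsFactors = FALSE
  )
  metadata$subtype <- NA_character_
  metadata$subtype[group == "case"] <-
    rep_len(c("IBS-C", "IBS-D"), spec$n_case)[sample.int(spec$n_case)]
  if (!is.null(spec$covariate_marginals)) {
    cov <- draw_covariates(spec$covariate_marginals, group)
    metadata <- cbind(metadata, cov, stringsAsFactors = FALSE)
  }
  list(table = feature_table(x, "raw"), metadata = metadata, spec = spec)
}

draw_covariates <- function(marginals, group) {
  n <- length(group)
  is_case <- group == "case"
  out <- list()
  for (v in names(marginals)) {
    mg <- marginals[[v]]
    if (is.null(mg$type)) stop("missing marginal definition for variable '", v, "'")
    if (mg$type == "binary") {
      if (is.null(mg$prop) || length(mg$prop) != 2) {
        stop("missing marginal: binary variable '", v, "' needs per-group prop")
      }
      levels <- if (!is.null(mg$levels)) mg$levels else c("yes", "no")
      p <- ifelse(is_case, mg$prop[[1]], mg$prop[[2]])
      out[[v]] <- ifelse(stats::runif(n) < p, levels[1], levels[2])
    } else if (mg$type == "continuous") {
      if (is.null(mg$mean) || is.null(mg$sd)) {
        stop("missing marginal: continuous variable '", v, "' needs mean and sd")
      }
      mu <- ifelse(is_case, mg$mean[[1]], mg$mean[[2]])
      sd <- ifelse(is_case, mg$sd[[1]], mg$sd[[2]])
      out[[v]] <- stats::rnorm(n, mu, sd)
    } else {
      stop("unknown marginal type '", mg$type, "' for variable '", v, "'")
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate cohort metadata alone
#'
#' Draws a metadata table (group labels plus covariates) from per-group
#' marginals without generating abundances; used to exercise the cohort
#' characteristics table on its own.
#'
#' @param marginals per-covariate marginals, see [cohort_marginals()].
#' @param n_case,n_control group sizes.
#' @param seed integer seed.
#' @return a data.frame with one row per sample.
#' @export
generate_cohort_metadata <- function(marginals, n_case = 44L, n_control = 69L, seed = 1L) {
  set.seed(seed)
  group <- rep(c("case", "control"), c(n_case, n_control))
  md <- data.frame(
    sample_id = sprintf("S%03d", seq_along(group)), group = group,
    stringsAsFactors = FALSE
  )
  cbind(md, draw_covariates(marginals, group), stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Feature table and metadata as CSV; the generating spec as YAML alongside
#' for provenance.
#'
#' @param sim output of [generate_feature_table()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ft <- file.path(dir, "feature_table.csv")
  md <- file.path(dir, "metadata.csv")
  sp <- file.path(dir, "synthetic_spec.yaml")
  write_feature_table(sim$table, ft, sidecar = FALSE)
  utils::write.csv(sim$metadata, md, row.names = FALSE, quote = FALSE)
  spec <- sim$spec
  spec$effects <- lapply(spec$effects, unclass)
  yaml::write_yaml(unclass(spec), sp)
  invisible(c(feature_table = ft, metadata = md, spec = sp))
}
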