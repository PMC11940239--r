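#' Hyperparameter grid for the Random Forest search
#'
#' Four axes: the number of features sampled at each split (mtry), the
#' number of trees, the maximum tree depth (0 = unlimited) and the minimum
#' number of samples per leaf.
#'
#' @param features_per_split,n_trees,max_depth,min_leaf numeric vectors,
#'   each nonempty; `max_depth` may contain 0 for unlimited, all other
#'   values must be positive.
#' @return an object of class `rf_grid`.
#' @export
rf_grid <- function(features_per_split, n_trees, max_depth, min_leaf) {
  axes <- list(
    features_per_split = features_per_split, n_trees = n_trees,
    max_depth = max_depth, min_leaf = min_leaf
  )
  for (a in names(axes)) {
    v <- axes[[a]]
    if (!length(v)) stop("empty grid axis: ", a)
    lo <- if (a == "max_depth") 0 else 1
    if (any(v < lo)) stop("grid axis ", a, " must have values >= ", lo)
  }
  structure(lapply(axes, as.integer), class = "rf_grid")
}

#' Default hyperparameter grid
#'
#' mtry in {ceil(sqrt(m)), ceil(m/3)}, 250 or 500 trees, unlimited or
#' depth-8 trees, and leaves of at least 1 or 5 samples — 16 grid points
#' spanning the four tuned hyperparameters at desk scale.
#'
#' @param n_features number of predictors m.
#' @return an `rf_grid`.
#' @export
default_rf_grid <- function(n_features) {
  rf_grid(
    features_per_split = unique(c(ceiling(sqrt(n_features)), ceiling(n_features / 3))),
    n_trees = c(250L, 500L),
    max_depth = c(0L, 8L),
    min_leaf = c(1L, 5L)
  )
}

grid_points <- function(grid) {
  expand.grid(
    features_per_split = grid$features_per_split,
    n_trees = grid$n_trees,
    max_depth = grid$max_depth,
    min_leaf = grid$min_leaf,
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Configuration of the repeated nested cross-validation run
#'
#' @param train_fraction fraction of samples in the outer training split
#'   (default 0.7, i.e. a 70/30 split).
#' @param inner_folds folds of the inner hyperparameter-selection CV
#'   (default 2).
#' @param n_iterations outer repetitions (default 100).
#' @param n_bootstrap bootstrap resamples for the 95% CIs (default 1000).
#' @param grid an [rf_grid()]; `NULL` uses [default_rf_grid()] sized to the
#'   data at fit time.
#' @param level confidence level of the bootstrap intervals (default 0.95).
#' @param seed master seed; every stream of the run derives from it.
#' @return an object of class `rf_config`.
#' @export
rf_config <- function(train_fraction = 0.7, inner_folds = 2L,
                      n_iterations = 100L, n_bootstrap = 1000L,
                      grid = NULL, level = 0.95, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction must be in (0, 1)")
  if (inner_folds < 2) stop("inner_folds must be >= 2")
  if (n_iterations < 1 || n_bootstrap < 1) stop("n_iterations and n_bootstrap must be >= 1")
  if (!is.null(grid) && !inherits(grid, "rf_grid")) stop("grid must be an rf_grid")
  structure(
    list(
      train_fraction = train_fraction, inner_folds = as.integer(inner_folds),
      n_iterations = as.integer(n_iterations), n_bootstrap = as.integer(n_bootstrap),
      grid = grid, level = level, seed = as.integer(seed)
    ),
    class = "rf_config"
  )
}

#' Stratified train/test split
#'
#' Per class, `round(train_fraction * class size)` samples go to training;
#' the rest to test. Errors if either partition would lose a class. Uses the
#' current RNG state.
#'
#' @param labels two-class label vector.
#' @param train_fraction fraction of each class allocated to training.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2) stop("stratified_split requires exactly two classes")
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    k <- round(train_fraction * length(idx))
    if (k < 1 || k >= length(idx)) {
      stop("class '", lv, "' too small to appear in both partitions at fraction ",
           train_fraction)
    }
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Stratified fold assignment; refolds (new RNG draws) until every fold holds
# both classes, max 10 attempts.
stratified_folds <- function(labels, k) {
  for (attempt in 1:10) {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[fold == f])) == 2 &&
        length(unique(labels[fold != f])) == 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("degenerate inner folds: a fold is single-class after 10 refold attempts")
}

# Minimal forest contract: any learner exposing these two calls can stand in.
fit_forest <- function(x, y, params, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  ranger::ranger(
    x = x, y = as.factor(y), probability = TRUE,
    num.trees = params$n_trees,
    mtry = min(params$features_per_split, ncol(x)),
    max.depth = params$max_depth,
    min.node.size = params$min_leaf,
    seed = seed, num.threads = 1, verbose = FALSE
  )
}

predict_forest_scores <- function(model, x, positive) {
  p <- stats::predict(model, data = x, num.threads = 1, verbose = FALSE)$predictions
  p[, positive]
}

#' Inner-CV grid search for Random Forest hyperparameters
#'
#' Evaluates every grid point by mean validation AUC over `inner_folds`
#' stratified folds of the training data and returns the maximizer. Ties are
#' broken toward the simpler model: fewer trees, shallower depth (unlimited
#' counts as deepest), larger minimum leaf, smaller mtry, then first-in-grid
#' order. Uses the current RNG state.
#'
#' @param x training matrix (samples x features).
#' @param y training labels (two classes).
#' @param grid an [rf_grid()].
#' @param inner_folds number of stratified folds (default 2).
#' @param positive label treated as positive for the AUC.
#' @return one-row data.frame: the chosen grid point plus its `mean_auc`.
#' @export
grid_search <- function(x, y, grid, inner_folds = 2L, positive = levels(as.factor(y))[1]) {
  y <- as.factor(as.character(y))
  pts <- grid_points(grid)
  fold <- stratified_folds(as.character(y), inner_folds)
  fit_seeds <- matrix(
    sample.int(.Machine$integer.max, nrow(pts) * inner_folds),
    nrow(pts), inner_folds
  )
  auc <- matrix(NA_real_, nrow(pts), inner_folds)
  for (f in seq_len(inner_folds)) {
    xtr <- x[fold != f, , drop = FALSE]; ytr <- y[fold != f]
    xva <- x[fold == f, , drop = FALSE]; yva <- y[fold == f]
    for (g in seq_len(nrow(pts))) {
      fit <- fit_forest(xtr, ytr, pts[g, ], seed = fit_seeds[g, f])
      auc[g, f] <- compute_auc(predict_forest_scores(fit, xva, positive), yva, positive)
    }
  }
  mean_auc <- rowMeans(auc)
  depth_key <- ifelse(pts$max_depth == 0, Inf, pts$max_depth)
  ord <- order(
    -mean_auc, pts$n_trees, depth_key, -pts$min_leaf,
    pts$features_per_split, seq_len(nrow(pts))
  )
  best <- pts[ord[1], , drop = FALSE]
  best$mean_auc <- mean_auc[ord[1]]
  rownames(best) <- NULL
  best
}

#' Y-scramble class labels
#'
#' Returns a uniform random permutation of the label multiset: class counts
#' are preserved, any association with the predictors is destroyed. Uses the
#' current RNG state.
#'
#' @param labels label vector of length >= 2.
#' @return permuted labels.
#' @export
scramble_labels <- function(labels) {
  if (length(labels) < 2) stop("need at least 2 labels to scramble")
  labels[sample.int(length(labels))]
}

#' Permutation 1-AUC feature importance
#'
#' For each feature, permutes that column of the test data (one independent
#' draw per feature, all other columns untouched), re-scores the fitted
#' model, and records 1 - AUC. A feature the model relies on loses rank
#' information under permutation, so its permuted 1-AUC rises above the
#' unpermuted baseline. Uses the current RNG state.
#'
#' @param model a fitted forest (from the internal forest contract).
#' @param x_test test matrix.
#' @param y_test test labels (both classes present).
#' @param positive positive-class label.
#' @return list with `baseline_1auc` (unpermuted) and `per_feature`, a named
#'   vector of permuted 1-AUC values covering every feature exactly once.
#' @export
permutation_importance <- function(model, x_test, y_test, positive) {
  m <- ncol(x_test); n <- nrow(x_test)
  baseline <- 1 - compute_auc(predict_forest_scores(model, x_test, positive), y_test, positive)
  # one stacked prediction over all per-feature permuted copies
  stacked <- x_test[rep(seq_len(n), m), , drop = FALSE]
  for (j in seq_len(m)) {
    rows <- (j - 1L) * n + seq_len(n)
    stacked[rows, j] <- x_test[sample.int(n), j]
  }
  scores <- predict_forest_scores(model, stacked, positive)
  per_feature <- vapply(seq_len(m), function(j) {
    1 - compute_auc(scores[(j - 1L) * n + seq_len(n)], y_test, positive)
  }, numeric(1))
  names(per_feature) <- colnames(x_test)
  list(baseline_1auc = baseline, per_feature = per_feature)
}

#' Repeated nested-CV Random Forest validation with a Y-scrambled null arm
#'
#' The full validation scaffold. Each of `n_iterations` repetitions draws a
#' fresh stratified 70/30 split and runs two arms through an identical
#' procedure: the real arm trains on the true labels; the scrambled arm
#' first permutes the training labels (test labels stay intact). Per arm and
#' iteration: inner-CV grid search on the training data, a forest fit at the
#' chosen point, the test-set AUC from predicted case probabilities, and
#' permutation 1-AUC importance for every feature. Medians over iterations
#' are summarized with percentile bootstrap confidence intervals; a feature
#' is called significant when its permuted 1-AUC interval does not overlap
#' the unpermuted baseline interval of the same arm.
#'
#' @param table a scaled `feature_table` (or numeric matrix with dimnames).
#' @param labels two-class label vector over samples.
#' @param config an [rf_config()].
#' @param positive positive-class (case) label; default the first factor
#'   level.
#' @return an object of class `rf_validation` with elements `iterations`
#'   (per-iteration, per-arm hyperparameters and test AUC), `importance`
#'   (per-feature, per-arm median 1-AUC, CI, significance and real-arm
#'   rank), `auc_summary`, `baseline`, `config`, `positive`.
#' @export
rf_validate <- function(table, labels, config = rf_config(), positive = NULL) {
  if (inherits(table, "feature_table")) {
    stopifnot_state(table, "scaled", "rf_validate")
    x <- table$values
  } else {
    x <- as.matrix(table)
  }
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2) stop("rf_validate requires exactly two classes")
  if (length(labels) != nrow(x)) stop("labels length must match samples")
  if (is.null(positive)) positive <- levels(labels)[1]
  grid <- if (is.null(config$grid)) default_rf_grid(ncol(x)) else config$grid
  min_class_train <- round(config$train_fraction * min(table(labels)))
  if (min_class_train < config$inner_folds) {
    stop("train_fraction leaves fewer training samples per class than inner_folds")
  }

  n_iter <- config$n_iterations
  m <- ncol(x)
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max, n_iter * 8), n_iter, 8)
  boot_seed <- sample.int(.Machine$integer.max, 1)

  arms <- c("real", "scrambled")
  auc <- matrix(NA_real_, n_iter, 2, dimnames = list(NULL, arms))
  imp <- array(NA_real_, c(n_iter, m, 2), dimnames = list(NULL, colnames(x), arms))
  iter_rows <- vector("list", n_iter * 2)

  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      set.seed(seeds[i, 1])
      sp <- stratified_split(labels, config$train_fraction)
      xtr <- x[sp$train, , drop = FALSE]; xte <- x[sp$test, , drop = FALSE]
      ytr <- labels[sp$train]; yte <- labels[sp$test]
      set.seed(seeds[i, 2])
      ytr_s <- scramble_labels(ytr)
      out <- list()
      for (a in 1:2) {
        ya <- if (a == 1) ytr else ytr_s
        set.seed(seeds[i, 2 + a])
        best <- grid_search(xtr, ya, grid, config$inner_folds, positive)
        set.seed(seeds[i, 4 + a])
        fit <- fit_forest(xtr, ya, best, seed = sample.int(.Machine$integer.max, 1))
        a_auc <- compute_auc(predict_forest_scores(fit, xte, positive), yte, positive)
        set.seed(seeds[i, 6 + a])
        pi <- permutation_importance(fit, xte, yte, positive)
        out[[a]] <- list(best = best, auc = a_auc, imp = pi$per_feature)
      }
      out
    }, error = function(e) {
      stop("iteration ", i, " failed: ", conditionMessage(e), call. = FALSE)
    })
    for (a in 1:2) {
      auc[i, a] <- res[[a]]$auc
      imp[i, , a] <- res[[a]]$imp
      b <- res[[a]]$best
      iter_rows[[(i - 1) * 2 + a]] <- data.frame(
        iteration = i, arm = arms[a],
        features_per_split = b$features_per_split, n_trees = b$n_trees,
        max_depth = b$max_depth, min_leaf = b$min_leaf,
        inner_mean_auc = b$mean_auc, test_auc = res[[a]]$auc,
        stringsAsFactors = FALSE
      )
    }
  }

  set.seed(boot_seed)
  auc_summary <- do.call(rbind, lapply(1:2, function(a) {
    ci <- bootstrap_ci(auc[, a], config$n_bootstrap, config$level)
    data.frame(
      arm = arms[a], median_auc = stats::median(auc[, a]),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      stringsAsFactors = FALSE
    )
  }))
  baseline <- do.call(rbind, lapply(1:2, function(a) {
    ci <- bootstrap_ci(1 - auc[, a], config$n_bootstrap, config$level)
    data.frame(
      arm = arms[a], median_1auc = stats::median(1 - auc[, a]),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      stringsAsFactors = FALSE
    )
  }))
  importance <- do.call(rbind, lapply(1:2, function(a) {
    imp_a <- matrix(imp[, , a], nrow = n_iter, ncol = m)
    cis <- bootstrap_ci_matrix(imp_a, config$n_bootstrap, config$level)
    med <- apply(imp_a, 2, stats::median)
    base <- baseline[baseline$arm == arms[a], ]
    data.frame(
      feature = colnames(x), arm = arms[a],
      median_1auc = unname(med), ci_lower = cis[1, ], ci_upper = cis[2, ],
      significant = cis[1, ] > base$ci_upper | cis[2, ] < base$ci_lower,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  real_imp <- importance[importance$arm == "real", ]
  rank_map <- stats::setNames(
    rank(-real_imp$median_1auc, ties.method = "first"), real_imp$feature
  )
  importance$rank <- unname(rank_map[importance$feature])

  structure(
    list(
      iterations = do.call(rbind, iter_rows),
      auc = auc, importance = importance,
      auc_summary = auc_summary, baseline = baseline,
      config = config, grid = grid, positive = positive
    ),
    class = "rf_validation"
  )
}

#' @export
print.rf_validation <- function(x, ...) {
  cat(sprintf(
    "Random Forest validation: %d iterations, %.0f/%.0f split, %d-fold inner CV\n",
    x$config$n_iterations, 100 * x$config$train_fraction,
    100 * (1 - x$config$train_fraction), x$config$inner_folds
  ))
  s <- x$auc_summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-9s median AUC %.2f (95%% CI %.2f-%.2f)\n",
      s$arm[i], s$median_auc[i], s$ci_lower[i], s$ci_upper[i]
    ))
  }
  nsig <- sum(x$importance$significant[x$importance$arm == "real"])
  cat("  significant features (real arm):", nsig, "\n")
  invisible(x)
}

#' @export
summary.rf_validation <- function(object, n_top = 10, ...) {
  print(object)
  real <- object$importance[object$importance$arm == "real", ]
  real <- real[order(real$rank), ]
  top <- utils::head(real, n_top)
  cat("\nTop features by median permuted 1-AUC (real arm):\n")
  top$median_1auc <- round(top$median_1auc, 3)
  top$ci_lower <- round(top$ci_lower, 3); top$ci_upper <- round(top$ci_upper, 3)
  print(top[, c("rank", "feature", "median_1auc", "ci_lower", "ci_upper", "significant")],
        row.names = FALSE)
  invisible(object)
}

#' Plot an RF validation result
#'
#' Two panels: (A) the distribution of test AUCs per arm with the bootstrap
#' CI of the median; (B) the top features ranked by real-arm median permuted
#' 1-AUC, with bootstrap CIs for both arms and the real-arm baseline band.
#'
#' @param x an `rf_validation`.
#' @param n_top number of features in panel B (default 10).
#' @param ... ignored.
#' @export
plot.rf_validation <- function(x, n_top = 10, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 8, 3, 1))
  on.exit(graphics::par(op))
  graphics::boxplot(
    x$auc[, "real"], x$auc[, "scrambled"], names = c("Y-real", "Y-scrambled"),
    ylab = "test AUC", main = "A. Model performance", ylim = c(0, 1)
  )
  graphics::abline(h = 0.5, lty = 3)
  real <- x$importance[x$importance$arm == "real", ]
  real <- real[order(real$rank), ]
  top <- utils::head(real, n_top)
  scram <- x$importance[x$importance$arm == "scrambled", ]
  scram <- scram[match(top$feature, scram$feature), ]
  ypos <- rev(seq_len(nrow(top)))
  graphics::plot(
    top$median_1auc, ypos, xlim = range(0, 1, top$ci_lower, top$ci_upper),
    pch = 19, col = "#B2182B", yaxt = "n", ylab = "",
    xlab = "permuted 1-AUC", main = "B. Feature importance"
  )
  graphics::axis(2, at = ypos, labels = top$feature, las = 1, cex.axis = 0.7)
  graphics::segments(top$ci_lower, ypos, top$ci_upper, ypos, col = "#B2182B")
  graphics::points(scram$median_1auc, ypos - 0.25, pch = 19, col = "#2166AC")
  graphics::segments(scram$ci_lower, ypos - 0.25, scram$ci_upper, ypos - 0.25, col = "#2166AC")
  base <- x$baseline[x$baseline$arm == "real", ]
  graphics::rect(base$ci_lower, 0, base$ci_upper, nrow(top) + 1,
                 col = grDevices::adjustcolor("grey50", 0.25), border = NA)
  graphics::legend("bottomright", legend = c("Y-real", "Y-scrambled", "baseline CI"),
                   col = c("#B2182B", "#2166AC", "grey60"), pch = c(19, 19, 15), cex = 0.7)
  invisible(x)
}

#' Write RF validation artifacts
#'
#' Iterations and importance tables as TSV, the AUC/baseline summaries as
#' YAML.
#'
#' @param result an `rf_validation`.
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_rf_validation <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  it <- file.path(dir, "rf_iterations.tsv")
  im <- file.path(dir, "rf_importance.tsv")
  sm <- file.path(dir, "rf_summary.yaml")
  utils::write.table(result$iterations, it, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$importance, im, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    auc_summary = result$auc_summary, baseline = result$baseline,
    config = list(
      train_fraction = result$config$train_fraction,
      inner_folds = result$config$inner_folds,
      n_iterations = result$config$n_iterations,
      n_bootstrap = result$config$n_bootstrap,
      seed = result$config$seed
    ),
    positive = result$positive
  ), sm)
  invisible(c(iterations = it, importance = im, summary = sm))
}
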