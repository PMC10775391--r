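# Train/test splitting, cross-validated gradient-boosting fits,
# minimal-feature selection and adaptive hyperparameter search.

#' Stratified train/test split
#'
#' Indices are partitioned so that outcome proportions match across splits
#' within one individual (largest-remainder per class). Deterministic given
#' the seed.
#'
#' @param y outcome vector (classes for classification; continuous outcomes
#'   are binned internally for stratification)
#' @param ratio training fraction
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
split_train_test <- function(y, ratio = 0.8, seed = 1L) {
  if (!length(y)) stopf("split_train_test: empty cohort")
  strat <- y
  if (is.numeric(strat) && length(unique(strat)) > 10) {
    br <- unique(stats::quantile(strat, seq(0, 1, length.out = 6), na.rm = TRUE))
    strat <- cut(strat, br, include.lowest = TRUE)
  }
  strat <- as.factor(strat)
  if (any(table(strat) < 2))
    stopf("split_train_test: a class has fewer than 2 members")
  rs <- restore_seed(seed); on.exit(rs())
  train <- integer(0)
  for (lv in levels(strat)) {
    idx <- which(strat == lv)
    n_tr <- round(length(idx) * ratio)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# Default xgboost parameters per task; class weights are attached separately.
base_xgb_params <- function(task) {
  common <- list(eta = 0.15, max_depth = 3, min_child_weight = 5,
                 subsample = 0.9, colsample_bytree = 0.9, lambda = 1,
                 nthread = 1)
  if (task == "classification")
    c(common, list(objective = "binary:logistic", eval_metric = "logloss"))
  else
    c(common, list(objective = "reg:squarederror", eval_metric = "rmse"))
}

# Fit one booster. Classification rows are weighted by inverse class
# frequency ("sample weights ... to account for case-control class
# imbalance").
fit_xgb <- function(X, y, task, params = NULL, nrounds = 80, seed = 1L) {
  params <- utils::modifyList(base_xgb_params(task), params %||% list())
  params$seed <- as.integer(seed %% .Machine$integer.max)
  w <- NULL
  if (task == "classification") {
    tab <- table(factor(y, levels = c(0, 1)))
    w <- as.numeric(length(y) / (2 * tab[as.character(y)]))
  }
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y, weight = w)
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds,
                     verbose = 0)
}

predict_xgb <- function(booster, X) {
  stats::predict(booster, xgboost::xgb.DMatrix(as.matrix(X)))
}

# Held-out metric used during CV and selection.
holdout_metric <- function(metric, y, p) {
  switch(metric,
         auroc = auroc_point(as.integer(y), p),
         f1 = confusion_at(y, p, 0.5)$f1,
         r2 = 1 - sum((y - p)^2) / sum((y - mean(y))^2),
         rmse = -sqrt(mean((y - p)^2)),
         stopf("unknown metric '%s'", metric))
}

default_metric <- function(task)
  if (task == "classification") "f1" else "r2"

# k-fold CV of one parameter setting; returns per-fold metrics.
cv_fold_metrics <- function(X, y, task, params, nrounds, folds, metric, seed,
                            max_folds = NULL) {
  ks <- sort(unique(folds))
  if (!is.null(max_folds)) ks <- ks[seq_len(max_folds)]
  vapply(ks, function(k) {
    tr <- folds != k
    fit <- fit_xgb(X[tr, , drop = FALSE], y[tr], task, params, nrounds,
                   seed = seed + k)
    holdout_metric(metric, y[!tr], predict_xgb(fit, X[!tr, , drop = FALSE]))
  }, numeric(1))
}

#' Minimal-model feature selection over a grid of feature-count bounds
#'
#' For each bound `b` in the ascending grid, fits and cross-validates a model
#' on the top-`b` ranked candidate features, then returns the smallest bound
#' whose CV metric is within `tolerance` of the best bound's metric.
#'
#' @param X numeric feature matrix (training rows)
#' @param y outcome
#' @param candidates feature names ranked by importance (from
#'   [preselect_top_k()])
#' @param bounds_grid ascending feature-count bounds
#' @param tolerance allowed CV-metric shortfall from the best bound (default
#'   0.005 for classification AUROC, 0.01 for regression R^2)
#' @param task "classification" or "regression"
#' @param params,nrounds booster settings
#' @param cv_folds number of folds
#' @param metric CV metric ("auroc" or "r2" by default)
#' @param seed integer seed
#' @return list: `features` (selected ranked list), `bound`, `metrics`
#'   (per-bound CV means)
#' @export
select_minimal_features <- function(X, y, candidates,
                                    bounds_grid = c(10, 20, 40, 60, 80, 100, 200),
                                    tolerance = NULL,
                                    task = "classification",
                                    params = NULL, nrounds = 60,
                                    cv_folds = 3, metric = NULL, seed = 1L) {
  if (!length(bounds_grid)) stopf("select_minimal_features: empty bounds grid")
  bounds_grid <- sort(unique(pmin(bounds_grid, length(candidates))))
  metric <- metric %||% (if (task == "classification") "auroc" else "r2")
  tolerance <- tolerance %||% (if (task == "classification") 0.005 else 0.01)
  folds <- stratified_folds(y, cv_folds, seed = seed)
  means <- vapply(bounds_grid, function(b) {
    mean(cv_fold_metrics(X[, candidates[seq_len(b)], drop = FALSE], y, task,
                         params, nrounds, folds, metric, seed))
  }, numeric(1))
  best <- max(means)
  bound <- bounds_grid[which(means >= best - tolerance)[1]]
  list(features = candidates[seq_len(bound)], bound = bound,
       metrics = stats::setNames(means, bounds_grid))
}

#' Default hyperparameter search space
#'
#' Bounds for the adaptive search; each entry has `lower`, `upper` and
#' optional `log`/`integer` flags.
#'
#' @return named list of parameter bounds
#' @export
default_search_space <- function() {
  list(eta = list(lower = 0.03, upper = 0.4, log = TRUE),
       max_depth = list(lower = 2, upper = 6, integer = TRUE),
       min_child_weight = list(lower = 1, upper = 30, log = TRUE),
       subsample = list(lower = 0.6, upper = 1),
       colsample_bytree = list(lower = 0.5, upper = 1),
       lambda = list(lower = 0.3, upper = 8, log = TRUE))
}

sample_params <- function(space, around = NULL, frac = 0.15) {
  out <- list()
  for (nm in names(space)) {
    sp <- space[[nm]]
    lo <- sp$lower; hi <- sp$upper
    if (isTRUE(sp$log)) { lo <- log(lo); hi <- log(hi) }
    if (is.null(around)) {
      v <- stats::runif(1, lo, hi)
    } else {
      c0 <- around[[nm]]
      if (isTRUE(sp$log)) c0 <- log(c0)
      v <- stats::rnorm(1, c0, frac * (hi - lo))
      v <- min(max(v, lo), hi)
    }
    if (isTRUE(sp$log)) v <- exp(v)
    if (isTRUE(sp$integer)) v <- as.integer(round(v))
    out[[nm]] <- v
  }
  out
}

#' Adaptive hyperparameter search with early pruning
#'
#' Sequential search over a bounded space: uniform exploration during a
#' warm-up phase, then a mix of exploration and Gaussian sampling around the
#' incumbent best. Trials are evaluated fold-by-fold and pruned early when
#' their running mean falls below the median running mean of completed trials
#' at the same stage (a median-rule pruner). The returned parameters are the
#' argmax of the completed-trial CV metric; pruned trials are never reported
#' as best. Deterministic given the seed.
#'
#' @param X,y training data
#' @param task "classification" or "regression"
#' @param search_space bounds, as [default_search_space()]
#' @param n_trials number of trials
#' @param cv_folds folds per trial
#' @param metric CV metric (default F1 for classification, R^2 for
#'   regression)
#' @param nrounds boosting rounds per fit
#' @param base_params fixed booster parameters underlying every trial
#' @param seed integer seed
#' @return list of class `tuning_result`: `best_params`, `best_metric`,
#'   `history` (one row per trial), `cv` (folds and seed), `metric`
#' @export
tune <- function(X, y, task = "classification",
                 search_space = default_search_space(),
                 n_trials = 100, cv_folds = 10, metric = NULL,
                 nrounds = 60, base_params = list(), seed = 1L) {
  metric <- metric %||% default_metric(task)
  if (task == "regression" && metric == "f1")
    stopf("metric 'f1' is undefined for regression")
  folds <- stratified_folds(y, cv_folds, seed = seed)
  rs <- restore_seed(seed); on.exit(rs())
  warmup <- max(5L, n_trials %/% 4L)
  hist <- vector("list", n_trials)
  stage_means <- list()   # running means of completed trials per stage
  best_params <- NULL; best_metric <- -Inf
  for (i in seq_len(n_trials)) {
    around <- if (i > warmup && !is.null(best_params) && stats::runif(1) < 0.6)
      best_params else NULL
    params <- sample_params(search_space, around)
    fm <- numeric(0); pruned <- FALSE
    for (k in sort(unique(folds))) {
      tr <- folds != k
      fit <- fit_xgb(X[tr, , drop = FALSE], y[tr], task,
                     utils::modifyList(base_params, params), nrounds,
                     seed = seed + 1000L * i + k)
      fm <- c(fm, holdout_metric(metric, y[!tr],
                                 predict_xgb(fit, X[!tr, , drop = FALSE])))
      st <- length(fm)
      if (st < cv_folds) {
        ref <- stage_means[[as.character(st)]]
        if (length(ref) >= 3 && mean(fm) < stats::median(ref)) {
          pruned <- TRUE
          break
        }
      }
    }
    m <- if (pruned) NA_real_ else mean(fm)
    if (!pruned) {
      for (st in seq_along(fm))
        stage_means[[as.character(st)]] <-
          c(stage_means[[as.character(st)]], mean(fm[seq_len(st)]))
      if (m > best_metric) { best_metric <- m; best_params <- params }
    }
    hist[[i]] <- data.frame(trial = i, metric = m, pruned = pruned,
                            as.data.frame(params))
  }
  if (is.null(best_params)) stopf("tune: no trial completed")
  structure(list(best_params = best_params, best_metric = best_metric,
                 history = do.call(rbind, hist),
                 cv = list(folds = cv_folds, seed = seed), metric = metric),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Adaptive search: %d trials (%d completed), best %s = %.4f\n",
              nrow(x$history), sum(!x$history$pruned), x$metric, x$best_metric))
  str(x$best_params, give.head = FALSE)
  invisible(x)
}
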