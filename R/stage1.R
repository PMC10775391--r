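# Stage-1 meta-feature battery: spec enumeration, scope contracts, training
# on the prevalent cohort and inference of meta-features.

#' Declare one stage-1 prediction task
#'
#' @param outcome diagnosis or biomarker name
#' @param task "classification" or "regression"
#' @param horizon one of "baseline_early", "baseline_late", "baseline_any",
#'   "future_10y", "future_20y", "baseline_value"
#' @param scope "unmodifiable_only" or "all_features"
#' @return object of class `meta_spec`
#' @export
meta_spec <- function(outcome, task, horizon, scope) {
  horizon <- match.arg(horizon, c("baseline_early", "baseline_late",
                                  "baseline_any", "future_10y", "future_20y",
                                  "baseline_value"))
  scope <- match.arg(scope, c("unmodifiable_only", "all_features"))
  task <- match.arg(task, c("classification", "regression"))
  if (horizon %in% c("baseline_early", "baseline_late", "baseline_any") &&
      scope != "unmodifiable_only")
    stopf("baseline diagnosis horizons require scope 'unmodifiable_only' (reverse causation)")
  if (horizon %in% c("future_10y", "future_20y") && scope != "all_features")
    stopf("future horizons use scope 'all_features'")
  structure(list(outcome = outcome, task = task, horizon = horizon,
                 scope = scope,
                 name = paste("meta", outcome, horizon,
                              if (scope == "unmodifiable_only") "u" else "a",
                              sep = "_")),
            class = "meta_spec")
}

#' Enumerate the stage-1 task battery
#'
#' Per diagnosis: three baseline-onset classification tasks (early / late /
#' any; unmodifiable features only, to avoid reverse causation) and two
#' future-onset tasks (10- and 20-year; all features). Per biomarker: two
#' baseline-value regression tasks, one per feature scope. The count is
#' `5 * n_diagnoses + 2 * n_biomarkers`.
#'
#' @param diagnoses character vector of diagnosis names
#' @param biomarkers character vector of biomarker names
#' @return list of [meta_spec()]
#' @export
enumerate_specs <- function(diagnoses, biomarkers) {
  specs <- list()
  for (dx in diagnoses) {
    for (h in c("baseline_early", "baseline_late", "baseline_any"))
      specs[[length(specs) + 1L]] <-
        meta_spec(dx, "classification", h, "unmodifiable_only")
    for (h in c("future_10y", "future_20y"))
      specs[[length(specs) + 1L]] <-
        meta_spec(dx, "classification", h, "all_features")
  }
  for (bm in biomarkers) {
    specs[[length(specs) + 1L]] <-
      meta_spec(bm, "regression", "baseline_value", "unmodifiable_only")
    specs[[length(specs) + 1L]] <-
      meta_spec(bm, "regression", "baseline_value", "all_features")
  }
  specs
}

#' Validate a design against a task's feature scope
#'
#' Fails iff any design column's schema scope violates the task's scope rule
#' (an `unmodifiable_only` task admits no modifiable column). Invoked before
#' every stage-1 fit and every inference.
#'
#' @param spec a [meta_spec()]
#' @param design_columns character vector of design column names
#' @param schema a [feature_schema()] covering all columns
#' @return `TRUE` or `FALSE`, with offending columns in attribute
#'   `violations`
#' @export
validate_scope <- function(spec, design_columns, schema) {
  m <- match(design_columns, schema$name)
  if (anyNA(m))
    stopf("validate_scope: column(s) missing from schema: %s",
          paste(design_columns[is.na(m)], collapse = ", "))
  if (spec$scope == "all_features") return(TRUE)
  bad <- design_columns[schema$scope[m] == "modifiable"]
  structure(length(bad) == 0L, violations = bad)
}

# Scope-permitted design columns for a spec; the target biomarker itself is
# never its own predictor.
scope_columns <- function(spec, schema) {
  cols <- if (spec$scope == "unmodifiable_only")
    schema$name[schema$scope == "unmodifiable"] else schema$name
  setdiff(cols, spec$outcome)
}

#' Budget profile for stage-1 and final-model training
#'
#' Collects the selection/tuning knobs so that desk-scale and larger runs
#' share one code path.
#'
#' @param preselect_k features kept by Saabas pre-selection
#' @param bounds_grid feature-count grid for minimal-model selection
#' @param tolerance CV shortfall allowed by the minimal-model rule
#' @param cv_folds folds for selection and tuning
#' @param tune_trials adaptive-search trials (0 skips tuning and keeps
#'   `base_params`)
#' @param nrounds boosting rounds of the final fit
#' @param cv_nrounds boosting rounds during selection CV
#' @param tune_nrounds boosting rounds during tuning trials (defaults to
#'   `cv_nrounds`)
#' @param base_params booster parameters merged under any tuned parameters
#' @param search_space tuning bounds (`NULL` = [default_search_space()])
#' @param bag number of seed-replicate boosters averaged in the final fit
#' @return list of class `fit_budget`
#' @export
fit_budget <- function(preselect_k = 200, bounds_grid = c(10, 20, 40),
                       tolerance = NULL, cv_folds = 3, tune_trials = 0,
                       nrounds = 80, cv_nrounds = 50, tune_nrounds = NULL,
                       base_params = list(), search_space = NULL, bag = 1) {
  structure(list(preselect_k = preselect_k, bounds_grid = bounds_grid,
                 tolerance = tolerance, cv_folds = cv_folds,
                 tune_trials = tune_trials, nrounds = nrounds,
                 cv_nrounds = cv_nrounds,
                 tune_nrounds = tune_nrounds %||% cv_nrounds,
                 base_params = base_params, search_space = search_space,
                 bag = bag), class = "fit_budget")
}

# Shared selection -> tuning -> fit path used by stage-1 and the final model.
fit_selected <- function(X, y, task, budget, seed, metric = NULL) {
  pre_fit <- fit_xgb(X, y, task, nrounds = budget$cv_nrounds, seed = seed)
  attr_pre <- saabas_attribute(pre_fit, X, method = "fast")
  cand <- preselect_top_k(attr_pre, budget$preselect_k)
  sel <- select_minimal_features(
    X, y, cand, bounds_grid = budget$bounds_grid,
    tolerance = budget$tolerance, task = task,
    nrounds = budget$cv_nrounds, cv_folds = budget$cv_folds, seed = seed)
  Xs <- X[, sel$features, drop = FALSE]
  params <- budget$base_params; tuning <- NULL; cvm <- max(sel$metrics)
  if (budget$tune_trials > 0) {
    tuning <- tune(Xs, y, task,
                   search_space = budget$search_space %||% default_search_space(),
                   n_trials = budget$tune_trials,
                   cv_folds = budget$cv_folds, nrounds = budget$tune_nrounds,
                   base_params = budget$base_params,
                   metric = metric, seed = seed)
    params <- utils::modifyList(budget$base_params, tuning$best_params)
    cvm <- tuning$best_metric
  }
  boosters <- lapply(seq_len(budget$bag), function(b)
    fit_xgb(Xs, y, task, params, nrounds = budget$nrounds,
            seed = seed + 7919L * b))
  list(booster = boosters[[1]], boosters = boosters, params = params,
       features = sel$features, selection = sel,
       tuning = tuning, cv_metric = cvm)
}

#' Train one stage-1 model on the prevalent cohort
#'
#' Runs the shared pipeline (Saabas pre-selection, minimal-model selection,
#' optional adaptive tuning, class-weighted final fit) on the
#' scope-permitted features for the spec's outcome. A classification task
#' with fewer than 10 cases is skipped with a warning (returns `NULL`).
#' Rows must come from the prevalent cohort: any other cohort tag raises.
#'
#' @param features numeric feature data.frame (id column plus features)
#' @param outcome_tables result of [build_outcome_cohorts()] (for diagnosis
#'   tasks); biomarker tasks regress the measured baseline value
#' @param spec a [meta_spec()]
#' @param schema a [feature_schema()]
#' @param budget a [fit_budget()]
#' @param cohort_tags optional per-row cohort labels; anything other than
#'   "prevalent" raises (no-leakage contract)
#' @param seed integer seed
#' @return object of class `stage1_model` (or `NULL` if skipped)
#' @export
train_stage1 <- function(features, outcome_tables, spec, schema,
                         budget = fit_budget(), cohort_tags = NULL,
                         seed = 1L) {
  stopifnot(inherits(spec, "meta_spec"))
  if (!is.null(cohort_tags) && any(cohort_tags != "prevalent"))
    stopf("train_stage1: stage-1 models must never see non-prevalent rows")
  cols <- scope_columns(spec, schema)
  cols <- intersect(cols, names(features))
  if (!length(cols)) stopf("train_stage1: no scope-permitted features")
  ok <- validate_scope(spec, cols, schema)
  if (!isTRUE(ok))
    stopf("train_stage1: scope violation: %s",
          paste(attr(ok, "violations"), collapse = ", "))
  if (spec$task == "classification") {
    tab <- outcome_tables[[spec$outcome]]
    if (is.null(tab)) stopf("no outcome table for diagnosis '%s'", spec$outcome)
    y <- tab[[spec$horizon]]
    rows <- which(!is.na(y))
    if (sum(y[rows] == 1L) < 10) {
      warnf("spec '%s' skipped: fewer than 10 cases", spec$name)
      return(NULL)
    }
  } else {
    y <- features[[spec$outcome]]
    if (is.null(y)) stopf("biomarker '%s' absent from features", spec$outcome)
    rows <- which(!is.na(y))
  }
  X <- as.matrix(features[rows, cols, drop = FALSE])
  fit <- fit_selected(X, y[rows], spec$task, budget, seed)
  structure(list(spec = spec, booster = fit$booster,
                 features = fit$features, cv_metric = fit$cv_metric,
                 metric_name = if (spec$task == "classification") "auroc" else "r2",
                 seed = seed), class = "stage1_model")
}

#' Train the full stage-1 battery
#'
#' @param features prevalent-cohort feature table
#' @param outcome_tables per-diagnosis outcome labels
#'   ([build_outcome_cohorts()])
#' @param specs list of [meta_spec()] (see [enumerate_specs()])
#' @param schema feature schema
#' @param budget a [fit_budget()]
#' @param seed integer seed (each task derives its own)
#' @return named list of `stage1_model` (skipped specs omitted)
#' @export
train_stage1_battery <- function(features, outcome_tables, specs, schema,
                                 budget = fit_budget(), seed = 1L) {
  models <- list()
  for (spec in specs) {
    m <- train_stage1(features, outcome_tables, spec, schema, budget,
                      seed = derive_seed(seed, spec$name))
    if (!is.null(m)) models[[spec$name]] <- m
  }
  models
}

#' Infer meta-features from fitted stage-1 models
#'
#' One column per model: predicted probability for classification tasks,
#' predicted value for regression tasks. Deterministic given the fitted
#' models.
#'
#' @param models list of `stage1_model`
#' @param features feature table holding every selected feature
#' @return numeric matrix, columns named by spec
#' @export
infer_meta_features <- function(models, features) {
  out <- vapply(models, function(m) {
    missing <- setdiff(m$features, names(features))
    if (length(missing))
      stopf("infer_meta_features: model '%s' needs missing feature(s): %s",
            m$spec$name, paste(missing, collapse = ", "))
    predict_xgb(m$booster, features[, m$features, drop = FALSE])
  }, numeric(nrow(features)))
  colnames(out) <- vapply(models, function(m) m$spec$name, character(1))
  out
}
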