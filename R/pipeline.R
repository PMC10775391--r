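# End-to-end orchestration: synthetic cohort -> cohorts -> features ->
# stage-1 battery -> stacked model -> evaluation -> subgroups ->
# interventions; plus model serialization.

#' Desk-scale budget profiles
#'
#' The default problem size used throughout the package's tests and worked
#' examples: stage-1 tasks skip hyperparameter tuning and use a small
#' feature-count grid; the final model tunes briefly. See the methods
#' vignette for the rationale.
#'
#' @return a [fit_budget()]
#' @export
desk_stage1_budget <- function() {
  fit_budget(preselect_k = 200, bounds_grid = c(10, 20), cv_folds = 3,
             tune_trials = 0, nrounds = 70, cv_nrounds = 45)
}

#' @rdname desk_stage1_budget
#' @export
desk_final_budget <- function() {
  fit_budget(preselect_k = 200, bounds_grid = c(12, 20, 30),
             cv_folds = 3, tune_trials = 5, nrounds = 300, cv_nrounds = 60,
             tune_nrounds = 300,
             base_params = list(eta = 0.08, max_depth = 2,
                                colsample_bytree = 1, alpha = 1),
             search_space = list(
               eta = list(lower = 0.04, upper = 0.15, log = TRUE),
               max_depth = list(lower = 2, upper = 3, integer = TRUE),
               min_child_weight = list(lower = 1, upper = 20, log = TRUE),
               subsample = list(lower = 0.7, upper = 1)),
             bag = 5)
}

#' Run the full meta-prediction pipeline on a synthetic cohort
#'
#' Sequences the whole framework: cohort generation, missingness planting,
#' CAD ascertainment and balanced cohort construction, feature engineering,
#' stage-1 battery training on the prevalent cohort, meta-feature inference
#' and stacked-model fitting on the incident cohort, held-out evaluation
#' against a logistic comparator, attribution-based subgroup discovery, and
#' counterfactual intervention simulation with generator ground truth.
#'
#' @param config a [sim_config()]
#' @param diagnoses,biomarkers stage-1 registries
#' @param registry diagnosis [code_registry()]
#' @param stage1_budget,final_budget [fit_budget()] profiles
#' @param k_subgroups clusters cut from the case dendrogram
#' @param scenarios named list of [intervention_scenario()] (`NULL` for the
#'   standard LDL/HbA1c/SBP set)
#' @param with_missingness plant and impute the configured missingness
#' @param run_subgroups,run_interventions toggles for the downstream stages
#' @return a list with every stage's artifacts (see Details in the vignette)
#' @export
run_pipeline <- function(config = sim_config(),
                         diagnoses = c("cad", "angina", "t2d"),
                         biomarkers = c("ldl", "sbp", "hba1c"),
                         registry = default_code_registry(),
                         stage1_budget = desk_stage1_budget(),
                         final_budget = desk_final_budget(),
                         k_subgroups = 3,
                         scenarios = NULL,
                         with_missingness = TRUE,
                         run_subgroups = TRUE,
                         run_interventions = TRUE) {
  seed <- config$seed
  cohort <- generate_cohort(config)
  if (with_missingness) cohort <- plant_missingness(cohort)
  assign <- build_cohorts(cohort, registry)
  fx <- build_features(cohort)
  feats <- fx$features
  schema <- fx$schema

  prev_ids <- assign$id[assign$cohort == "prevalent"]
  inc_ids <- assign$id[assign$cohort == "incident"]
  outcome_tables <- build_outcome_cohorts(cohort, prev_ids, registry)

  specs <- enumerate_specs(diagnoses, biomarkers)
  prev_rows <- match(prev_ids, feats$id)
  stage1 <- train_stage1_battery(
    feats[prev_rows, , drop = FALSE], outcome_tables, specs, schema,
    budget = stage1_budget, seed = derive_seed(seed, "stage1"))

  inc_rows <- match(inc_ids, feats$id)
  inc_feats <- feats[inc_rows, , drop = FALSE]
  meta <- infer_meta_features(stage1, inc_feats)
  prs_cols <- grep("^prs_", schema$name, value = TRUE)
  measured_cols <- setdiff(schema$name, prs_cols)
  y <- as.integer(assign$role[match(inc_ids, assign$id)] == "case")

  model <- metapred(inc_feats[measured_cols], inc_feats[prs_cols], meta, y,
                    stage1 = stage1, budget = final_budget,
                    seed = derive_seed(seed, "final"))
  asm <- assemble_design(inc_feats[measured_cols], inc_feats[prs_cols], meta)

  # held-out evaluation against the logistic comparator
  inc_assign <- assign[match(inc_ids, assign$id), ]
  event_year <- as.numeric(inc_assign$onset_date -
                             cohort$baseline$enrol_date[inc_rows]) / 365.25
  event_year[y == 0 | event_year <= 0 | event_year > 10] <- NA
  followup <- pmin(cohort$baseline$followup_years[inc_rows], 10)
  comp_df <- data.frame(inc_feats[c("age", "sex", "sbp", "total_chol",
                                    "smoking_status")], cad_incident = y)
  comparator <- fit_comparator(comp_df[model$split$train, ])
  comp_risk <- predict(comparator, comp_df)
  te <- model$split$test
  eval <- list(
    auroc = model$metrics$auroc, auprc = model$metrics$auprc,
    cutoff = model$metrics$cutoff, confusion = model$metrics$confusion,
    comparator_auroc = auroc(y[te], comp_risk[te], n_boot = 0)$estimate,
    comparator_auprc = auprc(y[te], comp_risk[te], n_boot = 0)$estimate,
    continuous_nri = continuous_nri(comp_risk[te], model$test_pred, y[te]),
    idi = idi(comp_risk[te], model$test_pred, y[te]),
    cindex = concordance_index(
      model$test_pred,
      ifelse(is.na(event_year[te]), pmax(followup[te], 0.05),
             event_year[te]),
      !is.na(event_year[te])),
    comparator_cindex = concordance_index(
      comp_risk[te],
      ifelse(is.na(event_year[te]), pmax(followup[te], 0.05), event_year[te]),
      !is.na(event_year[te])),
    percentile_incidence = percentile_incidence(
      event_year[te], model$test_pred, horizon = 10,
      n_bins = min(100, floor(length(te) / 20))))
  comp_cut <- youden_cutoff(y[te], comp_risk[te])
  rt <- reclassification_table(
    factor(ifelse(comp_risk[te] >= comp_cut, "high", "low"),
           levels = c("low", "high")),
    model$test_pred >= model$metrics$cutoff, y[te])
  eval$reclassification <- rt
  eval$categorical_nri <- categorical_nri(rt, "high")

  out <- list(cohort = cohort, assignment = assign, features = feats,
              schema = schema, outcome_tables = outcome_tables,
              stage1 = stage1, meta = meta, design = asm$design,
              family_map = asm$family_map, y = y, model = model,
              incident_ids = inc_ids, incident_rows = inc_rows,
              event_year = event_year, followup = followup,
              comparator = comparator, comparator_risk = comp_risk,
              evaluation = eval, config = config)

  if (run_subgroups) {
    case_rows <- which(y == 1L)
    attrm <- attribution_matrix(model, as.data.frame(asm$design[case_rows, ,
                                                                drop = FALSE]))
    labels <- cluster_cases(attrm, k = k_subgroups)
    feat_tab <- as.data.frame(asm$design[case_rows, , drop = FALSE])
    eta_rank <- rank_features_by_eta(feat_tab, labels)
    ctrl_rows <- which(y == 0L)
    ctrl_labels <- assign_controls(
      asm$design[case_rows, model$features, drop = FALSE], labels,
      asm$design[ctrl_rows, model$features, drop = FALSE],
      seed = derive_seed(seed, "assign_controls"))
    all_labels <- rep(NA_integer_, length(y))
    all_labels[case_rows] <- labels
    all_labels[ctrl_rows] <- ctrl_labels
    out$subgroups <- list(attr = attrm, case_labels = labels,
                          eta_rank = eta_rank, labels = all_labels,
                          truth = cohort$truth$subgroup[inc_rows])
  }

  if (run_interventions) {
    scenarios <- scenarios %||% default_scenarios()
    out$interventions <- lapply(scenarios, function(sc) {
      extra <- list(comparator_risk = comp_risk)
      eligible <- eligibility_mask(inc_feats, sc, extra = extra)
      prof <- reinfer(model, inc_feats, sc, eligible = eligible)
      oracle <- counterfactual_risk(
        subset_cohort_rows(cohort, inc_rows), sc, eligible = eligible)
      prs_for <- switch(sc$analyte, ldl = "prs_cad", hba1c = "prs_t2d",
                        sbp = "prs_sbp", "prs_cad")
      el <- which(eligible)
      list(scenario = sc, eligible = eligible, profile = prof,
           oracle_pre = oracle$pre, oracle_post = oracle$post,
           rolling = rolling_by_prs(prof$absolute[el],
                                    inc_feats[[prs_for]][el]),
           oracle_correlation = if (length(el) > 2 &&
                                    stats::sd(prof$absolute[el]) > 0)
             stats::cor(prof$absolute[el], (oracle$pre - oracle$post)[el])
           else NA_real_)
    })
  }
  out
}

# Restrict a sim_cohort to a row subset (used to run the generator oracle on
# the incident cohort only).
subset_cohort_rows <- function(cohort, rows) {
  cohort$baseline <- cohort$baseline[rows, , drop = FALSE]
  cohort$truth <- cohort$truth[rows, , drop = FALSE]
  cohort$dosages <- cohort$dosages[rows, , drop = FALSE]
  cohort$true_scores <- cohort$true_scores[rows, , drop = FALSE]
  cohort
}

serialize_version <- "metapred/1"

#' Save a fitted meta-prediction model
#'
#' Boosters are stored as raw serialization buffers inside an RDS file; a
#' JSON sidecar records the format version, selected features, families and
#' seeds, and is validated on load.
#'
#' @param model a fitted [metapred()]
#' @param path output path (`.rds`); the sidecar is written at
#'   `paste0(path, ".json")`
#' @return `path`, invisibly
#' @export
save_metapred <- function(model, path) {
  stopifnot(inherits(model, "metapred"))
  obj <- unclass(model)
  obj$boosters <- lapply(model$boosters, xgboost::xgb.save.raw)
  obj$booster <- NULL
  obj$stage1 <- lapply(model$stage1, function(m) {
    m$booster <- xgboost::xgb.save.raw(m$booster)
    m
  })
  obj$.version <- serialize_version
  saveRDS(obj, path)
  side <- list(version = serialize_version, features = model$features,
               families = model$selected_families, seed = model$seed,
               n = model$n,
               auroc = model$metrics$auroc$estimate)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a saved meta-prediction model
#'
#' @param path path passed to [save_metapred()]
#' @return the restored `metapred` model
#' @export
load_metapred <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stopf("load_metapred: cannot parse '%s': %s",
                                            path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$.version, serialize_version))
    stopf("load_metapred: version mismatch or corrupted file")
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!identical(side$version, serialize_version) ||
        !identical(as.character(side$features), obj$features))
      stopf("load_metapred: sidecar does not match the stored model")
  }
  obj$boosters <- lapply(obj$boosters, xgboost::xgb.load.raw)
  obj$booster <- obj$boosters[[1]]
  obj$stage1 <- lapply(obj$stage1, function(m) {
    m$booster <- xgboost::xgb.load.raw(m$booster)
    m
  })
  obj$.version <- NULL
  class(obj) <- "metapred"
  obj
}
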