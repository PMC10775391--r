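# The final stacked 10-year incident CAD classifier.

#' Assemble the stacked design matrix
#'
#' Horizontally concatenates measured features, polygenic scores and
#' meta-features, tagging each column with its family. Inputs must be
#' row-aligned; duplicate column names across families are rejected.
#'
#' @param measured_table data.frame of measured baseline features
#' @param prs_matrix matrix/data.frame of standardized polygenic scores
#' @param meta_matrix matrix of stage-1 meta-features
#' @return list with `design` (numeric matrix) and `family_map` (named list
#'   of column names per family)
#' @export
assemble_design <- function(measured_table, prs_matrix, meta_matrix) {
  parts <- list(measured = as.data.frame(measured_table),
                prs = as.data.frame(prs_matrix),
                meta = as.data.frame(meta_matrix))
  n <- unique(vapply(parts, nrow, integer(1)))
  if (length(n) != 1) stopf("assemble_design: inputs are not row-aligned")
  nm <- unlist(lapply(parts, names), use.names = FALSE)
  if (anyDuplicated(nm))
    stopf("assemble_design: duplicate column name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  design <- as.matrix(do.call(cbind, unname(parts)))
  colnames(design) <- nm
  list(design = design, family_map = lapply(parts, names))
}

#' Fit the stacked meta-prediction model for 10-year incident CAD risk
#'
#' The core fitting function of the package. Measured baseline features,
#' polygenic scores and stage-1 meta-features are stacked into one design;
#' the incident cohort is split 80:20 with outcome stratification; feature
#' pre-selection (Saabas top-k), minimal-model selection and optional
#' adaptive hyperparameter tuning run on the training split; and held-out
#' discrimination metrics are reported on the test split.
#'
#' @param measured data.frame of measured features (no id column)
#' @param prs matrix/data.frame of standardized polygenic scores
#' @param meta matrix of stage-1 meta-feature predictions
#' Training rows are weighted by inverse class frequency; reported risks are
#' mapped back to the absolute scale by shifting each booster's raw margin by
#' the log-odds of the training prevalence (the exact prior correction for
#' balanced class weighting) before the sigmoid. With `budget$bag > 1` the
#' final fit is an average over seed-replicate boosters, which stabilises
#' per-individual risks and counterfactual differences.
#'
#' @param y binary 10-year incident outcome
#' @param stage1 named list of `stage1_model` backing the meta columns;
#'   required for closed-loop re-inference ([predict.metapred()] on raw
#'   features, intervention simulation)
#' @param split_ratio training fraction of the 80:20 split
#' @param budget a [fit_budget()]
#' @param n_boot bootstrap resamples for metric confidence intervals
#' @param seed integer seed
#' @return object of class `metapred`
#' @export
metapred <- function(measured, prs, meta, y, stage1 = NULL,
                     split_ratio = 0.8, budget = fit_budget(),
                     n_boot = 200, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("metapred: degenerate outcome")
  asm <- assemble_design(measured, prs, meta)
  stopifnot(nrow(asm$design) == length(y))
  if (!is.null(stage1)) {
    dep <- setdiff(asm$family_map$meta, names(stage1))
    if (length(dep))
      stopf("metapred: meta column(s) without a stage-1 dependency: %s",
            paste(dep, collapse = ", "))
  }
  sp <- split_train_test(y, ratio = split_ratio,
                         seed = derive_seed(seed, "split"))
  Xtr <- asm$design[sp$train, , drop = FALSE]
  fit <- fit_selected(Xtr, y[sp$train], "classification", budget,
                      seed = derive_seed(seed, "final"))
  offset <- stats::qlogis(mean(y[sp$train]))
  p_test <- ensemble_risk(fit$boosters, offset,
                          asm$design[sp$test, fit$features, drop = FALSE])
  y_test <- y[sp$test]
  cutoff <- youden_cutoff(y_test, p_test)
  metrics <- list(
    auroc = auroc(y_test, p_test, n_boot = n_boot,
                  seed = derive_seed(seed, "boot")),
    auprc = auprc(y_test, p_test, n_boot = n_boot,
                  seed = derive_seed(seed, "boot")),
    cutoff = cutoff,
    confusion = confusion_at(y_test, p_test, cutoff))
  sel_fam <- lapply(asm$family_map, intersect, y = fit$features)
  structure(list(
    booster = fit$booster, boosters = fit$boosters,
    margin_offset = offset, params = fit$params, features = fit$features,
    family_map = asm$family_map, selected_families = sel_fam,
    selection = fit$selection, tuning = fit$tuning,
    stage1 = stage1, split = sp, test_pred = p_test, test_y = y_test,
    metrics = metrics, budget = budget, seed = seed,
    n = nrow(asm$design)), class = "metapred")
}

#' @export
print.metapred <- function(x, ...) {
  cat("Stacked 10-year incident CAD meta-prediction model\n")
  cat(sprintf("  n = %d (train %d / test %d), %d selected features (measured %d, PRS %d, meta %d)\n",
              x$n, length(x$split$train), length(x$split$test),
              length(x$features), length(x$selected_families$measured),
              length(x$selected_families$prs), length(x$selected_families$meta)))
  ci <- x$metrics$auroc$ci
  cat(sprintf("  held-out AUROC %.3f (95%% CI %.3f-%.3f), AUPRC %.3f\n",
              x$metrics$auroc$estimate, ci[1], ci[2],
              x$metrics$auprc$estimate))
  cat(sprintf("  Youden cutoff %.3f: F1 %.3f, macro-F1 %.3f\n",
              x$metrics$cutoff, x$metrics$confusion$f1,
              x$metrics$confusion$macro_f1))
  invisible(x)
}

#' @export
summary.metapred <- function(object, ...) {
  print(object)
  cm <- object$metrics$confusion
  cat(sprintf("  TPR %.2f  TNR %.2f  FPR %.2f  FNR %.2f  accuracy %.2f\n",
              cm$tpr, cm$tnr, cm$fpr, cm$fnr, cm$accuracy))
  imp <- tryCatch(xgboost::xgb.importance(model = object$booster),
                  error = function(e) NULL)
  if (!is.null(imp)) {
    cat("  top features by gain:\n")
    top <- utils::head(as.data.frame(imp)[, c("Feature", "Gain")], 8)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-28s %.3f\n", top$Feature[i], top$Gain[i]))
  }
  invisible(object)
}

#' Predict 10-year incident CAD risk
#'
#' When `newdata` lacks the model's meta-feature columns they are recomputed
#' through the frozen stage-1 models (the prediction pipeline is closed over
#' raw features); precomputed meta columns are used as-is and give
#' bit-identical results.
#'
#' @param object a fitted [metapred()] model
#' @param newdata data.frame of raw features (measured + PRS), optionally
#'   already carrying meta columns
#' @param ... unused
#' @return risk probabilities in `[0, 1]`
#' @export
predict.metapred <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  need_meta <- setdiff(intersect(object$features, object$family_map$meta),
                       names(newdata))
  if (length(need_meta)) {
    if (is.null(object$stage1))
      stopf("predict.metapred: meta column(s) %s require the stage-1 store",
            paste(need_meta, collapse = ", "))
    mf <- infer_meta_features(object$stage1[need_meta], newdata)
    newdata <- cbind(newdata, as.data.frame(mf))
  }
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stopf("predict.metapred: missing feature(s): %s",
          paste(missing, collapse = ", "))
  ensemble_risk(object$boosters, object$margin_offset,
                newdata[, object$features, drop = FALSE])
}

# Prior-corrected ensemble risk: average of plogis(margin + offset) over the
# bagged boosters.
ensemble_risk <- function(boosters, offset, X) {
  dm <- xgboost::xgb.DMatrix(as.matrix(X))
  p <- 0
  for (b in boosters)
    p <- p + stats::plogis(stats::predict(b, dm, outputmargin = TRUE) + offset)
  p / length(boosters)
}

#' Plot held-out risk stratification
#'
#' Draws the cumulative CAD incidence at the horizon per percentile bin of
#' predicted risk on the held-out test split.
#'
#' @param x a `metapred` model
#' @param event_year per-individual event year for the test rows (`NA` =
#'   no event); row order must match the cohort passed at fit time
#' @param n_bins number of risk bins
#' @param horizon follow-up horizon in years
#' @param ... passed to [graphics::plot()]
#' @export
plot.metapred <- function(x, event_year, n_bins = 20, horizon = 10, ...) {
  ey <- event_year[x$split$test]
  pi <- percentile_incidence(ey, x$test_pred, horizon = horizon,
                             n_bins = n_bins)
  inc <- 100 * pi[, horizon]
  graphics::plot(seq_along(inc) * (100 / n_bins), inc, type = "h", lwd = 6,
                 col = "steelblue", xlab = "percentile of predicted risk",
                 ylab = sprintf("CAD incidence by year %d (%%)", horizon), ...)
  invisible(pi)
}

#' Single-family ablation of the stacked model
#'
#' Retrains restricted models on each feature family (measured, PRS, meta)
#' with the same budget, train split and seed, and reports held-out AUROC and
#' AUPRC next to the full model.
#'
#' @param model a fitted `metapred`
#' @param design the full design matrix used at fit time (see
#'   [assemble_design()])
#' @param y the outcome vector used at fit time
#' @return data.frame: family, n_features, auroc, auprc
#' @export
ablate_families <- function(model, design, y) {
  y <- as.integer(y)
  sp <- model$split
  rows <- list(full = model$features)
  for (fam in names(model$family_map)) {
    cols <- intersect(model$family_map[[fam]], colnames(design))
    if (!length(cols)) {
      warnf("ablate_families: family '%s' is empty; skipped", fam)
      next
    }
    rows[[fam]] <- cols
  }
  out <- lapply(names(rows), function(fam) {
    cols <- rows[[fam]]
    if (fam == "full") {
      p <- model$test_pred
    } else {
      fit <- fit_selected(design[sp$train, cols, drop = FALSE], y[sp$train],
                          "classification", model$budget,
                          seed = derive_seed(model$seed, paste0("ablate_", fam)))
      p <- ensemble_risk(fit$boosters, model$margin_offset,
                         design[sp$test, fit$features, drop = FALSE])
      cols <- fit$features
    }
    data.frame(family = fam, n_features = length(cols),
               auroc = auroc(y[sp$test], p, n_boot = 0)$estimate,
               auprc = auprc(y[sp$test], p, n_boot = 0)$estimate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
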