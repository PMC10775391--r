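# Counterfactual intervention engine: eligibility, analyte modulation with
# co-modulation, closed-loop re-inference and effect stratification.

#' Convert a clinical measurement to the package's internal units
#'
#' Internal units: mmol/L for lipids and glucose, mmol/mol for HbA1c, mmHg
#' for blood pressure. Supported input units: "mmol/L", "mg/dL" (lipids
#' divide by 38.67, glucose by 18.016), "mmol/mol", "percent" (HbA1c:
#' `10.929 * (x - 2.15)`), "mmHg".
#'
#' @param value numeric value(s)
#' @param unit input unit
#' @param analyte analyte name (decides the mg/dL divisor)
#' @return value in internal units
#' @export
to_internal_units <- function(value, unit, analyte) {
  switch(unit,
         "mmol/L" = , "mmol/mol" = , "mmHg" = value,
         "mg/dL" = if (analyte == "glucose") value / 18.016 else value / 38.67,
         "percent" = 10.929 * (value - 2.15),
         stopf("unknown unit '%s'", unit))
}

#' Define a counterfactual intervention scenario
#'
#' A scenario lowers one primary analyte to a clinical target in eligible
#' individuals (lowering only: values already below target are untouched) and
#' shifts co-modulated analytes by coupling rules expressed as a slope per
#' unit of primary-analyte change.
#'
#' @param label scenario name
#' @param analyte primary analyte column
#' @param target clinical target value
#' @param unit unit of `target`
#' @param eligibility list with `feature`, `threshold`, optional `unit` and
#'   `direction` (">=" by default, as in the clinical at-risk definitions)
#' @param couplings named numeric vector: co-modulated analyte -> slope
#'   (internal units per internal unit of the primary analyte)
#' @return object of class `intervention_scenario`
#' @export
intervention_scenario <- function(label, analyte, target, unit,
                                  eligibility, couplings = NULL) {
  ti <- to_internal_units(target, unit, analyte)
  if (!is.finite(ti)) stopf("intervention_scenario: non-finite target")
  el <- eligibility
  el$direction <- el$direction %||% ">="
  el$threshold_internal <- to_internal_units(
    el$threshold, el$unit %||% "mmol/L", el$feature)
  structure(list(label = label, analyte = analyte,
                 target = target, unit = unit, target_internal = ti,
                 eligibility = el, couplings = couplings),
            class = "intervention_scenario")
}

#' Standard scenarios: LDL, HbA1c and SBP lowering
#'
#' The shipped defaults follow the standard clinical at-risk thresholds
#' (comparator risk >= 7.5% for LDL lowering, HbA1c >= 6%, SBP >= 140 mmHg)
#' and target ladders (LDL 35/55/70/100 mg/dL; HbA1c 5-7%; SBP 80-160 mmHg).
#' Total cholesterol is co-modulated 1:1 with LDL; glucose follows HbA1c at
#' the estimated-average-glucose slope (0.0555 mmol/L per mmol/mol).
#'
#' @param ldl_target,hba1c_target,sbp_target target values (mg/dL, percent,
#'   mmHg)
#' @return named list of scenarios
#' @export
default_scenarios <- function(ldl_target = 70, hba1c_target = 6,
                              sbp_target = 120) {
  list(
    ldl = intervention_scenario(
      sprintf("LDL to %g mg/dL", ldl_target), "ldl", ldl_target, "mg/dL",
      eligibility = list(feature = "comparator_risk", threshold = 0.075,
                         unit = "mmol/L"),
      couplings = c(total_chol = 1)),
    hba1c = intervention_scenario(
      sprintf("HbA1c to %g%%", hba1c_target), "hba1c", hba1c_target, "percent",
      eligibility = list(feature = "hba1c", threshold = 6, unit = "percent"),
      couplings = c(glucose = 0.0555)),
    sbp = intervention_scenario(
      sprintf("SBP to %g mmHg", sbp_target), "sbp", sbp_target, "mmHg",
      eligibility = list(feature = "sbp", threshold = 140, unit = "mmHg")))
}

#' Read intervention scenarios from YAML
#'
#' Each top-level entry carries `label`, `analyte`, `target`, `unit`,
#' `eligibility` (feature/threshold/unit/direction) and optional `couplings`
#' (named analyte -> slope map).
#'
#' @param path YAML file path
#' @return named list of [intervention_scenario()]
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) {
    intervention_scenario(e$label, e$analyte, e$target, e$unit,
                          eligibility = e$eligibility,
                          couplings = unlist(e$couplings))
  })
}

#' Eligibility mask for a scenario
#'
#' @param features data.frame holding the eligibility feature (thresholds are
#'   inclusive: `>=` as printed in the clinical definitions)
#' @param scenario an [intervention_scenario()]
#' @param extra named list of derived per-individual values (e.g. a
#'   comparator risk score) consulted before the feature table
#' @return logical mask
#' @export
eligibility_mask <- function(features, scenario, extra = NULL) {
  el <- scenario$eligibility
  v <- if (!is.null(extra) && el$feature %in% names(extra)) extra[[el$feature]]
  else features[[el$feature]]
  if (is.null(v)) stopf("eligibility_mask: feature '%s' not found", el$feature)
  if (el$direction == ">=") v >= el$threshold_internal else v <= el$threshold_internal
}

#' Apply an intervention scenario to a feature table
#'
#' Eligible rows whose primary analyte exceeds the target are set to the
#' target (lowering only); co-modulated analytes shift by the coupling slope
#' times the achieved change. All other rows are returned unchanged.
#'
#' @param X feature data.frame (internal units)
#' @param scenario an [intervention_scenario()]
#' @param eligible logical mask (see [eligibility_mask()])
#' @return modified copy of `X`
#' @export
apply_scenario <- function(X, scenario, eligible) {
  if (!scenario$analyte %in% names(X))
    stopf("apply_scenario: unknown analyte '%s'", scenario$analyte)
  v <- X[[scenario$analyte]]
  target <- scenario$target_internal
  act <- eligible & !is.na(v) & v > target
  delta <- ifelse(act, v - target, 0)
  X[[scenario$analyte]] <- v - delta
  for (co in names(scenario$couplings)) {
    if (!co %in% names(X)) stopf("apply_scenario: unknown coupled analyte '%s'", co)
    X[[co]] <- X[[co]] - scenario$couplings[[co]] * delta
  }
  X
}

#' Re-infer risk after an intervention
#'
#' Applies the scenario, recomputes the meta-features whose scope includes
#' modifiable inputs through the frozen stage-1 models, and re-scores the
#' final model. Meta-features of unmodifiable-only scope are bit-identical to
#' baseline by construction; an empty scenario reproduces baseline risk
#' bit-identically.
#'
#' Derived combination features (waist-hip ratio, cholesterol ratios) are
#' recomputed on the modulated table so that deterministic functions of the
#' modified analytes stay consistent.
#'
#' @param model a fitted [metapred()] with its stage-1 store
#' @param features raw feature data.frame (measured + PRS columns)
#' @param scenario an [intervention_scenario()]
#' @param eligible logical mask (defaults to the scenario's criterion
#'   evaluated on `features`)
#' @param derived registry of derived-feature formulas re-evaluated after
#'   modulation (`NULL` to skip)
#' @return an `effect_profile` (see [risk_reduction()]) with the modified
#'   table in attribute `modified`
#' @export
reinfer <- function(model, features, scenario, eligible = NULL,
                    derived = default_derived_registry()) {
  stopifnot(inherits(model, "metapred"))
  eligible <- eligible %||% eligibility_mask(features, scenario)
  pre <- predict.metapred(model, features)
  Xmod <- apply_scenario(features, scenario, eligible)
  if (!is.null(derived)) {
    reg <- derived[names(derived) %in% names(Xmod)]
    ins <- unique(unlist(lapply(reg, all.vars)))
    if (all(ins %in% names(Xmod)) && length(reg))
      Xmod[names(reg)] <- derive_features(Xmod[ins], reg)[names(reg)]
  }
  post <- predict.metapred(model, Xmod)
  structure(risk_reduction(pre, post, eligible = eligible),
            modified = Xmod)
}

#' Absolute and relative risk reduction
#'
#' @param pre,post aligned risk vectors
#' @param eligible optional logical mask recorded in the profile
#' @return data.frame of class `effect_profile`: pre, post, `absolute`
#'   (pre - post) and `relative` ((post - pre)/pre; `NA` with a warning when
#'   pre = 0)
#' @export
risk_reduction <- function(pre, post, eligible = NULL) {
  stopifnot(length(pre) == length(post))
  rel <- rep(NA_real_, length(pre))
  ok <- pre > 0
  if (any(!ok)) warnf("risk_reduction: %d row(s) with zero baseline risk excluded from relative change", sum(!ok))
  rel[ok] <- (post[ok] - pre[ok]) / pre[ok]
  out <- data.frame(pre = pre, post = post, absolute = pre - post,
                    relative = rel)
  out$eligible <- eligible %||% rep(TRUE, length(pre))
  class(out) <- c("effect_profile", "data.frame")
  out
}

#' Rolling intervention effect by polygenic-score percentile
#'
#' Individuals are binned into 100 percentile bins of the supplied score; at
#' bin `b` the mean and SEM of the absolute risk reduction are computed over
#' individuals pooled from bins `b - w` to `b + w` (truncated at the edges).
#'
#' @param effects numeric vector of absolute risk reductions (eligible
#'   individuals)
#' @param prs score used for percentile binning (same rows)
#' @param half_window pooling half-width in percentile bins
#' @return data.frame: percentile, mean, sem, n
#' @export
rolling_by_prs <- function(effects, prs, half_window = 5) {
  stopifnot(length(effects) == length(prs))
  n <- length(prs)
  if (n < 100) warnf("rolling_by_prs: fewer than 100 individuals; bins are sparse")
  bin <- ceiling(100 * rank(prs, ties.method = "first") / n)
  out <- lapply(1:100, function(b) {
    idx <- bin >= max(1, b - half_window) & bin <= min(100, b + half_window)
    e <- effects[idx]
    data.frame(percentile = b, mean = mean(e),
               sem = stats::sd(e) / sqrt(length(e)), n = length(e))
  })
  do.call(rbind, out)
}

#' Per-subgroup intervention effect summaries
#'
#' Median absolute reduction and median relative change per subgroup, with
#' bootstrap standard errors (percentile bootstrap of the median).
#'
#' @param effects an `effect_profile` (eligible rows are summarised)
#' @param labels subgroup labels aligned with `effects`
#' @param n_boot bootstrap resamples
#' @param seed integer seed
#' @return data.frame: group, n, median_absolute, se_absolute,
#'   median_relative, se_relative (single-member groups report `se = 0` and
#'   `degenerate = TRUE`)
#' @export
subgroup_effects <- function(effects, labels, n_boot = 500, seed = 1L) {
  stopifnot(inherits(effects, "effect_profile"),
            nrow(effects) == length(labels))
  keep <- effects$eligible & !is.na(labels)
  eff <- effects[keep, , drop = FALSE]
  lab <- labels[keep]
  rs <- restore_seed(seed); on.exit(rs())
  boot_se <- function(v) {
    if (length(v) < 2) return(0)
    meds <- vapply(seq_len(n_boot), function(b)
      stats::median(v[sample.int(length(v), replace = TRUE)], na.rm = TRUE),
      numeric(1))
    stats::sd(meds)
  }
  groups <- sort(unique(lab))
  out <- lapply(groups, function(g) {
    v <- eff[lab == g, , drop = FALSE]
    data.frame(group = g, n = nrow(v),
               median_absolute = stats::median(v$absolute),
               se_absolute = boot_se(v$absolute),
               median_relative = stats::median(v$relative, na.rm = TRUE),
               se_relative = boot_se(v$relative),
               degenerate = nrow(v) < 2)
  })
  empty <- setdiff(unique(stats::na.omit(labels)), groups)
  if (length(empty)) warnf("subgroup_effects: empty subgroup(s) omitted")
  do.call(rbind, out)
}
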