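# Synthetic biobank generator: genotypes, biomarkers, EHR records and a
# discrete-time incident CAD hazard with known ground truth.

#' Generate a genotype dosage matrix
#'
#' Per-variant allele frequencies are drawn uniformly from `maf_range` and
#' dosages as Binomial(2, maf). Deterministic given the seed.
#'
#' @param n individuals
#' @param m variants
#' @param maf_range allele-frequency pair within (0, 0.5]
#' @param seed integer seed
#' @return `n x m` integer matrix with variant column names and the drawn
#'   frequencies in attribute `maf`
#' @export
generate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(n >= 1, m >= 1)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be an increasing pair within (0, 0.5]")
  rs <- restore_seed(seed); on.exit(rs())
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  d <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  colnames(d) <- sprintf("var%04d", seq_len(m))
  attr(d, "maf") <- stats::setNames(maf, colnames(d))
  d
}

# Per-year hazard logit offsets (everything except the intercept), for years
# t = 1..horizon. covars: data.frame with age, sex, g_cad, ldl, hba1c, sbp
# and optionally g_cad_mult (per-individual subgroup multiplier on the G_CAD
# coefficient) and hz_shift (per-individual subgroup intercept bump).
hazard_offsets <- function(hz, covars, horizon) {
  ctr <- hz$centers
  gmult <- covars$g_cad_mult %||% rep(1, nrow(covars))
  base <- hz$sex_male * covars$sex +
    (covars$hz_shift %||% 0) +
    hz$g_cad * gmult * covars$g_cad +
    hz$ldl * (covars$ldl - ctr[["ldl"]]) +
    hz$hba1c * (covars$hba1c - ctr[["hba1c"]]) +
    hz$sbp * (covars$sbp - ctr[["sbp"]]) +
    hz$g_cad_x_ldl * covars$g_cad * (covars$ldl - ctr[["ldl"]])
  outer(base, rep(1, horizon)) +
    outer(covars$age, seq_len(horizon) - 0.5, function(a, t) {
      hz$age * (a + t - ctr[["age"]])
    })
}

# Analytic cumulative risk over `horizon` years: 1 - prod_t (1 - lambda_t).
analytic_risk <- function(intercept, offsets) {
  lam <- stats::plogis(intercept + offsets)
  if (any(is.nan(lam))) stopf("hazard coefficients produce non-finite logits")
  1 - apply(1 - lam, 1, prod)
}

calibrate_intercept <- function(target, mean_risk_fn) {
  f <- function(b0) mean_risk_fn(b0) - target
  stats::uniroot(f, lower = -16, upper = 4, tol = 1e-10)$root
}

#' Generate a synthetic biobank cohort
#'
#' Draws genotypes, latent genetic scores, a latent risk-subgroup mixture,
#' baseline biomarkers, medication text, prevalent diagnoses, EHR records with
#' eligibility summaries, and incident CAD onset by iterating the per-year
#' hazard over 20 years (the first 10 are the modelling horizon; years 11-20
#' exercise the late-onset exclusion and 20-year stage-1 outcomes). The
#' analytic per-individual 10-year risk is retained as ground truth.
#'
#' @param config a [sim_config()]
#' @return object of class `sim_cohort`: list with `baseline` (feature table),
#'   `dosages`, `variants`, `weight_sets`, `true_scores`, `ehr`,
#'   `self_report`, `truth` (hidden per-individual ground truth) and `config`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  id <- sprintf("id%06d", seq_len(n))

  dos <- generate_genotypes(n, config$n_variants, config$maf_range,
                            seed = derive_seed(config$seed, "genotypes"))
  rownames(dos) <- id
  ws <- config$weight_sets %||%
    make_weight_sets(config$n_variants, seed = derive_seed(config$seed, "weights"))
  raw <- dos %*% do.call(cbind, ws)
  colnames(raw) <- names(ws)
  scores <- apply(raw, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })

  rs <- restore_seed(derive_seed(config$seed, "covariates")); on.exit(rs())
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  sex <- stats::rbinom(n, 1L, 0.46)                     # 1 = male
  sgs <- config$subgroup_spec
  if (!is.null(sgs$genetic_top_fraction)) {
    # deterministic top-percentile polygenic-burden stratum; remaining
    # individuals are split among the other classes by their weights
    gi <- which(sgs$labels == "genetic")
    g <- scores[, "prs_cad"]
    thr <- stats::quantile(g, 1 - sgs$genetic_top_fraction)
    grp <- rep(NA_integer_, n)
    grp[g >= thr] <- gi
    rest <- which(is.na(grp))
    others <- setdiff(seq_len(sgs$k), gi)
    grp[rest] <- sample(others, length(rest), replace = TRUE,
                        prob = sgs$weights[others])
  } else {
    lo <- sgs$score_loadings %||% rep(0, sgs$k)
    pw <- exp(outer(scores[, "prs_cad"], lo) +
                matrix(log(sgs$weights), n, sgs$k, byrow = TRUE))
    pw <- pw / rowSums(pw)
    u <- stats::runif(n)
    grp <- 1L + rowSums(u > t(apply(pw, 1, cumsum)))
  }

  bm <- config$biomarker_model
  shifts <- config$subgroup_spec$shifts
  shift_of <- function(feature) {
    s <- vapply(shifts, function(sh) if (feature %in% names(sh)) sh[[feature]] else 0,
                numeric(1))
    s[grp]
  }
  draw_bm <- function(spec) {
    mu <- spec$intercept + spec$age * (age - 55) + spec$sex_male * sex
    for (sc in names(spec$scores)) mu <- mu + spec$scores[[sc]] * scores[, sc]
    mu + stats::rnorm(n, 0, spec$sd)
  }
  ldl_untreated <- draw_bm(bm$ldl)
  hdl <- pmax(0.5, draw_bm(bm$hdl) + shift_of("hdl"))
  sbp_untreated <- draw_bm(bm$sbp)
  hba1c_untreated <- pmax(20, draw_bm(bm$hba1c))
  bmi <- pmax(16, draw_bm(bm$bmi) + shift_of("bmi"))
  smoking_status <- sample(0:2, n, replace = TRUE, prob = c(0.52, 0.37, 0.11))
  pack_years <- ifelse(smoking_status == 0, 0,
                       round(stats::rgamma(n, shape = 2, scale = 8), 1))
  fh <- stats::rbinom(n, 1L, stats::plogis(-0.25 + 0.45 * scores[, "prs_cad"]))
  g <- matrix(stats::rgamma(n * 3, shape = rep(c(8, 1, 1), each = n)), ncol = 3)
  anc <- g / rowSums(g)
  colnames(anc) <- c("ancestry_eur", "ancestry_afr", "ancestry_eas")

  # medication use follows indication (untreated levels), and treatment
  # lowers the measured level; the hazard acts on the measured (treated)
  # value
  use_statin <- stats::runif(n) < stats::plogis(
    -2.3 + 0.60 * (ldl_untreated - 3.5) + 1.0 * fh + 0.035 * (age - 55))
  use_antihtn <- stats::runif(n) < stats::plogis(
    -2.2 + 0.060 * (sbp_untreated - 137) + 0.025 * (age - 55))
  use_metf <- stats::runif(n) < stats::plogis(
    -3.1 + 0.11 * (hba1c_untreated - 36))
  use_insulin <- stats::runif(n) < stats::plogis(
    -4.5 + 0.12 * (hba1c_untreated - 36))
  # subgroup elevations are treatment-refractory: applied after the
  # medication effect, so a latent group stays coherently elevated
  ldl <- pmax(0.8, ldl_untreated * (1 - 0.42 * use_statin) + shift_of("ldl"))
  sbp <- sbp_untreated - 9 * use_antihtn + shift_of("sbp")
  hba1c <- pmax(20, hba1c_untreated - 4 * use_metf - 6 * use_insulin +
                  shift_of("hba1c"))
  total_chol <- ldl + hdl + 0.7 + stats::rnorm(n, 0, 0.35)
  glucose <- pmax(3, 3.1 + 0.057 * hba1c + stats::rnorm(n, 0, 0.7))
  hip <- 100 + 1.7 * (bmi - 27.5) + stats::rnorm(n, 0, 4)
  whr_mu <- 0.86 + 0.07 * sex + 0.01 * (age - 55) / 10
  waist <- pmax(50, hip * whr_mu + stats::rnorm(n, 0, 3))

  hm <- config$subgroup_spec$hazard_multipliers
  g_cad_mult <- if (is.null(hm)) rep(1, n) else
    vapply(hm, function(m) if ("g_cad" %in% names(m)) m[["g_cad"]] else 1,
           numeric(1))[grp]
  hz_shift <- (config$subgroup_spec$hazard_shifts %||% rep(0, sgs$k))[grp]
  covars <- data.frame(age = age, sex = sex, g_cad = scores[, "prs_cad"],
                       ldl = ldl, hba1c = hba1c, sbp = sbp,
                       g_cad_mult = g_cad_mult, hz_shift = hz_shift)

  # baseline prevalent CAD (cross-sectional model, calibrated intercept)
  pm <- config$prevalence_model
  # the latent-class hazard bump is prospective only: baseline prevalence
  # reflects the polygenic score through its own coefficient
  prev_off <- pm$age * (age - pm$centers[["age"]]) + pm$sex_male * sex +
    pm$g_cad * scores[, "prs_cad"] +
    pm$ldl * (ldl - pm$centers[["ldl"]]) +
    pm$hba1c * (hba1c - pm$centers[["hba1c"]]) +
    pm$sbp * (sbp - pm$centers[["sbp"]])
  p0 <- pm$intercept
  if (is.na(p0))
    p0 <- calibrate_intercept(config$target_prevalence,
                              function(b0) mean(stats::plogis(b0 + prev_off)))
  cad_prev <- stats::runif(n) < stats::plogis(p0 + prev_off)

  # incident CAD over 20 years by iterating the per-year hazard
  hz <- config$hazard_model
  off10 <- hazard_offsets(hz, covars, 10)
  b0 <- hz$intercept
  if (is.na(b0)) {
    nonprev <- !cad_prev
    b0 <- calibrate_intercept(config$target_incidence, function(b) {
      mean(analytic_risk(b, off10[nonprev, , drop = FALSE]))
    })
  }
  off20 <- hazard_offsets(hz, covars, 20)
  lam20 <- stats::plogis(b0 + off20)
  if (any(is.nan(lam20))) stopf("hazard coefficients produce non-finite logits")
  u <- matrix(stats::runif(n * 20), n, 20)
  hit <- u < lam20
  onset <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  onset[cad_prev] <- NA_integer_
  true_risk10 <- analytic_risk(b0, off10)

  # other contributing diagnoses: baseline prevalence + 10/20-year incidence
  angina_prev <- stats::runif(n) < stats::plogis(
    -3.6 + 0.5 * scores[, "prs_cad"] + 0.3 * (ldl - 3.5) + 0.05 * (age - 55))
  t2d_prev <- stats::runif(n) < stats::plogis(
    -4.2 + 0.9 * scores[, "prs_t2d"] + 0.10 * (hba1c - 36) + 0.03 * (age - 55))
  htn_prev <- stats::runif(n) < stats::plogis(
    -2.5 + 0.05 * (sbp - 137) + 0.05 * (age - 55))
  r10_ang <- stats::plogis(-4.3 + 0.45 * scores[, "prs_cad"] +
                             0.28 * (ldl - 3.5) + 0.05 * (age - 55) + 0.3 * sex)
  r10_t2d <- stats::plogis(-4.8 + 0.9 * scores[, "prs_t2d"] +
                             0.09 * (hba1c - 36) + 0.04 * (age - 55))
  u_ang <- stats::runif(n); u_t2d <- stats::runif(n)
  ang_inc10 <- !angina_prev & u_ang < r10_ang
  ang_inc20 <- !angina_prev & u_ang < (1 - (1 - r10_ang)^2)
  t2d_inc10 <- !t2d_prev & u_t2d < r10_t2d
  t2d_inc20 <- !t2d_prev & u_t2d < (1 - (1 - r10_t2d)^2)

  # onset ages for baseline diagnoses (uniform between 30 and enrolment age)
  onset_age_of <- function(flag) ifelse(flag, round(stats::runif(n, 30, age), 1), NA)
  cad_prev_onset_age <- onset_age_of(cad_prev)
  angina_onset_age <- onset_age_of(angina_prev)
  t2d_onset_age <- onset_age_of(t2d_prev)
  htn_onset_age <- onset_age_of(htn_prev)

  # follow-up and EHR-entry summaries for eligibility filtering
  short <- stats::runif(n) < 0.08
  followup_years <- ifelse(short, stats::runif(n, 0.1, 9.5), stats::runif(n, 11, 15))
  sparse <- stats::runif(n) < 0.03
  n_filler <- ifelse(sparse, 0L,
                     stats::rpois(n, pmax(0.5, 0.6 * followup_years)))
  death_other <- stats::runif(n) < 0.025

  # medication free-text from the drawn usage flags
  p_aspirin <- stats::plogis(-2.3 + 0.6 * cad_prev + 0.02 * (age - 55))
  pick <- function(use, choices) ifelse(use, sample(choices, n, replace = TRUE), NA)
  med_cols <- cbind(
    pick(use_statin, c("Atorvastatin 20mg", "Simvastatin 40mg", "Rosuvastatin 10mg")),
    pick(use_antihtn, c("Ramipril 5mg", "Amlodipine 5mg", "Losartan 50mg")),
    pick(use_metf, "Metformin 500mg"),
    pick(use_insulin, "Insulin glargine"),
    pick(stats::runif(n) < p_aspirin, "Aspirin 75mg"),
    pick(stats::runif(n) < 0.10 * (1 - sex), "Estradiol patch"))
  medications <- apply(med_cols, 1, function(r) paste(stats::na.omit(r), collapse = ";"))

  enrol_date <- as.Date("2006-01-01") + round(stats::runif(n, 0, 1825))
  birth_date <- enrol_date - round(age * 365.25) - round(stats::runif(n, 0, 200))

  baseline <- data.frame(
    id = id, age = age, sex = sex, fh_heart_disease = fh,
    anc, ldl = round(ldl, 3), hdl = round(hdl, 3),
    total_chol = round(total_chol, 3), sbp = round(sbp, 1),
    hba1c = round(hba1c, 1), glucose = round(glucose, 2),
    bmi = round(bmi, 2), waist = round(waist, 1), hip = round(hip, 1),
    smoking_status = smoking_status, pack_years = pack_years,
    medications = medications,
    enrol_date = enrol_date, birth_date = birth_date,
    followup_years = round(followup_years, 2),
    death_other = as.integer(death_other),
    stringsAsFactors = FALSE)

  reg <- default_code_registry()
  ehr_parts <- list()
  date_from_onset_age <- function(oa) birth_date + round(oa * 365.25)
  # prevalent CAD: 80% carry an EHR record; 20% are self-report only
  sr_only <- cad_prev & stats::runif(n) < 0.20
  idx <- cad_prev & !sr_only
  if (any(idx)) ehr_parts[[length(ehr_parts) + 1L]] <- data.frame(
    id = id[idx], code = sample(reg$cad$ehr, sum(idx), replace = TRUE),
    date = date_from_onset_age(cad_prev_onset_age)[idx], stringsAsFactors = FALSE)
  # incident CAD: recorded iff onset falls within EHR follow-up
  idx <- !is.na(onset) & onset <= ceiling(followup_years)
  if (any(idx)) ehr_parts[[length(ehr_parts) + 1L]] <- data.frame(
    id = id[idx], code = sample(reg$cad$ehr, sum(idx), replace = TRUE),
    date = enrol_date[idx] + round((onset[idx] - 0.5) * 365.25),
    stringsAsFactors = FALSE)
  add_dx <- function(prev_flag, onset_age, inc10, inc20, dx) {
    if (any(prev_flag)) ehr_parts[[length(ehr_parts) + 1L]] <<- data.frame(
      id = id[prev_flag], code = sample(reg[[dx]]$ehr, sum(prev_flag), replace = TRUE),
      date = date_from_onset_age(onset_age)[prev_flag], stringsAsFactors = FALSE)
    yr <- ifelse(inc10, sample.int(10, n, replace = TRUE),
                 10 + sample.int(10, n, replace = TRUE))
    idx <- (inc10 | inc20) & yr <= ceiling(followup_years)
    if (any(idx)) ehr_parts[[length(ehr_parts) + 1L]] <<- data.frame(
      id = id[idx], code = sample(reg[[dx]]$ehr, sum(idx), replace = TRUE),
      date = enrol_date[idx] + round((yr[idx] - 0.5) * 365.25),
      stringsAsFactors = FALSE)
  }
  add_dx(angina_prev, angina_onset_age, ang_inc10, ang_inc20, "angina")
  add_dx(t2d_prev, t2d_onset_age, t2d_inc10, t2d_inc20, "t2d")
  if (any(htn_prev)) ehr_parts[[length(ehr_parts) + 1L]] <- data.frame(
    id = id[htn_prev], code = sample(reg$hypertension$ehr, sum(htn_prev), replace = TRUE),
    date = date_from_onset_age(htn_onset_age)[htn_prev], stringsAsFactors = FALSE)
  # filler visits spread over follow-up
  tot_fill <- sum(n_filler)
  if (tot_fill > 0) {
    fid <- rep(seq_len(n), n_filler)
    ehr_parts[[length(ehr_parts) + 1L]] <- data.frame(
      id = id[fid],
      code = "Z00",
      date = enrol_date[fid] + round(stats::runif(tot_fill) * followup_years[fid] * 365.25),
      stringsAsFactors = FALSE)
  }
  ehr <- do.call(rbind, ehr_parts)
  ehr <- ehr[order(ehr$id, ehr$date), , drop = FALSE]
  rownames(ehr) <- NULL

  n_entries <- table(factor(ehr$id, levels = id))
  baseline$n_ehr_entries <- as.integer(n_entries) + 1L  # + enrolment visit

  self_report <- data.frame(
    id = id[sr_only],
    code = sample(reg$cad$self_report, sum(sr_only), replace = TRUE),
    age = cad_prev_onset_age[sr_only], stringsAsFactors = FALSE)

  variants <- data.frame(
    id = colnames(dos), chrom = sample(1:22, config$n_variants, replace = TRUE),
    pos = sample.int(5e7, config$n_variants),
    effect_allele = sample(c("A", "C", "G", "T"), config$n_variants, replace = TRUE),
    stringsAsFactors = FALSE)
  variants$other_allele <- vapply(variants$effect_allele, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))

  truth <- data.frame(
    id = id, subgroup = grp,
    g_cad = scores[, "prs_cad"], g_t2d = scores[, "prs_t2d"],
    g_sbp = scores[, "prs_sbp"], g_cad_mult = g_cad_mult,
    hz_shift = hz_shift,
    age = age, sex = sex, ldl = ldl, hba1c = hba1c, sbp = sbp,
    cad_prevalent = cad_prev, cad_onset_year = onset,
    cad_prev_onset_age = cad_prev_onset_age,
    angina_prev = angina_prev, t2d_prev = t2d_prev, htn_prev = htn_prev,
    angina_inc10 = ang_inc10, angina_inc20 = ang_inc20,
    t2d_inc10 = t2d_inc10, t2d_inc20 = t2d_inc20,
    true_risk10 = true_risk10, stringsAsFactors = FALSE)

  structure(list(baseline = baseline, dosages = dos, variants = variants,
                 weight_sets = ws, true_scores = scores, ehr = ehr,
                 self_report = self_report, truth = truth,
                 hazard_intercept = b0, prevalence_intercept = p0,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic biobank cohort: %d individuals, %d variants\n",
              nrow(x$baseline), ncol(x$dosages)))
  cat(sprintf("  prevalent CAD: %d (%.2f%%)\n", sum(x$truth$cad_prevalent),
              100 * mean(x$truth$cad_prevalent)))
  inc10 <- !is.na(x$truth$cad_onset_year) & x$truth$cad_onset_year <= 10
  cat(sprintf("  incident CAD (10y): %d (%.2f%% of non-prevalent)\n",
              sum(inc10), 100 * sum(inc10) / sum(!x$truth$cad_prevalent)))
  cat(sprintf("  latent subgroups: %s\n",
              paste(table(x$truth$subgroup), collapse = " / ")))
  invisible(x)
}

#' Ground-truth counterfactual 10-year risk under an intervention scenario
#'
#' Recomputes the analytic 10-year risk `1 - prod(1 - lambda_t)` after setting
#' the scenario's analyte(s) to target in eligible individuals (lowering
#' only). Individuals failing the eligibility criterion keep their factual
#' risk. This is the generator-side oracle for the model-side intervention
#' engine.
#'
#' @param cohort a `sim_cohort`
#' @param scenario an [intervention_scenario()]
#' @param eligible optional logical mask overriding the scenario's
#'   eligibility criterion (used when eligibility is defined on a derived
#'   score not stored in the cohort)
#' @return list with `pre` (factual analytic risk), `post` (counterfactual)
#'   and `eligible`
#' @export
counterfactual_risk <- function(cohort, scenario, eligible = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"),
            inherits(scenario, "intervention_scenario"))
  hzvars <- c("ldl", "hba1c", "sbp")
  if (!scenario$analyte %in% names(cohort$baseline))
    stopf("unknown analyte '%s'", scenario$analyte)
  covars <- cohort$truth[, c("age", "sex", "g_cad", "ldl", "hba1c", "sbp",
                             "g_cad_mult", "hz_shift")]
  if (is.null(eligible)) {
    eligible <- eligibility_mask(cohort$baseline, scenario)
  }
  stopifnot(length(eligible) == nrow(covars))
  target <- scenario$target_internal
  covars2 <- covars
  if (scenario$analyte %in% hzvars) {
    v <- covars2[[scenario$analyte]]
    covars2[[scenario$analyte]] <- ifelse(eligible & v > target, target, v)
  }
  # co-modulated analytes do not enter the generator hazard; nothing further
  hz <- cohort$config$hazard_model
  b0 <- cohort$hazard_intercept
  pre <- analytic_risk(b0, hazard_offsets(hz, covars, 10))
  post <- analytic_risk(b0, hazard_offsets(hz, covars2, 10))
  list(pre = pre, post = post, eligible = eligible)
}

#' Plant missing-completely-at-random values
#'
#' Masks baseline feature cells at the requested per-feature rates.
#' Identifier, date, follow-up and eligibility columns are protected and may
#' not be masked.
#'
#' @param cohort a `sim_cohort`
#' @param rates named per-feature missingness proportions in `[0, 1)`;
#'   defaults to the config's `missingness`
#' @param seed integer seed
#' @return the cohort with `NA`s planted in `baseline`
#' @export
plant_missingness <- function(cohort, rates = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  rates <- rates %||% cohort$config$missingness
  seed <- seed %||% derive_seed(cohort$config$seed, "missingness")
  protected <- c("id", "enrol_date", "birth_date", "followup_years",
                 "n_ehr_entries", "death_other")
  bad <- intersect(names(rates), protected)
  if (length(bad)) stopf("cannot plant missingness on protected column(s): %s",
                         paste(bad, collapse = ", "))
  unknown <- setdiff(names(rates), names(cohort$baseline))
  if (length(unknown)) stopf("unknown feature(s): %s", paste(unknown, collapse = ", "))
  if (any(rates < 0 | rates >= 1)) stopf("missingness rates must lie in [0, 1)")
  rs <- restore_seed(seed); on.exit(rs())
  n <- nrow(cohort$baseline)
  for (f in names(rates)) {
    if (rates[[f]] == 0) next
    mask <- stats::runif(n) < rates[[f]]
    cohort$baseline[[f]][mask] <- NA
  }
  cohort
}

#' Write a synthetic cohort to delimited text files
#'
#' Emits `baseline.tsv`, `ehr.tsv`, `self_report.tsv`, `dosages.tsv` (matrix
#' with an `id` column), `variants.tsv` and one `prs_<score>.txt` weight file
#' per weight set (tab-delimited: variant_id, effect_allele, weight).
#'
#' @param cohort a `sim_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$baseline, "baseline.tsv")
  wt(cohort$ehr, "ehr.tsv")
  wt(cohort$self_report, "self_report.tsv")
  wt(data.frame(id = rownames(cohort$dosages), cohort$dosages,
                check.names = FALSE), "dosages.tsv")
  wt(cohort$variants, "variants.tsv")
  for (nm in names(cohort$weight_sets)) {
    w <- cohort$weight_sets[[nm]]
    keep <- w != 0
    wt(data.frame(variant_id = cohort$variants$id[keep],
                  effect_allele = cohort$variants$effect_allele[keep],
                  weight = w[keep]), sprintf("prs_%s.txt", sub("^prs_", "", nm)))
  }
  invisible(dir)
}

#' Polygenic score definitions carried by a synthetic cohort
#'
#' Wraps the generator's weight sets as [prs_definition()] objects. To
#' exercise the registry provenance filter, scores listed in `flag_ukb` are
#' marked as derived from the evaluation biobank.
#'
#' @param cohort a `sim_cohort`
#' @param flag_ukb score names flagged as evaluation-biobank derived
#' @return list of `prs_definition`
#' @export
prs_definitions <- function(cohort, flag_ukb = character()) {
  lapply(names(cohort$weight_sets), function(nm) {
    w <- cohort$weight_sets[[nm]]
    keep <- w != 0
    prs_definition(id = nm,
                   variant_ids = cohort$variants$id[keep],
                   effect_alleles = cohort$variants$effect_allele[keep],
                   weights = w[keep],
                   ukb_derived = nm %in% flag_ukb)
  })
}
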