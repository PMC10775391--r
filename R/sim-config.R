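# Configuration of the synthetic biobank generator.

#' Generator configuration for a synthetic biobank cohort
#'
#' Defines the ground-truth mechanisms of the synthetic cohort: genotypes,
#' latent genetic scores, biomarker models with a latent subgroup mixture,
#' a baseline-prevalence model and a discrete-time (per-year) incident hazard
#' including a gene-by-LDL interaction. All defaults are the package's desk
#' study conditions; see the methods vignette for the rationale behind each
#' value.
#'
#' Units are the package's canonical internal units: mmol/L for lipids and
#' glucose, mmol/mol for HbA1c, mmHg for blood pressure.
#'
#' @param n_individuals cohort size
#' @param n_variants number of genotyped variants
#' @param maf_range minor-allele-frequency range, within (0, 0.5]
#' @param age_range age at enrolment (years), sampled uniformly
#' @param weight_sets optional named list of per-variant weight vectors (one
#'   per polygenic score); `NULL` generates 12 sparse sets deterministically
#'   from the seed
#' @param biomarker_model named list of per-biomarker linear models (fields
#'   `intercept`, `age`, `sex_male`, `scores` (named), `sd`)
#' @param hazard_model per-year logit hazard coefficients (see defaults)
#' @param prevalence_model baseline CAD logit coefficients
#' @param missingness named per-feature MCAR rates applied by
#'   [plant_missingness()] when the pipeline requests it
#' @param subgroup_spec latent mixture: `k`, mixing `weights` (sum to 1) and
#'   per-group biomarker mean `shifts`
#' @param target_incidence population 10-year CAD incidence the hazard
#'   intercept is calibrated to (set `hazard_model$intercept` to a number to
#'   bypass calibration)
#' @param target_prevalence population baseline CAD prevalence the prevalence
#'   intercept is calibrated to
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 500,
                       maf_range = c(0.05, 0.5),
                       age_range = c(40, 69),
                       weight_sets = NULL,
                       biomarker_model = default_biomarker_model(),
                       hazard_model = default_hazard_model(),
                       prevalence_model = default_prevalence_model(),
                       missingness = default_missingness(),
                       subgroup_spec = default_subgroup_spec(),
                       target_incidence = 0.047,
                       target_prevalence = 0.044,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_variants >= 1)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be an increasing pair within (0, 0.5]")
  w <- subgroup_spec$weights
  if (length(w) != subgroup_spec$k) stopf("subgroup_spec: k and weights disagree")
  if (abs(sum(w, na.rm = TRUE) - 1) > 1e-8)
    stopf("subgroup mixing weights must sum to 1")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    maf_range = maf_range, age_range = age_range,
    weight_sets = weight_sets,
    biomarker_model = biomarker_model, hazard_model = hazard_model,
    prevalence_model = prevalence_model, missingness = missingness,
    subgroup_spec = subgroup_spec,
    target_incidence = target_incidence,
    target_prevalence = target_prevalence,
    seed = as.integer(seed)), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_hazard_model <- function() {
  list(intercept = NA_real_,       # NA = calibrated to target_incidence
       age = 0.05,                 # per attained year, centred at 55
       sex_male = 0.45,
       g_cad = 0.55,               # per SD of the latent CAD score
       ldl = 0.34,                 # per mmol/L above 3.5
       hba1c = 0.040,              # per mmol/mol above 36
       sbp = 0.016,                # per mmHg above 137
       g_cad_x_ldl = 0.26,         # SD x mmol/L interaction
       centers = c(age = 55, ldl = 3.5, hba1c = 36, sbp = 137))
}

#' @rdname sim_config
#' @export
default_prevalence_model <- function() {
  list(intercept = NA_real_,       # NA = calibrated to target_prevalence
       age = 0.075, sex_male = 0.55, g_cad = 0.60,
       ldl = 0.28, hba1c = 0.030, sbp = 0.012,
       centers = c(age = 55, ldl = 3.5, hba1c = 36, sbp = 137))
}

#' @rdname sim_config
#' @export
default_biomarker_model <- function() {
  list(
    ldl = list(intercept = 3.5, age = 0.010, sex_male = 0.00,
               # CAD polygenic burden loads modestly on LDL itself, as CAD
               # risk scores carry lipid loci
               scores = c(prs_ldl = 0.45, prs_cad = 0.15), sd = 0.75),
    hdl = list(intercept = 1.52, age = 0.002, sex_male = -0.15,
               scores = c(prs_hdl = 0.12), sd = 0.30),
    sbp = list(intercept = 137, age = 0.45, sex_male = 3.5,
               scores = c(prs_sbp = 5.5), sd = 13),
    hba1c = list(intercept = 36, age = 0.16, sex_male = 0.6,
                 scores = c(prs_hba1c = 2.6, prs_t2d = 1.8), sd = 4.5),
    bmi = list(intercept = 27.5, age = 0.02, sex_male = 0.5,
               scores = c(prs_bmi = 1.6), sd = 4.0))
}

#' @rdname sim_config
#' @export
default_missingness <- function() {
  c(ldl = 0.04, hdl = 0.03, total_chol = 0.03, sbp = 0.03,
    hba1c = 0.05, glucose = 0.05, bmi = 0.02, pack_years = 0.25)
}

#' @rdname sim_config
#' @export
default_subgroup_spec <- function() {
  list(k = 3L, weights = c(0.5, 0.5, NA),
       labels = c("lipid", "cardiometabolic", "genetic"),
       shifts = list(
         lipid = c(ldl = 3.5),
         cardiometabolic = c(sbp = 40, hba1c = 22),
         genetic = c()),
       # the genetic-mechanism class is the top stratum of polygenic burden
       # (top `genetic_top_fraction` of the latent CAD score); it carries a
       # hazard and baseline-prevalence intercept bump on top of the shared
       # polygenic slope, like a discrete high-burden genotype class
       genetic_top_fraction = 0.18,
       hazard_shifts = c(lipid = 0, cardiometabolic = 0, genetic = 1.8),
       hazard_multipliers = list(
         lipid = c(g_cad = 1), cardiometabolic = c(g_cad = 1),
         genetic = c(g_cad = 1)))
}

# Names of the 12 generated polygenic weight sets. The first six back causal
# latent scores; the rest are nuisance traits carried along as candidates.
prs_names <- function() {
  c("prs_cad", "prs_ldl", "prs_hba1c", "prs_sbp", "prs_t2d", "prs_bmi",
    "prs_hdl", "prs_tg", "prs_lpa", "prs_mdd", "prs_alcohol", "prs_wbc")
}

#' Generate sparse polygenic weight sets
#'
#' Each score loads on a random subset of variants with standard-normal
#' weights; deterministic given the seed.
#'
#' @param n_variants number of variants in the dosage matrix
#' @param names score names
#' @param n_loci loci per score
#' @param seed integer seed
#' @return named list of length-`n_variants` weight vectors
#' @export
make_weight_sets <- function(n_variants, names = prs_names(),
                             n_loci = max(10L, round(n_variants * 0.12)),
                             seed = 1L) {
  rs <- restore_seed(seed); on.exit(rs())
  out <- lapply(names, function(nm) {
    w <- numeric(n_variants)
    idx <- sample.int(n_variants, min(n_loci, n_variants))
    w[idx] <- stats::rnorm(length(idx))
    w
  })
  names(out) <- names
  out
}
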