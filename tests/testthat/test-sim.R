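# Synthetic biobank generator: determinism, analytic calibration, oracles.

test_that("genotype generation is deterministic, bounded and moment-correct", {
  d1 <- generate_genotypes(4, 1, c(0.5, 0.5), seed = 1)
  d2 <- generate_genotypes(4, 1, c(0.5, 0.5), seed = 1)
  expect_identical(d1, d2)
  expect_true(all(d1 %in% 0:2))
  # degenerate frequency limit
  d0 <- generate_genotypes(50, 2, c(1e-12, 1e-12), seed = 2)
  expect_true(all(d0 == 0))
  # binomial moments: mean dosage within 3 SE of 2 * maf
  d <- generate_genotypes(10000, 1, c(0.2, 0.2), seed = 3)
  se <- sqrt(2 * 0.2 * 0.8 / 10000)
  expect_lt(abs(mean(d) - 0.4), 3 * se)
  expect_error(generate_genotypes(4, 1, c(0, 0.6)), "maf_range")
})

test_that("cohort generation is bit-identical under one config", {
  cfg <- sim_config(n_individuals = 400, n_variants = 40, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$baseline, c2$baseline)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$ehr, c2$ehr)
})

test_that("realized incidence and prevalence match the analytic expectation", {
  co <- small_cohort(n = 20000, seed = 31)
  nonprev <- !co$truth$cad_prevalent
  inc10 <- nonprev & !is.na(co$truth$cad_onset_year) & co$truth$cad_onset_year <= 10
  analytic <- mean(co$truth$true_risk10[nonprev])
  realized <- sum(inc10) / sum(nonprev)
  se <- sqrt(analytic * (1 - analytic) / sum(nonprev))
  expect_lt(abs(realized - analytic), 3 * se)
  # calibrated to the configured target
  expect_equal(analytic, co$config$target_incidence, tolerance = 1e-6)
  prev <- mean(co$truth$cad_prevalent)
  se_p <- sqrt(0.044 * 0.956 / nrow(co$baseline))
  expect_lt(abs(prev - co$config$target_prevalence), 3 * se_p)
})

test_that("true risk is monotone in the genetic score, all else equal", {
  co <- small_cohort(n = 500, seed = 8)
  hz <- co$config$hazard_model
  covars <- co$truth[1, c("age", "sex", "g_cad", "ldl", "hba1c", "sbp",
                          "g_cad_mult")]
  hi <- covars; hi$g_cad <- covars$g_cad + 1
  r_lo <- metapred:::analytic_risk(co$hazard_intercept,
                                   metapred:::hazard_offsets(hz, covars, 10))
  r_hi <- metapred:::analytic_risk(co$hazard_intercept,
                                   metapred:::hazard_offsets(hz, hi, 10))
  expect_gt(r_hi, r_lo)
})

test_that("degenerate hazard intercept produces zero incident cases", {
  hz <- default_hazard_model(); hz$intercept <- -Inf
  co <- generate_cohort(sim_config(n_individuals = 300, n_variants = 30,
                                   hazard_model = hz, seed = 5))
  expect_true(all(is.na(co$truth$cad_onset_year)))
  expect_true(all(co$truth$true_risk10 == 0))
})

test_that("counterfactual oracle lowers risk for eligible, leaves others alone", {
  co <- small_cohort(n = 2000, seed = 13)
  sc <- intervention_scenario("ldl70", "ldl", 70, "mg/dL",
                              eligibility = list(feature = "sbp",
                                                 threshold = 140, unit = "mmHg"))
  cf <- counterfactual_risk(co, sc)
  # lowering LDL reduces risk whenever the effective per-individual slope
  # (main effect + interaction x G_CAD) is positive
  hz <- co$config$hazard_model
  slope <- hz$ldl + hz$g_cad_x_ldl * co$truth$g_cad
  affected <- cf$eligible & co$truth$ldl > sc$target_internal & slope > 0
  expect_true(all(cf$post[affected] < cf$pre[affected]))
  expect_gt(mean(cf$pre[cf$eligible] - cf$post[cf$eligible]), 0)
  expect_identical(cf$post[!cf$eligible], cf$pre[!cf$eligible])
  # already below target: no change
  below <- cf$eligible & co$truth$ldl <= sc$target_internal
  expect_identical(cf$post[below], cf$pre[below])
})

test_that("zero LDL coefficients nullify an LDL scenario", {
  hz <- default_hazard_model()
  hz$ldl <- 0; hz$g_cad_x_ldl <- 0
  co <- generate_cohort(sim_config(n_individuals = 400, n_variants = 30,
                                   hazard_model = hz, seed = 6))
  sc <- intervention_scenario("ldl70", "ldl", 70, "mg/dL",
                              eligibility = list(feature = "sbp",
                                                 threshold = 0, unit = "mmHg"))
  cf <- counterfactual_risk(co, sc)
  expect_equal(cf$post, cf$pre, tolerance = 1e-12)
})

test_that("true LDL-lowering benefit is non-decreasing across G_CAD quintiles", {
  co <- small_cohort(n = 20000, seed = 31)
  sc <- intervention_scenario("ldl70", "ldl", 70, "mg/dL",
                              eligibility = list(feature = "ldl",
                                                 threshold = 70, unit = "mg/dL"))
  cf <- counterfactual_risk(co, sc)
  el <- cf$eligible
  red <- (cf$pre - cf$post)[el]
  g <- co$truth$g_cad[el]
  q <- cut(g, stats::quantile(g, seq(0, 1, 0.2)), include.lowest = TRUE)
  m <- tapply(red, q, mean)
  se <- tapply(red, q, function(v) sd(v) / sqrt(length(v)))
  expect_true(all(diff(m) > -(se[-1] + se[-5])))
})

test_that("planted missingness hits its rates and protects key columns", {
  co <- small_cohort(n = 10000, seed = 19)
  cm <- plant_missingness(co, rates = c(ldl = 0.19), seed = 4)
  frac <- mean(is.na(cm$baseline$ldl))
  se <- sqrt(0.19 * 0.81 / 10000)
  expect_lt(abs(frac - 0.19), 3 * se)
  # zero rate leaves the table unchanged
  cm0 <- plant_missingness(co, rates = c(ldl = 0), seed = 4)
  expect_identical(cm0$baseline, co$baseline)
  expect_error(plant_missingness(co, rates = c(followup_years = 0.1)),
               "protected")
  expect_error(plant_missingness(co, rates = c(ldl = 1)), "rates")
  expect_error(plant_missingness(co, rates = c(nope = 0.1)), "unknown")
})

test_that("cohort files round-trip through the delimited writers", {
  co <- generate_cohort(sim_config(n_individuals = 60, n_variants = 12, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("baseline.tsv", "ehr.tsv",
                                               "dosages.tsv", "variants.tsv")))))
  bl <- read.delim(file.path(dir, "baseline.tsv"))
  expect_equal(nrow(bl), 60)
  w <- read_prs_weights(file.path(dir, "prs_cad.txt"))
  expect_s3_class(w, "prs_definition")
  expect_true(all(w$variant_ids %in% co$variants$id))
})
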