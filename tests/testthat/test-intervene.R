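# Counterfactual intervention engine: units, modulation, re-inference,
# effect stratification.

test_that("unit conversions follow the canonical constants", {
  expect_equal(to_internal_units(70, "mg/dL", "ldl"), 70 / 38.67)
  expect_equal(to_internal_units(100, "mg/dL", "glucose"), 100 / 18.016)
  expect_equal(to_internal_units(6, "percent", "hba1c"), 10.929 * (6 - 2.15))
  expect_equal(to_internal_units(140, "mmHg", "sbp"), 140)
  expect_error(to_internal_units(1, "furlongs", "ldl"), "unknown unit")
})

test_that("scenario definitions round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    ldl70 = list(label = "LDL to 70", analyte = "ldl", target = 70,
                 unit = "mg/dL",
                 eligibility = list(feature = "sbp", threshold = 140,
                                    unit = "mmHg"),
                 couplings = list(total_chol = 1))), path)
  sc <- read_scenarios(path)$ldl70
  expect_s3_class(sc, "intervention_scenario")
  expect_equal(sc$target_internal, 70 / 38.67)
  expect_equal(sc$couplings[["total_chol"]], 1)
})

test_that("eligibility thresholds are inclusive as printed", {
  sc <- default_scenarios()
  f <- data.frame(hba1c = c(to_internal_units(6, "percent", "hba1c"), 40),
                  sbp = c(139, 140))
  expect_equal(eligibility_mask(f, sc$hba1c), c(TRUE, FALSE))
  expect_equal(eligibility_mask(f, sc$sbp), c(FALSE, TRUE))
  # comparator-risk eligibility: 8% passes the 7.5% bar
  el <- eligibility_mask(f, sc$ldl,
                         extra = list(comparator_risk = c(0.08, 0.05)))
  expect_equal(el, c(TRUE, FALSE))
  expect_error(eligibility_mask(data.frame(x = 1), sc$sbp), "not found")
})

test_that("scenario application lowers to target with co-modulation", {
  sc <- default_scenarios(ldl_target = 70)$ldl
  X <- data.frame(ldl = c(4.0, 1.5), total_chol = c(6.0, 3.5))
  out <- apply_scenario(X, sc, eligible = c(TRUE, TRUE))
  t_int <- 70 / 38.67
  expect_equal(out$ldl, c(t_int, 1.5))          # lowering only
  expect_equal(out$total_chol, c(6.0 - (4.0 - t_int), 3.5))
  # ineligible rows are untouched
  out2 <- apply_scenario(X, sc, eligible = c(FALSE, FALSE))
  expect_identical(out2, X)
  # coupled analyte follows the configured slope
  schb <- default_scenarios(hba1c_target = 6)$hba1c
  Xh <- data.frame(hba1c = 55, glucose = 7)
  outh <- apply_scenario(Xh, schb, eligible = TRUE)
  delta <- 55 - to_internal_units(6, "percent", "hba1c")
  expect_equal(outh$glucose, 7 - 0.0555 * delta)
  expect_error(apply_scenario(data.frame(x = 1), sc, TRUE), "unknown analyte")
})

test_that("risk reduction arithmetic and the zero-baseline guard", {
  out <- suppressWarnings(risk_reduction(c(0.2, 0.3, 0), c(0.15, 0.3, 0)))
  expect_equal(out$absolute, c(0.05, 0, 0))
  expect_equal(out$relative[1], -0.25)
  expect_equal(out$relative[2], 0)
  expect_true(is.na(out$relative[3]))
  expect_warning(risk_reduction(c(0, 0.1), c(0, 0.1)), "zero baseline")
})

test_that("an empty scenario reproduces baseline risk bit-identically", {
  res <- small_pipeline()
  feats <- res$features[res$incident_rows, ]
  # target far above everyone: nothing is modulated
  sc <- intervention_scenario("noop", "ldl", 5000, "mg/dL",
                              eligibility = list(feature = "sbp",
                                                 threshold = 0, unit = "mmHg"))
  prof <- reinfer(res$model, feats, sc)
  expect_identical(prof$pre, prof$post)
  expect_true(all(prof$absolute == 0))
})

test_that("unmodifiable-only meta-features are unchanged by any scenario", {
  res <- small_pipeline()
  feats <- res$features[res$incident_rows, ]
  sc <- default_scenarios()$sbp
  eligible <- eligibility_mask(feats, sc)
  Xmod <- apply_scenario(feats, sc, eligible)
  u_models <- Filter(function(m) m$spec$scope == "unmodifiable_only",
                     res$stage1)
  expect_gt(length(u_models), 0)
  expect_identical(infer_meta_features(u_models, feats),
                   infer_meta_features(u_models, Xmod))
})

test_that("re-inference lowers population risk for a planted positive effect", {
  res <- small_pipeline()
  feats <- res$features[res$incident_rows, ]
  sc <- default_scenarios()$ldl
  eligible <- eligibility_mask(feats, sc,
                               extra = list(comparator_risk = res$comparator_risk))
  prof <- reinfer(res$model, feats, sc, eligible = eligible)
  expect_lt(mean(prof$post[eligible]), mean(prof$pre[eligible]))
  # eligibility conservation: reductions exactly 0 for ineligible rows
  expect_true(all(prof$absolute[!eligible] == 0))
})

test_that("rolling PRS-percentile curves pool the stated window", {
  set.seed(2)
  n <- 1000
  prs <- rnorm(n)
  eff <- 0.05 + 0.01 * prs + rnorm(n, 0, 0.001)
  roll <- rolling_by_prs(eff, prs, half_window = 5)
  expect_equal(nrow(roll), 100)
  # edge bin 1 pools bins 1..6 only
  bin <- ceiling(100 * rank(prs, ties.method = "first") / n)
  expect_equal(roll$n[1], sum(bin <= 6))
  expect_equal(roll$mean[1], mean(eff[bin <= 6]))
  # monotone planted effect gives an increasing curve
  expect_gt(roll$mean[95], roll$mean[5])
  # constant effect: flat curve, sem ~ 0
  roll0 <- rolling_by_prs(rep(0.07, n), prs)
  expect_true(all(abs(roll0$mean - 0.07) < 1e-12))
  expect_true(all(roll0$sem < 1e-12))
})

test_that("subgroup effect summaries report medians with bootstrap SEs", {
  set.seed(9)
  eff <- risk_reduction(pre = runif(200, 0.1, 0.5),
                        post = runif(200, 0.05, 0.45))
  labels <- rep(1:2, each = 100)
  out <- subgroup_effects(eff, labels, n_boot = 100, seed = 1)
  expect_equal(out$group, 1:2)
  expect_equal(out$median_absolute[1],
               median(eff$absolute[1:100]))
  expect_true(all(out$se_absolute > 0))
  # single-member group: degenerate flag, zero SE
  out1 <- subgroup_effects(eff[1:3, ], c(1, 1, 2), n_boot = 50, seed = 1)
  expect_true(out1$degenerate[out1$group == 2])
  expect_equal(out1$se_absolute[out1$group == 2], 0)
  # all-zero effects give zero medians
  zero <- risk_reduction(rep(0.2, 10), rep(0.2, 10))
  outz <- subgroup_effects(zero, rep(1:2, 5), n_boot = 10, seed = 1)
  expect_true(all(outz$median_absolute == 0))
})

test_that("planted differential coupling separates subgroup medians", {
  set.seed(13)
  n <- 400
  labels <- rep(1:2, each = n / 2)
  eff <- risk_reduction(pre = rep(0.3, n),
                        post = 0.3 - ifelse(labels == 1, 0.10, 0.02) +
                          rnorm(n, 0, 0.01))
  out <- subgroup_effects(eff, labels, n_boot = 200, seed = 2)
  gap <- out$median_absolute[1] - out$median_absolute[2]
  expect_gt(gap, 0.08 - 3 * sum(out$se_absolute))
})
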