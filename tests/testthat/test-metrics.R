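# Discrimination, classification and reclassification machinery.

test_that("auroc matches hand example, handles ties and separable data", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), n_boot = 0)$estimate,
               0.75)
  expect_equal(auroc(c(0, 1, 0, 1), c(0.9, 0.95, 0.1, 0.99), n_boot = 0)$estimate, 1)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.4, 4), n_boot = 0)$estimate, 0.5)
  expect_error(auroc(c(1, 1, 1), c(0.1, 0.2, 0.3), n_boot = 0), "both classes")
})

test_that("auroc equals brute-force pair counting on random small instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(auroc(y, p, n_boot = 0)$estimate, bf_auroc(y, p))
  }
})

test_that("auroc agrees with an independent library implementation", {
  set.seed(77)
  y <- rbinom(500, 1, 0.3)
  p <- plogis(rnorm(500) + 1.2 * y)
  expect_equal(auroc(y, p, n_boot = 0)$estimate,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
})

test_that("auroc bootstrap CI brackets the estimate and is seed-stable", {
  set.seed(5)
  y <- rbinom(300, 1, 0.3); p <- plogis(rnorm(300) + y)
  a1 <- auroc(y, p, n_boot = 200, seed = 9)
  a2 <- auroc(y, p, n_boot = 200, seed = 9)
  expect_identical(a1, a2)
  expect_true(a1$ci[1] <= a1$estimate && a1$estimate <= a1$ci[2])
})

test_that("auprc equals exact average precision on a hand example", {
  # ranked desc: y = 1,0,1 -> precision at positives: 1/1, 2/3
  y <- c(1, 0, 1); p <- c(0.9, 0.6, 0.3)
  expect_equal(auprc(y, p, n_boot = 0)$estimate, 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(auprc(c(0, 1), c(0.1, 0.9), n_boot = 0)$estimate, 1)
})

test_that("confusion_at reproduces hand confusion matrix and boundaries", {
  r <- confusion_at(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(c(r$tp, r$fp, r$fn, r$tn), c(1, 1, 1, 1))
  expect_equal(r$f1, 0.5)
  perfect <- confusion_at(c(1, 0), c(0.9, 0.1), 0.5)
  expect_equal(c(perfect$tpr, perfect$tnr, perfect$fpr, perfect$fnr),
               c(1, 1, 0, 0))
  expect_equal(perfect$macro_f1, 1)
  all_pos <- confusion_at(c(1, 0), c(0.6, 0.6), 0)
  expect_equal(all_pos$tnr, 0)
})

test_that("youden cutoff matches an exhaustive scan and tie rules", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)
    # independent exhaustive scan
    cand <- sort(unique(p))
    j <- sapply(cand, function(cc) mean(p[y == 1] >= cc) - mean(p[y == 0] >= cc))
    expect_equal(youden_cutoff(y, p), cand[which.max(j)])
  }
  # perfectly separated: smallest positive-class value returned
  expect_equal(youden_cutoff(c(0, 0, 1, 1), c(0.1, 0.2, 0.7, 0.9)), 0.7)
  # constant predictions: the single cutoff has J = 0
  expect_equal(youden_cutoff(c(0, 1), c(0.5, 0.5)), 0.5)
})

test_that("percentile incidence is cumulative and concentrates planted events", {
  ey <- c(rep(NA, 90), rep(5, 10))
  p <- seq_len(100) / 100          # events carry the top predictions
  m <- percentile_incidence(ey, p, horizon = 10, n_bins = 10)
  expect_equal(unname(m[10, 10]), 1)
  expect_true(all(m[1:9, ] == 0))
  expect_true(all(diff(t(m)) >= -1e-12))  # non-decreasing in t within bins
  # null: uniform predictions and events give a roughly flat year-10 profile
  set.seed(2)
  ey2 <- ifelse(runif(2000) < 0.2, sample(1:10, 2000, TRUE), NA)
  m2 <- percentile_incidence(ey2, runif(2000), horizon = 10, n_bins = 5)
  expect_true(diff(range(m2[, 10])) < 0.1)
  expect_warning(percentile_incidence(c(NA, 1), c(0.2, 0.8), n_bins = 100),
                 "reducing bin count")
})

test_that("reclassification table matches a hand tally and normalises", {
  old <- factor(c("low", "low", "high", "high", "low", "high", "low", "low",
                  "high", "low"), levels = c("low", "high"))
  new <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  rt <- reclassification_table(old, new, y)
  expect_equal(sum(rt$events), 100)
  expect_equal(sum(rt$non_events), 100)
  expect_equal(rt$events["low", "positive"], 20)     # 1 of 5 events
  expect_equal(rt$non_events["high", "negative"], 20)
  # identical classifiers: no off-diagonal movement
  same <- reclassification_table(factor(new, levels = c(FALSE, TRUE),
                                        labels = c("neg", "pos")), new, y)
  expect_equal(same$events["neg", "positive"], 0)
  expect_equal(same$non_events["pos", "negative"], 0)
})

test_that("categorical NRI reproduces the published worked examples", {
  tabs <- published_reclassification()
  pos <- attr(tabs, "old_positive")
  expect_equal(round(categorical_nri(tabs$pce, pos$pce), 2), 0.13)
  expect_equal(round(categorical_nri(tabs$qrisk3, pos$qrisk3), 2), 0.17)
  expect_equal(round(categorical_nri(tabs$gps, pos$gps), 2), 0.11)
  # the metaGRS block's printed formula uses 16.75 where the cell prints
  # 16.78; computing from the cells gives 0.1152 (0.1149 with the printed
  # formula value)
  expect_equal(categorical_nri(tabs$metagrs, pos$metagrs), 0.1152,
               tolerance = 1e-8)
  expect_error(categorical_nri(tabs$pce, "no_such_tier"), "unknown")
})

test_that("categorical NRI is antisymmetric boundary-to-boundary", {
  # all events up-classified, all non-events unchanged (stay negative)
  ev <- matrix(c(0, 0, 100, 0), 2, 2,
               dimnames = list(c("low", "high"), c("negative", "positive")))
  ne <- matrix(c(100, 0, 0, 0), 2, 2,
               dimnames = list(c("low", "high"), c("negative", "positive")))
  rt <- structure(list(events = ev, non_events = ne, n_events = 10,
                       n_non_events = 10), class = "reclass_table")
  expect_equal(categorical_nri(rt, "high"), 1)
})

test_that("continuous NRI and IDI match hand computation and are antisymmetric", {
  y <- c(1, 1, 1, 0, 0, 0)
  p_old <- c(0.5, 0.4, 0.3, 0.3, 0.2, 0.1)
  p_new <- c(0.6, 0.3, 0.3, 0.2, 0.3, 0.1)
  # events: up 1, down 1 -> 0; non-events: down 1, up 1 -> 0
  expect_equal(continuous_nri(p_old, p_new, y), 0)
  # +0.1 to events only
  p2 <- p_old + 0.1 * y
  expect_equal(continuous_nri(p_old, p2, y), 1)
  expect_equal(continuous_nri(p_old, p_old, y), 0)
  d <- idi(p_old, p_new, y)
  slope_old <- mean(p_old[y == 1]) - mean(p_old[y == 0])
  slope_new <- mean(p_new[y == 1]) - mean(p_new[y == 0])
  expect_equal(d$idi, slope_new - slope_old)
  expect_equal(d$relative_idi, (slope_new - slope_old) / slope_old)
  expect_equal(idi(p_old, p_new, y)$idi, -idi(p_new, p_old, y)$idi)
  expect_equal(idi(p_old, p_old, y)$idi, 0)
  expect_error(idi(rep(0.3, 6), p_new, y), "slope is zero")
})

test_that("concordance index equals brute-force pair enumeration", {
  set.seed(21)
  for (i in 1:25) {
    n <- 20
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    risk <- round(runif(n), 2)
    if (sum(event) == 0) next
    expect_equal(concordance_index(risk, time, event),
                 bf_cindex(risk, time, event))
  }
  expect_equal(unname(concordance_index(rep(0.4, 10), 1:10, rep(1, 10))), 0.5)
  # perfect inverse ranking: highest risk fails first
  expect_equal(unname(concordance_index(10:1, 1:10, rep(1, 10))), 1)
})

test_that("comparator score predicts in [0,1] and uses only its predictors", {
  set.seed(3)
  df <- data.frame(age = runif(200, 40, 69), sex = rbinom(200, 1, 0.5),
                   sbp = rnorm(200, 137, 15), total_chol = rnorm(200, 5.6, 1),
                   smoking_status = sample(0:2, 200, TRUE))
  df$cad_incident <- rbinom(200, 1, plogis(-2 + 0.03 * (df$age - 55)))
  cs <- fit_comparator(df)
  p <- predict(cs, df)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, 200)
})
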