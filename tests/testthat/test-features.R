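# Feature engineering: aggregation, encoding, imputation, medications,
# derived features, polygenic scores.

test_that("repeated measures aggregate by mean / mode with smallest-value ties", {
  expect_equal(aggregate_repeated(c(120, 140), "continuous"), 130)
  expect_equal(aggregate_repeated(c(1, 2, 2), "ordinal"), 2)
  expect_equal(aggregate_repeated(c(1, 2), "ordinal"), 1)
  expect_equal(aggregate_repeated(c(NA, 3), "continuous"), 3)
  expect_true(is.na(aggregate_repeated(c(NA, NA), "ordinal")))
})

test_that("ordered target encoding matches a hand-computed running statistic", {
  # identity permutation via a seed-free check: compute expected values for
  # the permutation the encoder draws
  x <- c("a", "a", "b", "a")
  y <- c(1, 0, 1, 1)
  enc <- encode_catboost(x, y, prior_weight = 1, seed = 5)
  gm <- mean(y)
  set.seed(5); ord <- sample.int(4)
  expected <- numeric(4)
  seen <- list()
  for (pos in ord) {
    prior <- seen[[x[pos]]] %||% numeric(0)
    expected[pos] <- (sum(prior) + gm) / (length(prior) + 1)
    seen[[x[pos]]] <- c(prior, y[pos])
  }
  expect_equal(enc$encoded, expected)
  # inference map: full-data smoothed statistic; unseen -> global mean
  expect_equal(unname(enc$map["a"]), (2 + gm) / (3 + 1))
  expect_equal(apply_encoder(enc, c("zzz")), gm)
})

test_that("encoding a single category converges to the target mean", {
  set.seed(1)
  y <- rbinom(4000, 1, 0.3)
  enc <- encode_catboost(rep("only", 4000), y, seed = 2)
  expect_lt(abs(mean(enc$encoded[-(1:100)]) - mean(y)), 0.05)
  expect_warning(encode_catboost(c("a", "b"), c(1, 1)), "constant target")
})

test_that("out-of-sample encoding of pure noise does not leak the outcome", {
  set.seed(42)
  n <- 5000
  x <- sample(letters[1:20], n, replace = TRUE)
  y <- rbinom(n, 1, 0.3)        # independent of x
  folds <- metapred:::stratified_folds(y, 5, seed = 1)
  p <- numeric(n)
  for (k in 1:5) {
    tr <- folds != k
    enc <- encode_catboost(x[tr], y[tr], seed = k)
    p[!tr] <- apply_encoder(enc, x[!tr])
  }
  expect_lt(auroc(y, p, n_boot = 0)$estimate, 0.55)
})

test_that("chained imputation drops, forces and never touches observed cells", {
  set.seed(9)
  n <- 600
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  df$b[sample(n, 150)] <- NA       # 25% -> dropped unless forced
  df$c[sample(n, 60)] <- NA        # 10% -> imputed
  obs_c <- which(!is.na(df$c))
  out <- impute_chained(df, n_iterations = 2, num_trees = 10, seed = 1)
  expect_named(out$dropped, "b")
  expect_false("b" %in% names(out$data))
  expect_identical(out$data$c[obs_c], df$c[obs_c])
  expect_false(anyNA(out$data$c))
  # imputed values stay inside the observed range
  expect_true(all(out$data$c >= min(df$c, na.rm = TRUE) &
                    out$data$c <= max(df$c, na.rm = TRUE)))
  # forcing keeps the high-missingness feature
  out2 <- impute_chained(df, forced = "b", n_iterations = 2, num_trees = 10,
                         seed = 1)
  expect_true("b" %in% names(out2$data))
  expect_false(anyNA(out2$data$b))
  # no missing values: returned unchanged
  clean <- data.frame(a = rnorm(10), b = rnorm(10))
  expect_identical(impute_chained(clean)$data, clean)
  df$d[] <- NA
  expect_error(impute_chained(df), "100% missingness")
})

test_that("MCAR imputation preserves the feature mean", {
  set.seed(11)
  n <- 5000
  df <- data.frame(x = rnorm(n, 10, 2), z1 = rnorm(n), z2 = rnorm(n))
  df$x <- df$x + 0.8 * df$z1
  miss <- sample(n, 500)
  truth <- df$x
  df$x[miss] <- NA
  out <- impute_chained(df, n_iterations = 2, num_trees = 20, seed = 3)
  expect_lt(abs(mean(out$data$x) - mean(truth)) / sd(truth), 0.1)
})

test_that("medication keyword flags are case-insensitive and independent", {
  flags <- match_medications(c("Atorvastatin 20mg", "", "aspirin;METFORMIN 500mg"))
  expect_equal(flags$med_cholesterol, c(1, 0, 0))
  expect_equal(flags$med_antiplatelet, c(0, 0, 1))
  expect_equal(flags$med_metformin, c(0, 0, 1))
  # one keyword can set several classes
  reg <- list(class_a = "statin", class_b = "atorva")
  f2 <- match_medications("Atorvastatin", reg)
  expect_equal(unlist(f2), c(class_a = 1, class_b = 1))
  expect_error(match_medications("x", list()), "empty registry")
})

test_that("derived features compute ratios and guard division by zero", {
  df <- data.frame(waist = c(80, 90), hip = c(100, 0),
                   total_chol = c(5, 6), hdl = c(1.25, 1.5))
  out <- suppressWarnings(derive_features(df))
  expect_equal(out$whr[1], 0.8)
  expect_true(is.na(out$whr[2]))
  expect_equal(out$chol_hdl_ratio[1], 4)
  expect_warning(derive_features(df), "non-finite")
})

test_that("polygenic scores are standardized weighted allele sums", {
  dos <- matrix(c(0, 1, 2), 3, 3,
                dimnames = list(NULL, c("v1", "v2", "v3")))
  dos[, 2] <- c(1, 0, 2); dos[, 3] <- c(2, 2, 0)
  def <- prs_definition("s", c("v1", "v2", "v3"), c("A", "A", "A"),
                        c(0.5, -1, 0.2))
  z <- compute_prs(dos, def)
  raw <- attr(z, "raw")
  expect_equal(raw[1], 0 * 0.5 - 1 * 1 + 2 * 0.2)   # -0.6 by hand
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # linearity: scaling weights scales raw scores, standardized invariant
  def2 <- prs_definition("s2", def$variant_ids, def$effect_alleles,
                         3 * def$weights)
  z2 <- compute_prs(dos, def2)
  expect_equal(attr(z2, "raw"), 3 * raw)
  expect_equal(as.numeric(z2), as.numeric(z))
  # allele flip counts 2 - dosage
  flip <- prs_definition("f", "v1", "T", 1)
  zf <- compute_prs(dos, flip, effect_alleles = c(v1 = "A", v2 = "A", v3 = "A"))
  expect_equal(attr(zf, "raw"), 2 - dos[, "v1"])
  # degenerate: zero weights -> zeros with warning
  expect_warning(z0 <- compute_prs(dos, prs_definition("z", "v1", "A", 0)),
                 "zero variance")
  expect_true(all(z0 == 0))
  expect_error(compute_prs(dos, prs_definition("m", "nope", "A", 1)), "absent")
})

test_that("registry provenance filter drops evaluation-biobank scores", {
  defs <- list(prs_definition("a", "v1", "A", 1),
               prs_definition("b", "v1", "A", 1, ukb_derived = TRUE),
               prs_definition("c", "v1", "A", 1, ukb_derived = TRUE),
               prs_definition("d", "v1", "A", 1))
  kept <- filter_prs_registry(defs)
  expect_length(kept, 2)
  expect_equal(attr(kept, "n_dropped"), 2)
  none <- filter_prs_registry(defs[c(1, 4)])
  expect_length(none, 2)
})

test_that("feature schema partitions every feature into exactly one scope", {
  co <- small_cohort(n = 300, seed = 3)
  fx <- build_features(co, impute = FALSE)
  sch <- fx$schema
  expect_setequal(sch$name, setdiff(names(fx$features), "id"))
  expect_true(all(sch$scope %in% c("unmodifiable", "modifiable")))
  expect_true(all(sch$scope[grepl("^prs_", sch$name)] == "unmodifiable"))
  expect_true(all(sch$scope[sch$name %in% c("age", "sex", "fh_heart_disease")] ==
                    "unmodifiable"))
  expect_true(all(sch$scope[sch$name %in% c("ldl", "sbp", "smoking_status",
                                            "med_insulin")] == "modifiable"))
})
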