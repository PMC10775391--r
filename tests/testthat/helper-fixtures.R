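# Shared fixtures: tiny cohorts and boosters built in code at test time.

# Small synthetic cohort, memoised per (n, seed) within a test run.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(n = 1500, seed = 42, ...) {
  key <- paste0("cohort_", n, "_", seed, "_", length(list(...)))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(
      sim_config(n_individuals = n, n_variants = 80, seed = seed, ...))
  .fixture_env[[key]]
}

# A small fitted booster on simulated data with a known strong feature.
toy_booster <- function(n = 400, p = 4, task = "classification", seed = 7,
                        nrounds = 20, max_depth = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- if (task == "classification") rbinom(n, 1, plogis(1.5 * X[, 1]))
  else 2 * X[, 1] + rnorm(n, 0, 0.3)
  params <- list(objective = if (task == "classification") "binary:logistic"
                 else "reg:squarederror",
                 max_depth = max_depth, eta = 0.3, nthread = 1)
  b <- xgboost::xgb.train(params = params,
                          data = xgboost::xgb.DMatrix(X, label = y),
                          nrounds = nrounds)
  list(booster = b, X = X, y = y)
}

# One small end-to-end pipeline run shared across model-level tests.
small_pipeline <- function(seed = 77) {
  key <- paste0("pipe_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- suppressWarnings(run_pipeline(
      sim_config(n_individuals = 2500, n_variants = 80, seed = seed),
      diagnoses = c("cad", "t2d"), biomarkers = "ldl",
      stage1_budget = fit_budget(bounds_grid = c(5, 10), cv_folds = 3,
                                 nrounds = 40, cv_nrounds = 30),
      final_budget = fit_budget(bounds_grid = c(10, 20), cv_folds = 3,
                                tune_trials = 2, nrounds = 80, cv_nrounds = 40,
                                base_params = list(eta = 0.1, max_depth = 2),
                                bag = 2)))
  }
  .fixture_env[[key]]
}

# Brute-force AUROC over all case-control pairs (independent oracle).
bf_auroc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Brute-force Harrell concordance (independent oracle).
bf_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    if (ti == tj) {
      # comparable only when exactly one is an event (the censored one is
      # known to have outlived the event)
      if (event[i] + event[j] != 1) next
      first <- if (event[i]) i else j
      second <- if (event[i]) j else i
    } else {
      first <- if (ti < tj) i else j
      second <- if (ti < tj) j else i
      if (!event[first]) next
    }
    den <- den + 1
    if (risk[first] > risk[second]) num <- num + 1
    else if (risk[first] == risk[second]) num <- num + 0.5
  }
  num / den
}

# Independent oracle for Saabas attribution: walk one row through every tree
# of the dump, attributing cover-weighted node-mean changes to split features.
oracle_saabas <- function(model, X) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  X[] <- metapred:::float32(X)   # single-precision routing, as the library
  dump$Split <- metapred:::float32(dump$Split)
  p <- ncol(X)
  contrib <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))
  node_val <- function(nodes, nid) {
    nd <- nodes[nodes$ID == nid, ]
    if (nd$Feature == "Leaf") return(nd$Gain)
    vy <- node_val(nodes, nd$Yes); vn <- node_val(nodes, nd$No)
    cy <- nodes$Cover[nodes$ID == nd$Yes]; cn <- nodes$Cover[nodes$ID == nd$No]
    (cy * vy + cn * vn) / (cy + cn)
  }
  roots <- 0
  leaf_sum <- numeric(nrow(X))
  for (tr in unique(dump$Tree)) {
    nodes <- dump[dump$Tree == tr, ]
    root <- nodes$ID[nodes$Node == 0]
    roots <- roots + node_val(nodes, root)
    for (i in seq_len(nrow(X))) {
      nid <- root
      repeat {
        nd <- nodes[nodes$ID == nid, ]
        if (nd$Feature == "Leaf") { leaf_sum[i] <- leaf_sum[i] + nd$Gain; break }
        child <- if (X[i, nd$Feature] < nd$Split) nd$Yes else nd$No
        contrib[i, nd$Feature] <- contrib[i, nd$Feature] +
          node_val(nodes, child) - node_val(nodes, nid)
        nid <- child
      }
    }
  }
  list(contrib = contrib, roots = roots, leaf_sum = leaf_sum)
}

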