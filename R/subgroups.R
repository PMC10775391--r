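# Risk-subgroup discovery: clustering cases by attribution vectors, eta^2
# feature ranking, and probabilistic control assignment.

#' Attribution matrix of the final model over case rows
#'
#' Exact tree-SHAP contributions (raw margin space) of the fitted stacked
#' model for the supplied rows, averaged over the bagged boosters, with the
#' model's prior-correction offset folded into the base value. Satisfies
#' local accuracy against the ensemble's corrected margin within 1e-6.
#'
#' @param model a fitted [metapred()]
#' @param X_cases data.frame/matrix holding the model's feature columns for
#'   the case rows
#' @return an `attribution_matrix`
#' @export
attribution_matrix <- function(model, X_cases) {
  stopifnot(inherits(model, "metapred"))
  X <- as.data.frame(X_cases)
  missing <- setdiff(model$features, names(X))
  if (length(missing))
    stopf("attribution_matrix: missing feature(s): %s",
          paste(missing, collapse = ", "))
  Xm <- as.matrix(X[, model$features, drop = FALSE])
  parts <- lapply(model$boosters, function(b) shap_attribute(b, Xm))
  contrib <- Reduce(`+`, lapply(parts, `[[`, "contributions")) / length(parts)
  base <- mean(vapply(parts, `[[`, numeric(1), "base")) +
    (model$margin_offset %||% 0)
  structure(list(contributions = contrib, base = base,
                 features = model$features), class = "attribution_matrix")
}

#' Cluster cases by their attribution vectors
#'
#' Agglomerative hierarchical clustering with Ward's linkage on Euclidean
#' distances between per-case attribution vectors (used unscaled: all
#' contributions share the model-output unit). The tree is cut either at a
#' fixed height or into `k` groups; labels are renumbered by decreasing
#' group-mean predicted risk (group 1 = highest risk).
#'
#' @param attr an `attribution_matrix` over cases
#' @param k number of groups (default 5)
#' @param h fixed cut height (overrides `k` when given)
#' @return integer labels, with the `hclust` tree in attribute `tree`
#' @export
cluster_cases <- function(attr, k = 5, h = NULL) {
  stopifnot(inherits(attr, "attribution_matrix"))
  M <- attr$contributions
  if (is.null(h) && k > nrow(M)) stopf("cluster_cases: k exceeds the number of cases")
  tree <- stats::hclust(stats::dist(M, method = "euclidean"),
                        method = "ward.D2")
  labels <- if (!is.null(h)) stats::cutree(tree, h = h)
  else stats::cutree(tree, k = k)
  risk <- stats::plogis(attr$base + rowSums(M))
  mean_risk <- tapply(risk, labels, mean)
  remap <- match(labels, as.integer(names(sort(mean_risk, decreasing = TRUE))))
  structure(remap, tree = tree)
}

#' One-way ANOVA effect size
#'
#' `eta^2 = SS_between / SS_total` of the values across the grouping.
#'
#' @param values numeric vector
#' @param labels group labels (>= 2 groups)
#' @return eta squared in `[0, 1]`
#' @export
eta_squared <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stopf("eta_squared: need >= 2 groups")
  sst <- sum((values - mean(values))^2)
  if (sst == 0) stopf("eta_squared: zero total variance")
  gm <- tapply(values, labels, mean)
  gn <- tapply(values, labels, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssb / sst
}

#' Rank features by eta-squared across subgroups
#'
#' Features whose one-way ANOVA effect size exceeds 0.01 are returned in
#' descending order with conventional tier annotations: large (eta^2 >=
#' 0.14), moderate (0.14 > eta^2 >= 0.06), small otherwise.
#'
#' @param feature_table data.frame of numeric features over the clustered
#'   cases
#' @param labels subgroup labels from [cluster_cases()]
#' @param min_eta reporting threshold
#' @return data.frame: feature, eta2, tier
#' @export
rank_features_by_eta <- function(feature_table, labels, min_eta = 0.01) {
  feature_table <- as.data.frame(feature_table)
  e2 <- vapply(feature_table, function(v) {
    if (stats::sd(v) == 0) return(0)
    eta_squared(v, labels)
  }, numeric(1))
  keep <- e2 > min_eta
  out <- data.frame(feature = names(e2)[keep], eta2 = unname(e2[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$eta2), , drop = FALSE]
  out$tier <- ifelse(out$eta2 >= 0.14, "large",
                     ifelse(out$eta2 >= 0.06, "moderate", "small"))
  rownames(out) <- NULL
  out
}

#' Assign controls to case subgroups
#'
#' Trains a multiclass gradient-boosted classifier on the cases (same
#' features as the clustering) and assigns each control to the argmax class
#' iff its probability strictly exceeds `prob_threshold`; otherwise the
#' control stays unassigned (`NA`).
#'
#' @param case_features data.frame of features over the cases
#' @param case_labels subgroup labels of the cases
#' @param control_features features over the controls
#' @param prob_threshold strict assignment threshold (default 0.5)
#' @param nrounds,seed classifier settings
#' @return integer labels with `NA` for unassigned controls; assignment
#'   probabilities in attribute `prob`
#' @export
assign_controls <- function(case_features, case_labels, control_features,
                            prob_threshold = 0.5, nrounds = 80, seed = 1L) {
  k <- length(unique(case_labels))
  if (k < 2) stopf("assign_controls: need >= 2 case classes")
  cols <- names(as.data.frame(case_features))
  params <- list(objective = "multi:softprob", num_class = k,
                 eval_metric = "mlogloss", eta = 0.15, max_depth = 3,
                 nthread = 1, seed = as.integer(seed))
  dm <- xgboost::xgb.DMatrix(as.matrix(case_features),
                             label = as.integer(factor(case_labels)) - 1L)
  fit <- xgboost::xgb.train(params = params, data = dm, nrounds = nrounds,
                            verbose = 0)
  pr <- stats::predict(fit, xgboost::xgb.DMatrix(
    as.matrix(as.data.frame(control_features)[, cols, drop = FALSE])))
  if (!is.matrix(pr)) pr <- matrix(pr, ncol = k, byrow = TRUE)
  colnames(pr) <- levels(factor(case_labels))
  best <- max.col(pr)
  lab <- as.integer(colnames(pr)[best])
  lab[pr[cbind(seq_len(nrow(pr)), best)] <= prob_threshold] <- NA_integer_
  structure(lab, prob = pr)
}
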