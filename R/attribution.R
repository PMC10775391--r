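# Per-feature attribution for gradient-boosted tree ensembles: a reference
# Saabas path-walk implementation, fast library-backed variants, and
# attribution-based feature pre-selection.

#' Saabas path attribution for an xgboost ensemble
#'
#' Walks each row's decision path in every tree and attributes the change in
#' the (cover-weighted) node mean prediction at each split to the split
#' feature; contributions are summed over trees. The base value is the
#' ensemble's expected output (sum of root means plus the model's intercept),
#' so `base + rowSums(contributions)` equals the raw margin prediction
#' exactly for path-additive trees (local accuracy).
#'
#' `method = "fast"` delegates to xgboost's built-in approximate-contribution
#' predictor (the same algorithm in compiled code); `"reference"` runs the
#' package's own path walk over the parsed tree dump. Both satisfy the same
#' local-accuracy contract and agree to numerical precision.
#'
#' @param model an `xgb.Booster` fitted on named features
#' @param X numeric matrix with the training feature columns
#' @param method "fast" (library) or "reference" (own path walk)
#' @return object of class `attribution_matrix`: list with `contributions`
#'   (n x p), `base` (scalar expected margin), `features`
#' @export
saabas_attribute <- function(model, X, method = c("fast", "reference")) {
  method <- match.arg(method)
  if (!inherits(model, "xgb.Booster"))
    stopf("saabas_attribute: unsupported model (need an xgb.Booster with node statistics)")
  X <- as.matrix(X)
  if (method == "fast") {
    ctr <- stats::predict(model, xgboost::xgb.DMatrix(X),
                          predcontrib = TRUE, approxcontrib = TRUE)
    return(new_attribution(ctr, colnames(X)))
  }
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  # route exactly as the library does: single-precision comparisons on both
  # the feature value and the parsed split threshold
  X[] <- float32(X)
  dump$Split <- float32(dump$Split)
  contrib <- matrix(0, nrow(X), ncol(X), dimnames = list(NULL, colnames(X)))
  root_sum <- 0
  leaf_val <- numeric(nrow(X))
  for (tr in unique(dump$Tree)) {
    nodes <- dump[dump$Tree == tr, , drop = FALSE]
    rownames(nodes) <- nodes$ID
    value <- node_means(nodes)
    root_id <- nodes$ID[nodes$Node == 0]
    root_sum <- root_sum + value[[root_id]]
    cur <- rep(root_id, nrow(X))
    active <- !is.na(nodes[cur, "Feature"]) & nodes[cur, "Feature"] != "Leaf"
    while (any(active)) {
      for (nid in unique(cur[active])) {
        rows <- which(cur == nid & active)
        nd <- nodes[nid, ]
        xv <- X[rows, nd$Feature]
        child <- ifelse(is.na(xv), nd$Missing,
                        ifelse(xv < nd$Split, nd$Yes, nd$No))
        contrib[rows, nd$Feature] <- contrib[rows, nd$Feature] +
          value[child] - value[[nid]]
        cur[rows] <- child
      }
      active <- nodes[cur, "Feature"] != "Leaf"
    }
    leaf_val <- leaf_val + value[cur]
  }
  # model intercept (base margin): constant linking summed leaf values to the
  # margin prediction; recovered from a single probe row
  margin1 <- stats::predict(model, xgboost::xgb.DMatrix(X[1, , drop = FALSE]),
                            outputmargin = TRUE)
  intercept <- unname(margin1 - leaf_val[1])
  structure(list(contributions = contrib, base = root_sum + intercept,
                 features = colnames(X),
                 # double-precision ensemble margin (sum of routed leaf
                 # values), against which local accuracy holds exactly
                 margin = unname(leaf_val + intercept)),
            class = "attribution_matrix")
}

# Cover-weighted node mean predictions for one tree of an xgboost dump.
node_means <- function(nodes) {
  value <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$ID)
  fill <- function(nid) {
    nd <- nodes[nid, ]
    if (nd$Feature == "Leaf") {
      value[[nid]] <<- nd$Gain     # leaf weight is stored in the Gain column
    } else {
      fill(nd$Yes); fill(nd$No)
      cy <- nodes[nd$Yes, "Cover"]; cn <- nodes[nd$No, "Cover"]
      value[[nid]] <<- (cy * value[[nd$Yes]] + cn * value[[nd$No]]) / (cy + cn)
    }
  }
  fill(nodes$ID[nodes$Node == 0])
  value
}

# Round doubles to their nearest float32 representation (tree thresholds and
# feature values are compared in single precision inside xgboost).
float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), what = "numeric",
          size = 4L, n = length(v))
}

new_attribution <- function(ctr, features) {
  p <- length(features)
  structure(list(contributions = ctr[, seq_len(p), drop = FALSE],
                 base = unname(ctr[1, p + 1L]),
                 features = features), class = "attribution_matrix")
}

#' Exact tree-SHAP attribution
#'
#' Library-provided exact Shapley contributions in raw margin space; shares
#' the local-accuracy contract of [saabas_attribute()].
#'
#' @inheritParams saabas_attribute
#' @return an `attribution_matrix`
#' @export
shap_attribute <- function(model, X) {
  X <- as.matrix(X)
  ctr <- stats::predict(model, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  new_attribution(ctr, colnames(X))
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("Attribution matrix: %d rows x %d features, base = %.4f\n",
              nrow(x$contributions), length(x$features), x$base))
  top <- sort(colMeans(abs(x$contributions)), decreasing = TRUE)
  cat("Top mean |contribution|:\n")
  print(round(utils::head(top, 5), 4))
  invisible(x)
}

#' Check local accuracy of an attribution matrix
#'
#' @param attr an `attribution_matrix`
#' @param margin raw margin predictions for the same rows
#' @return maximum absolute reconstruction error
#' @export
local_accuracy_error <- function(attr, margin) {
  max(abs(attr$base + rowSums(attr$contributions) - margin))
}

#' Pre-select the top-k features by mean absolute contribution
#'
#' Features are ranked by the mean absolute attribution over the supplied
#' rows; ties break lexicographically by feature name.
#'
#' @param attr an `attribution_matrix` computed on training rows
#' @param k number of features to keep
#' @return ordered character vector of `min(k, p)` feature names
#' @export
preselect_top_k <- function(attr, k = 200) {
  stopifnot(inherits(attr, "attribution_matrix"))
  imp <- colMeans(abs(attr$contributions))
  ord <- order(-imp, attr$features)
  attr$features[ord][seq_len(min(k, length(imp)))]
}
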