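# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from one global
#' seed so that stages are independently reproducible. Kept below 2^31 - 1.
#'
#' @param seed global integer seed
#' @param stage character tag of the stage
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' @param y outcome (binary vector, or anything coercible to factor for
#'   classification; continuous values are binned into quintiles)
#' @param k number of folds
#' @param seed integer seed
#' @return integer vector of fold ids in 1..k
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  if (is.numeric(y) && length(unique(y)) > 10) {
    br <- unique(stats::quantile(y, probs = seq(0, 1, length.out = 6), na.rm = TRUE))
    y <- cut(y, breaks = br, include.lowest = TRUE)
  }
  y <- as.factor(y)
  fold <- integer(length(y))
  rs <- restore_seed(seed)
  on.exit(rs())
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Set the RNG to `seed`, returning a function that restores the prior state.
restore_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# Largest-remainder apportionment of `total` items proportional to `weights`.
largest_remainder <- function(total, weights) {
  if (total == 0) return(rep(0L, length(weights)))
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    take <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
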