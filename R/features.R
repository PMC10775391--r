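# Feature engineering: aggregation, ordered target encoding, chained
# imputation, medication keyword flags, derived features, and the
# unmodifiable/modifiable feature schema.

#' Aggregate repeated measurements
#'
#' Continuous measures take the mean; ordinal measures take the mode (ties
#' resolve to the smallest value). Missing entries are dropped first; an
#' all-missing input aggregates to `NA`.
#'
#' @param values numeric vector of repeated measurements
#' @param kind "continuous" or "ordinal"
#' @return a scalar
#' @export
aggregate_repeated <- function(values, kind = c("continuous", "ordinal")) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  if (kind == "continuous") return(mean(values))
  tab <- table(values)
  as.numeric(names(tab)[which.max(tab)])  # ties: first = smallest value
}

#' Ordered target encoding for a categorical column
#'
#' Each training value is replaced by the running target statistic over
#' prior-ordered rows of the same category (one random permutation per seed),
#' smoothed towards the global mean with weight `prior_weight`:
#' `(sum_prior + prior_weight * global_mean) / (count_prior + prior_weight)`.
#' The returned encoder maps categories seen at inference to their full-data
#' smoothed statistic; unseen categories fall back to the global mean.
#'
#' @param x categorical column (factor or character)
#' @param y binary or continuous target
#' @param prior_weight smoothing weight of the global mean
#' @param seed integer seed for the ordering permutation
#' @return list with `encoded` (training column), `map` (category ->
#'   inference encoding), `global_mean`
#' @export
encode_catboost <- function(x, y, prior_weight = 1, seed = 1L) {
  stopifnot(length(x) == length(y))
  x <- as.character(x)
  y <- as.numeric(y)
  gm <- mean(y)
  if (stats::var(y) == 0) {
    warnf("encode_catboost: constant target; returning the global mean")
    map <- stats::setNames(rep(gm, length(unique(x))), unique(x))
    return(list(encoded = rep(gm, length(x)), map = map, global_mean = gm))
  }
  rs <- restore_seed(seed); on.exit(rs())
  ord <- sample.int(length(x))
  enc <- numeric(length(x))
  xo <- x[ord]; yo <- y[ord]
  for (lv in unique(xo)) {
    pos <- which(xo == lv)
    cs <- cumsum(yo[pos]) - yo[pos]          # target sum over prior rows
    cnt <- seq_along(pos) - 1
    enc[ord[pos]] <- (cs + prior_weight * gm) / (cnt + prior_weight)
  }
  stats_full <- tapply(y, x, function(v) c(sum(v), length(v)))
  map <- vapply(stats_full, function(s) (s[1] + prior_weight * gm) /
                  (s[2] + prior_weight), numeric(1))
  list(encoded = enc, map = map, global_mean = gm)
}

#' Apply a fitted ordered target encoder to new data
#'
#' @param encoder result of [encode_catboost()]
#' @param x new categorical column
#' @return numeric encoding; unseen categories receive the global mean
#' @export
apply_encoder <- function(encoder, x) {
  x <- as.character(x)
  out <- unname(encoder$map[x])
  out[is.na(out)] <- encoder$global_mean
  out
}

#' Chained imputation with tree-based conditional models
#'
#' Iteratively imputes each incomplete feature from all other retained
#' features using random-forest regression/classification ([ranger::ranger]),
#' visiting features in order of increasing missingness for
#' `n_iterations` sweeps. Features missing in more than `max_missing` of rows
#' are dropped unless listed in `forced`; features in `excluded` (typically
#' medication flags) are neither imputed nor used as predictors. Observed
#' cells are never altered, and tree predictions keep imputed values inside
#' each feature's observed range.
#'
#' @param table data.frame of numeric features (non-numeric columns are not
#'   supported; encode first)
#' @param max_missing drop threshold on the per-feature missing fraction
#' @param forced features imputed regardless of their missingness rate
#' @param excluded features left untouched and unused as predictors
#' @param n_iterations number of chained sweeps
#' @param num_trees trees per conditional forest
#' @param seed integer seed
#' @return list with `data` (completed table, dropped columns removed),
#'   `dropped` (named reasons), and `diagnostics` (per-feature pre/post
#'   mean and sd)
#' @export
impute_chained <- function(table, max_missing = 0.20, forced = character(),
                           excluded = character(), n_iterations = 5,
                           num_trees = 25, seed = 1L) {
  stopifnot(is.data.frame(table))
  numcols <- vapply(table, is.numeric, logical(1))
  if (!all(numcols)) stopf("impute_chained: non-numeric column(s): %s",
                           paste(names(table)[!numcols], collapse = ", "))
  miss <- vapply(table, function(c) mean(is.na(c)), numeric(1))
  if (any(miss == 1))
    stopf("feature(s) with 100%% missingness: %s",
          paste(names(miss)[miss == 1], collapse = ", "))
  drop <- names(miss)[miss > max_missing & !(names(miss) %in% forced) &
                        !(names(miss) %in% excluded)]
  dropped <- stats::setNames(
    rep(sprintf("exceeds %d%% missingness", round(100 * max_missing)),
        length(drop)), drop)
  keep <- setdiff(names(table), drop)
  dat <- table[keep]
  targets <- names(miss[keep])[miss[keep] > 0 & !(keep %in% excluded)]
  targets <- targets[order(miss[targets])]
  pre <- lapply(dat[targets], function(c) c(mean = mean(c, na.rm = TRUE),
                                            sd = stats::sd(c, na.rm = TRUE)))
  if (length(targets)) {
    preds_all <- setdiff(keep, excluded)
    na_idx <- lapply(dat[targets], function(c) which(is.na(c)))
    # initial fill: median
    for (f in targets)
      dat[[f]][na_idx[[f]]] <- stats::median(dat[[f]], na.rm = TRUE)
    rs <- restore_seed(seed); on.exit(rs())
    for (it in seq_len(n_iterations)) {
      for (f in targets) {
        idx <- na_idx[[f]]
        if (!length(idx)) next
        preds <- setdiff(preds_all, f)
        obs <- setdiff(seq_len(nrow(dat)), idx)
        fit <- ranger::ranger(
          x = dat[obs, preds, drop = FALSE], y = table[[f]][obs],
          num.trees = num_trees, seed = sample.int(1e6, 1),
          num.threads = 1, verbose = FALSE)
        dat[[f]][idx] <- stats::predict(
          fit, dat[idx, preds, drop = FALSE], num.threads = 1)$predictions
      }
    }
  }
  post <- lapply(dat[targets], function(c) c(mean = mean(c), sd = stats::sd(c)))
  diag <- if (length(targets)) data.frame(
    feature = targets,
    missing_fraction = unname(miss[targets]),
    mean_observed = vapply(pre, `[[`, numeric(1), "mean"),
    sd_observed = vapply(pre, `[[`, numeric(1), "sd"),
    mean_completed = vapply(post, `[[`, numeric(1), "mean"),
    sd_completed = vapply(post, `[[`, numeric(1), "sd"),
    row.names = NULL) else data.frame()
  list(data = dat, dropped = dropped, diagnostics = diag)
}

#' Default medication keyword registry
#'
#' Maps medication classes to drug-name keywords matched case-insensitively
#' as substrings of free-text medication entries.
#'
#' @return named list of keyword vectors
#' @export
default_medication_registry <- function() {
  list(
    med_cholesterol = c("statin", "ezetimibe"),
    med_antihypertensive = c("ramipril", "amlodipine", "losartan",
                             "bendroflumethiazide", "lisinopril"),
    med_metformin = "metformin",
    med_insulin = "insulin",
    med_antiplatelet = c("aspirin", "clopidogrel"),
    med_hrt = c("estradiol", "estrogen"))
}

#' Binary medication-class flags from free-text drug lists
#'
#' A flag is true iff any registry keyword is a case-insensitive substring of
#' any listed drug name. Flags are independent: one drug may set several
#' classes.
#'
#' @param free_text character vector of semicolon-separated drug names (or a
#'   list of character vectors)
#' @param keyword_registry named list: class -> keyword vector
#' @return data.frame of 0/1 flags, one column per class
#' @export
match_medications <- function(free_text,
                              keyword_registry = default_medication_registry()) {
  if (!length(keyword_registry)) stopf("match_medications: empty registry")
  if (is.list(free_text))
    free_text <- vapply(free_text, paste, character(1), collapse = ";")
  txt <- tolower(free_text)
  txt[is.na(txt)] <- ""
  out <- lapply(keyword_registry, function(kws) {
    hit <- rep(FALSE, length(txt))
    for (kw in kws) hit <- hit | grepl(tolower(kw), txt, fixed = TRUE)
    as.integer(hit)
  })
  as.data.frame(out)
}

#' Default derived-feature registry
#'
#' Quoted formulas evaluated on the post-imputation feature table.
#'
#' @return named list of quoted expressions
#' @export
default_derived_registry <- function() {
  list(whr = quote(waist / hip),
       chol_hdl_ratio = quote(total_chol / hdl),
       non_hdl_chol = quote(total_chol - hdl))
}

#' Append derived (combination) features
#'
#' Evaluates each registered formula on the table and appends the result.
#' Non-finite results (e.g. division by zero) become missing values with a
#' warning.
#'
#' @param table data.frame holding the formula inputs (post-imputation)
#' @param registry named list of quoted expressions, as
#'   [default_derived_registry()]
#' @return the table with appended columns
#' @export
derive_features <- function(table, registry = default_derived_registry()) {
  for (nm in names(registry)) {
    v <- eval(registry[[nm]], envir = table)
    bad <- !is.finite(v) & !is.na(v)
    if (any(bad)) {
      warnf("derive_features: '%s' non-finite in %d row(s); set to NA", nm, sum(bad))
      v[bad] <- NA
    }
    table[[nm]] <- v
  }
  table
}

#' Polygenic score definition
#'
#' @param id score identifier
#' @param variant_ids,effect_alleles,weights aligned per-variant vectors
#' @param ukb_derived provenance flag: derived from the evaluation biobank
#' @return object of class `prs_definition`
#' @export
prs_definition <- function(id, variant_ids, effect_alleles, weights,
                           ukb_derived = FALSE) {
  stopifnot(length(variant_ids) == length(weights),
            length(effect_alleles) == length(weights))
  if (any(!is.finite(weights))) stopf("prs_definition: non-finite weights")
  structure(list(id = id, variant_ids = variant_ids,
                 effect_alleles = effect_alleles, weights = weights,
                 ukb_derived = isTRUE(ukb_derived)), class = "prs_definition")
}

#' Read a polygenic-score weight file
#'
#' Tab-delimited with a header and `#` comment lines: columns `variant_id`,
#' `effect_allele`, `weight`.
#'
#' @param path file path
#' @param id score id (defaults to the file name)
#' @param ukb_derived provenance flag
#' @return a [prs_definition()]
#' @export
read_prs_weights <- function(path, id = NULL, ukb_derived = FALSE) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "effect_allele", "weight") %in% names(tab)))
  prs_definition(id %||% sub("\\.[^.]*$", "", basename(path)),
                 tab$variant_id, tab$effect_allele, tab$weight, ukb_derived)
}

#' Compute a standardized polygenic risk score
#'
#' The raw score is the weighted sum of effect-allele dosages; records whose
#' effect allele disagrees with the dosage matrix's effect allele are counted
#' as `2 - dosage`. The returned score is standardized to mean 0, sd 1 over
#' the cohort; a zero-variance raw score yields all zeros with a warning.
#'
#' @param dosages `n x m` dosage matrix with variant column names
#' @param prs_def a [prs_definition()]
#' @param effect_alleles optional named vector: the dosage matrix's counted
#'   allele per variant (omit to assume alignment)
#' @return standardized score vector with the raw score in attribute `raw`
#' @export
compute_prs <- function(dosages, prs_def, effect_alleles = NULL) {
  stopifnot(inherits(prs_def, "prs_definition"))
  missing <- setdiff(prs_def$variant_ids, colnames(dosages))
  if (length(missing))
    stopf("compute_prs: variant(s) absent from dosage matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  d <- dosages[, prs_def$variant_ids, drop = FALSE]
  if (!is.null(effect_alleles)) {
    flip <- effect_alleles[prs_def$variant_ids] != prs_def$effect_alleles
    if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  }
  raw <- as.numeric(d %*% prs_def$weights)
  s <- stats::sd(raw)
  if (s == 0) {
    warnf("compute_prs: '%s' has zero variance; returning zeros", prs_def$id)
    z <- rep(0, length(raw))
  } else z <- (raw - mean(raw)) / s
  attr(z, "raw") <- raw
  z
}

#' Filter a PRS registry by provenance
#'
#' Drops scores flagged as derived from the evaluation cohort's own biobank
#' (to prevent overfitting through score reuse).
#'
#' @param defs list of [prs_definition()]
#' @return the retained list, with the dropped count in attribute `n_dropped`
#' @export
filter_prs_registry <- function(defs) {
  flagged <- vapply(defs, function(d) d$ukb_derived, logical(1))
  structure(defs[!flagged], n_dropped = sum(flagged))
}

#' Feature schema: scope and kind per feature
#'
#' Age, sex, ancestry fractions, family history and polygenic scores are
#' unmodifiable; biomarkers, lifestyle and medication flags are modifiable.
#' Scopes are exhaustive and exclusive over the supplied names.
#'
#' @param feature_names character vector of model feature names
#' @return data.frame: `name`, `kind`, `scope`
#' @export
feature_schema <- function(feature_names) {
  unmod <- grepl("^(prs_|meta_)", feature_names) |
    feature_names %in% c("age", "sex", "fh_heart_disease") |
    grepl("^ancestry_", feature_names)
  # meta_* columns are handled separately by scope validation; mark them here
  # so the schema stays exhaustive when meta-features join the design.
  kind <- ifelse(feature_names %in% c("sex", "fh_heart_disease") |
                   grepl("^med_", feature_names), "binary",
                 ifelse(feature_names == "smoking_status", "ordinal",
                        "continuous"))
  data.frame(name = feature_names, kind = kind,
             scope = ifelse(unmod, "unmodifiable", "modifiable"),
             stringsAsFactors = FALSE)
}

#' Build the model-ready feature matrix from a synthetic cohort
#'
#' Applies the full feature-engineering path: medication keyword flags,
#' drop/impute by the missingness rule, derived features, and standardized
#' polygenic scores from the cohort's weight sets. Returns a numeric feature
#' table keyed by id together with its schema.
#'
#' @param cohort a `sim_cohort` (possibly after [plant_missingness()])
#' @param impute run chained imputation (set `FALSE` for complete data)
#' @param forced features imputed despite exceeding the missingness cap
#' @param n_iterations,num_trees imputation budget, see [impute_chained()]
#' @param seed integer seed
#' @return list with `features` (data.frame, first column `id`), `schema`,
#'   and `imputation` diagnostics
#' @export
build_features <- function(cohort, impute = TRUE,
                           forced = c("pack_years", "smoking_status"),
                           n_iterations = 3, num_trees = 20, seed = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  seed <- seed %||% derive_seed(cohort$config$seed, "features")
  bl <- cohort$baseline
  meds <- match_medications(bl$medications)
  drop_cols <- c("id", "medications", "enrol_date", "birth_date",
                 "followup_years", "n_ehr_entries", "death_other")
  feat <- bl[setdiff(names(bl), drop_cols)]
  excluded <- names(meds)
  feat <- cbind(feat, meds)
  diag <- data.frame(); dropped <- character()
  if (impute && anyNA(feat)) {
    imp <- impute_chained(feat, forced = forced, excluded = excluded,
                          n_iterations = n_iterations, num_trees = num_trees,
                          seed = seed)
    feat <- imp$data; diag <- imp$diagnostics; dropped <- imp$dropped
  }
  feat <- derive_features(feat)
  prs <- vapply(cohort$weight_sets, function(w) {
    raw <- as.numeric(cohort$dosages %*% w)
    s <- stats::sd(raw)
    if (s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  }, numeric(nrow(bl)))
  feat <- cbind(id = bl$id, feat, prs, stringsAsFactors = FALSE)
  list(features = feat, schema = feature_schema(setdiff(names(feat), "id")),
       imputation = diag, dropped = dropped)
}
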