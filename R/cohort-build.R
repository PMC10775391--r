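# Diagnosis ascertainment from EHR/self-report and case-control cohort
# construction with eligibility filtering and balanced control allocation.

#' Diagnosis code registry
#'
#' Maps each diagnosis to its qualifying EHR (diagnostic/procedure) codes and
#' self-report response codes. Code sets must be non-empty and unique.
#'
#' @param ... named entries, each a list with `ehr` and optionally
#'   `self_report` character vectors
#' @return object of class `code_registry`
#' @export
code_registry <- function(...) {
  entries <- list(...)
  if (!length(entries) || is.null(names(entries)) || any(names(entries) == ""))
    stopf("code_registry: entries must be named")
  for (nm in names(entries)) {
    e <- entries[[nm]]
    e$self_report <- e$self_report %||% character()
    if (!length(e$ehr)) stopf("code_registry: '%s' has an empty EHR code set", nm)
    if (anyDuplicated(e$ehr) || anyDuplicated(e$self_report))
      stopf("code_registry: '%s' has duplicate codes", nm)
    entries[[nm]] <- e
  }
  structure(entries, class = "code_registry")
}

#' Default registry for the synthetic code universe
#'
#' CAD is ascertained from myocardial-infarction/ischaemia diagnosis codes and
#' revascularisation procedure codes, or from self-reported heart attack /
#' revascularisation responses; three contributing diagnoses (angina, type-2
#' diabetes, hypertension) share the same mechanics. The synthetic EHR
#' generator emits codes from this registry.
#'
#' @return a [code_registry()]
#' @export
default_code_registry <- function() {
  code_registry(
    cad = list(ehr = c("I21", "I22", "I23", "I24", "I25.2", "I46",
                       "K40", "K45", "K49"),
               self_report = c("1075", "1070", "1095")),
    angina = list(ehr = "I20", self_report = "1074"),
    t2d = list(ehr = "E11", self_report = "1223"),
    hypertension = list(ehr = "I10", self_report = "1065"))
}

#' Read or write a code registry as YAML
#'
#' The on-disk format is a named map of diagnoses, each with `ehr` and
#' optional `self_report` code lists.
#'
#' @param path YAML file path
#' @return a [code_registry()]
#' @export
read_code_registry <- function(path) {
  do.call(code_registry, yaml::read_yaml(path))
}

#' @rdname read_code_registry
#' @param registry a [code_registry()]
#' @export
write_code_registry <- function(registry, path) {
  stopifnot(inherits(registry, "code_registry"))
  yaml::write_yaml(lapply(unclass(registry), function(e)
    list(ehr = as.list(e$ehr), self_report = as.list(e$self_report))), path)
  invisible(path)
}

#' Ascertain a diagnosis from EHR and self-report records
#'
#' An individual is a case iff any qualifying code appears in either source;
#' onset is the date of the earliest qualifying record. Self-report onset
#' dates are derived from the reported age and the birth date.
#'
#' @param ehr data.frame with columns `id`, `code`, `date`
#' @param self_report data.frame with columns `id`, `code`, `age` (may be
#'   empty or `NULL`)
#' @param registry_entry one entry of a [code_registry()]
#' @param birth_dates named `Date` vector (id -> birth date), required when
#'   self-report records are supplied
#' @param ids optional id universe defining the output rows (defaults to the
#'   ids seen in the records)
#' @return data.frame: `id`, `status` ("case"/"control"), `onset_date`,
#'   `source` ("ehr"/"self_report"/`NA`)
#' @export
ascertain_diagnosis <- function(ehr, self_report = NULL, registry_entry,
                                birth_dates = NULL, ids = NULL) {
  dates <- if (inherits(ehr$date, "Date")) ehr$date
  else as.Date(as.character(ehr$date), format = "%Y-%m-%d")
  if (anyNA(dates))
    stopf("unparseable EHR date(s) for id(s): %s",
          paste(unique(ehr$id[is.na(dates)]), collapse = ", "))
  hit <- ehr$code %in% registry_entry$ehr
  cand <- data.frame(id = ehr$id[hit], date = dates[hit],
                     source = rep("ehr", sum(hit)), stringsAsFactors = FALSE)
  if (!is.null(self_report) && nrow(self_report)) {
    srhit <- self_report$code %in% registry_entry$self_report
    if (any(srhit)) {
      if (is.null(birth_dates))
        stopf("birth_dates required to date self-reported events")
      sr <- self_report[srhit, , drop = FALSE]
      sr_date <- birth_dates[sr$id] + round(sr$age * 365.25)
      cand <- rbind(cand, data.frame(id = sr$id, date = sr_date,
                                     source = rep("self_report", nrow(sr)),
                                     stringsAsFactors = FALSE))
    }
  }
  ids <- ids %||% sort(unique(c(ehr$id, if (!is.null(self_report)) self_report$id)))
  out <- data.frame(id = ids, status = "control",
                    onset_date = as.Date(NA), source = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(cand)) {
    cand <- cand[order(cand$id, cand$date), , drop = FALSE]
    first <- cand[!duplicated(cand$id), , drop = FALSE]
    m <- match(first$id, out$id)
    ok <- !is.na(m)
    out$status[m[ok]] <- "case"
    out$onset_date[m[ok]] <- first$date[ok]
    out$source[m[ok]] <- first$source[ok]
  }
  out
}

#' Control eligibility from EHR sufficiency
#'
#' A control is ineligible iff it has less than 1 year of EHR follow-up, or
#' fewer than 3 EHR entries, or a CAD onset beyond 10 years after baseline
#' ("less than" is strict: exactly 1 year and exactly 3 entries pass).
#'
#' @param ehr_summary data.frame with `followup_years`, `n_ehr_entries` and
#'   logical `late_onset` columns
#' @return data.frame with logical `eligible` and character `reason`
#'   (`NA` when eligible)
#' @export
filter_controls <- function(ehr_summary) {
  stopifnot(all(c("followup_years", "n_ehr_entries", "late_onset") %in%
                  names(ehr_summary)))
  if (any(ehr_summary$followup_years < 0) || any(ehr_summary$n_ehr_entries < 0))
    stopf("follow-up and entry counts must be non-negative")
  reason <- rep(NA_character_, nrow(ehr_summary))
  reason[ehr_summary$late_onset] <- "cad_beyond_10y"
  reason[is.na(reason) & ehr_summary$n_ehr_entries < 3] <- "insufficient_entries"
  reason[is.na(reason) & ehr_summary$followup_years < 1] <- "insufficient_followup"
  data.frame(eligible = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Allocate controls between the prevalent and incident cohorts
#'
#' Eligible controls are randomly partitioned between the two cohorts in
#' proportion to their case counts (largest-remainder rounding), so the two
#' cohort case rates agree within rounding. Deterministic given the seed;
#' every eligible control is used exactly once.
#'
#' @param cases_prevalent,cases_incident,eligible_controls disjoint id vectors
#' @param seed integer seed
#' @return data.frame: `id`, `cohort` ("prevalent"/"incident"), `role`
#' @export
assign_cohorts <- function(cases_prevalent, cases_incident, eligible_controls,
                           seed = 1L) {
  if (!length(cases_prevalent) || !length(cases_incident))
    stopf("assign_cohorts: both case sets must be non-empty")
  all_ids <- c(cases_prevalent, cases_incident, eligible_controls)
  if (anyDuplicated(all_ids)) stopf("assign_cohorts: id sets must be disjoint")
  counts <- largest_remainder(length(eligible_controls),
                              c(length(cases_prevalent), length(cases_incident)))
  rs <- restore_seed(seed); on.exit(rs())
  perm <- eligible_controls[sample.int(length(eligible_controls))]
  rbind(
    data.frame(id = cases_prevalent, cohort = "prevalent", role = "case",
               stringsAsFactors = FALSE),
    data.frame(id = cases_incident, cohort = "incident", role = "case",
               stringsAsFactors = FALSE),
    data.frame(id = perm[seq_len(counts[1])], cohort = "prevalent",
               role = "control", stringsAsFactors = FALSE),
    data.frame(id = perm[counts[1] + seq_len(counts[2])], cohort = "incident",
               role = "control", stringsAsFactors = FALSE))
}

#' Early/late onset stratum
#'
#' Early onset is strictly before age 55; onset at exactly 55 is late.
#'
#' @param onset_age onset age in years
#' @return character vector of "early"/"late"
#' @export
onset_stratum <- function(onset_age) {
  if (anyNA(onset_age)) stopf("onset_stratum: missing onset age")
  ifelse(onset_age < 55, "early", "late")
}

#' Build the primary prevalent/incident CAD cohorts from a synthetic cohort
#'
#' Ascertains CAD from the cohort's EHR and self-report tables, classifies
#' onsets as prevalent (before baseline), incident (within 10 years of
#' baseline) or late (beyond 10 years), applies control eligibility
#' filtering, and allocates controls proportionally.
#'
#' @param cohort a `sim_cohort`
#' @param registry a [code_registry()]
#' @param seed integer seed for control allocation
#' @return data.frame: `id`, `cohort` ("prevalent"/"incident"/"excluded"),
#'   `role`, `onset_date`, `onset_age`, `stratum`, `exclusion_reason`
#' @export
build_cohorts <- function(cohort, registry = default_code_registry(),
                          seed = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  seed <- seed %||% derive_seed(cohort$config$seed, "assign")
  bl <- cohort$baseline
  births <- stats::setNames(bl$birth_date, bl$id)
  st <- ascertain_diagnosis(cohort$ehr, cohort$self_report, registry$cad,
                            birth_dates = births, ids = bl$id)
  stopifnot(identical(st$id, bl$id))
  onset_age <- as.numeric(st$onset_date - births[st$id]) / 365.25
  days <- as.numeric(st$onset_date - bl$enrol_date)
  is_case <- st$status == "case"
  prevalent <- is_case & days <= 0
  incident <- is_case & days > 0 & days <= 3652
  late <- is_case & days > 3652

  elig <- filter_controls(data.frame(
    followup_years = bl$followup_years,
    n_ehr_entries = bl$n_ehr_entries,
    late_onset = late))
  ctrl <- !is_case | late
  eligible_ctrl <- ctrl & elig$eligible

  asg <- assign_cohorts(bl$id[prevalent], bl$id[incident],
                        bl$id[eligible_ctrl], seed = seed)
  out <- data.frame(id = bl$id, cohort = "excluded", role = NA_character_,
                    onset_date = st$onset_date, onset_age = round(onset_age, 2),
                    stratum = NA_character_,
                    exclusion_reason = elig$reason, stringsAsFactors = FALSE)
  m <- match(asg$id, out$id)
  out$cohort[m] <- asg$cohort
  out$role[m] <- asg$role
  out$exclusion_reason[out$cohort != "excluded"] <- NA_character_
  has_age <- is_case & !is.na(onset_age)
  out$stratum[has_age] <- onset_stratum(onset_age[has_age])
  out
}

#' Per-diagnosis outcome tables for stage-1 training
#'
#' For each registered diagnosis, labels every prevalent-cohort member for the
#' five stage-1 outcomes: baseline onset (any / early / late, onset strictly
#' before baseline) and future onset within 10 and 20 years. Controls for a
#' diagnosis exclude individuals with no EHR entries after the first visit or
#' who died of other causes during follow-up. Individuals with a baseline
#' diagnosis are excluded from (set `NA` in) that diagnosis's future-onset
#' outcomes so prevalence is not conflated with incidence; cases of the
#' non-matching onset stratum are likewise `NA` in the early/late outcomes.
#'
#' @param cohort a `sim_cohort`
#' @param member_ids ids of the prevalent cohort (cases + allocated controls)
#' @param registry a [code_registry()]
#' @return named list (per diagnosis) of data.frames with columns `id`,
#'   `baseline_any`, `baseline_early`, `baseline_late`, `future_10y`,
#'   `future_20y` (0/1/NA)
#' @export
build_outcome_cohorts <- function(cohort, member_ids,
                                  registry = default_code_registry()) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(registry, "code_registry"))
  bl <- cohort$baseline[match(member_ids, cohort$baseline$id), , drop = FALSE]
  births <- stats::setNames(bl$birth_date, bl$id)
  ctrl_ok <- (bl$n_ehr_entries - 1L) >= 1L & bl$death_other == 0L
  out <- list()
  for (dx in names(registry)) {
    st <- ascertain_diagnosis(cohort$ehr, cohort$self_report, registry[[dx]],
                              birth_dates = births, ids = bl$id)
    days <- as.numeric(st$onset_date - bl$enrol_date)
    onset_age <- as.numeric(st$onset_date - births[st$id]) / 365.25
    base_case <- st$status == "case" & days <= 0
    fut10 <- st$status == "case" & days > 0 & days <= 3652
    fut20 <- st$status == "case" & days > 0 & days <= 7305
    lab <- function(case_flag) {
      y <- ifelse(case_flag, 1L, ifelse(ctrl_ok & st$status != "case", 0L, NA))
      y
    }
    strat <- rep(NA_character_, nrow(bl))
    ok <- base_case & !is.na(onset_age)
    strat[ok] <- onset_stratum(onset_age[ok])
    early <- lab(base_case & strat == "early")
    late <- lab(base_case & strat == "late")
    # the off-stratum case is excluded, not a control
    early[base_case & strat == "late"] <- NA
    late[base_case & strat == "early"] <- NA
    f10 <- lab(fut10); f20 <- lab(fut20)
    f10[base_case] <- NA; f20[base_case] <- NA
    # future controls must themselves be free of the diagnosis during window
    f10[!base_case & !fut10 & st$status == "case"] <- NA  # onset beyond 10y
    tab <- data.frame(id = bl$id,
                      baseline_any = lab(base_case),
                      baseline_early = early, baseline_late = late,
                      future_10y = f10, future_20y = f20,
                      stringsAsFactors = FALSE)
    if (sum(base_case) == 0)
      warnf("diagnosis '%s' has zero baseline cases in the prevalent cohort", dx)
    out[[dx]] <- tab
  }
  out
}
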