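# Diagnosis ascertainment, eligibility filtering, balanced allocation.

test_that("code registries round-trip through YAML", {
  reg <- default_code_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_code_registry(reg, path)
  reg2 <- read_code_registry(path)
  expect_s3_class(reg2, "code_registry")
  expect_setequal(names(reg2), names(reg))
  expect_setequal(reg2$cad$ehr, reg$cad$ehr)
  expect_error(code_registry(cad = list(ehr = character())), "empty")
  expect_error(code_registry(cad = list(ehr = c("I21", "I21"))), "duplicate")
})

test_that("ascertainment takes the earliest qualifying record", {
  reg <- default_code_registry()
  ehr <- data.frame(id = c("a", "a", "b"),
                    code = c("I21", "K40", "Z00"),
                    date = c("2005-03-01", "2003-07-10", "2004-01-01"),
                    stringsAsFactors = FALSE)
  st <- ascertain_diagnosis(ehr, NULL, reg$cad, ids = c("a", "b"))
  expect_equal(st$status, c("case", "control"))
  expect_equal(st$onset_date[1], as.Date("2003-07-10"))
  expect_true(is.na(st$onset_date[2]))
})

test_that("self-reported events are dated from the reported age", {
  reg <- default_code_registry()
  ehr <- data.frame(id = "a", code = "Z00", date = "2010-01-01",
                    stringsAsFactors = FALSE)
  sr <- data.frame(id = "a", code = "1075", age = 50, stringsAsFactors = FALSE)
  births <- c(a = as.Date("1950-06-15"))
  st <- ascertain_diagnosis(ehr, sr, reg$cad, birth_dates = births, ids = "a")
  expect_equal(st$status, "case")
  expect_equal(st$source, "self_report")
  expect_equal(st$onset_date, births[["a"]] + round(50 * 365.25))
})

test_that("unparseable EHR dates raise an error naming the record", {
  reg <- default_code_registry()
  ehr <- data.frame(id = "bad1", code = "I21", date = "not-a-date",
                    stringsAsFactors = FALSE)
  expect_error(suppressWarnings(ascertain_diagnosis(ehr, NULL, reg$cad)),
               "bad1")
})

test_that("control eligibility applies strict 'less than' thresholds", {
  s <- data.frame(followup_years = c(0.9, 3, 1.0, 12, 12),
                  n_ehr_entries = c(5, 2, 3, 10, 10),
                  late_onset = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- filter_controls(s)
  expect_equal(out$eligible, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$reason[1], "insufficient_followup")
  expect_equal(out$reason[2], "insufficient_entries")
  expect_equal(out$reason[4], "cad_beyond_10y")
  # monotone eligibility: more data never flips eligible -> ineligible
  s2 <- s; s2$followup_years <- s$followup_years + 5; s2$n_ehr_entries <- s$n_ehr_entries + 5
  out2 <- filter_controls(s2)
  expect_true(all(out2$eligible >= out$eligible | s$late_onset))
})

test_that("control allocation is proportional with largest-remainder rounding", {
  a <- assign_cohorts(paste0("p", 1:100), paste0("i", 1:100),
                      paste0("c", 1:2000), seed = 3)
  tab <- table(a$cohort, a$role)
  expect_equal(unname(tab["prevalent", "control"]), 1000)
  expect_equal(unname(tab["incident", "control"]), 1000)
  rate <- function(ch) mean(a$role[a$cohort == ch] == "case")
  expect_equal(rate("prevalent"), rate("incident"))
  # asymmetric counts
  b <- assign_cohorts(paste0("p", 1:10), paste0("i", 1:30),
                      paste0("c", 1:4000), seed = 1)
  tb <- table(b$cohort, b$role)
  expect_equal(unname(tb["prevalent", "control"]), 1000)
  expect_equal(unname(tb["incident", "control"]), 3000)
  # published-scale arithmetic: 16,301 and 15,809 cases over 307,280 controls
  counts <- metapred:::largest_remainder(307280, c(16301, 15809))
  expect_equal(sum(counts), 307280)
  expect_lt(abs(counts[1] - 155995), 600)   # proportional allocation
  r1 <- 16301 / (16301 + counts[1]); r2 <- 15809 / (15809 + counts[2])
  expect_lt(abs(r1 - r2), 1e-5)
  expect_equal(round(100 * r1, 2), 9.46)
  # determinism and single-use of every control
  a2 <- assign_cohorts(paste0("p", 1:100), paste0("i", 1:100),
                       paste0("c", 1:2000), seed = 3)
  expect_identical(a, a2)
  expect_false(anyDuplicated(a$id) > 0)
  expect_error(assign_cohorts(character(), "i1", "c1"), "non-empty")
})

test_that("onset stratum splits strictly at age 55", {
  expect_equal(onset_stratum(c(54.9, 55, 40)), c("early", "late", "early"))
  expect_error(onset_stratum(c(50, NA)), "missing")
})

test_that("cohort construction partitions individuals and balances case rates", {
  co <- small_cohort(n = 8000, seed = 55)
  asg <- build_cohorts(co)
  expect_equal(nrow(asg), 8000)
  expect_true(all(asg$cohort %in% c("prevalent", "incident", "excluded")))
  r_prev <- mean(asg$role[asg$cohort == "prevalent"] == "case")
  r_inc <- mean(asg$role[asg$cohort == "incident"] == "case")
  expect_lt(abs(r_prev - r_inc), 0.001)
  # prevalent cases have onset on/before enrolment; incident in (0, 10y]
  enrol <- co$baseline$enrol_date[match(asg$id, co$baseline$id)]
  days <- as.numeric(asg$onset_date - enrol)
  prev_case <- asg$cohort == "prevalent" & asg$role == "case"
  inc_case <- asg$cohort == "incident" & asg$role == "case"
  expect_true(all(days[prev_case] <= 0))
  expect_true(all(days[inc_case] > 0 & days[inc_case] <= 3652))
})

test_that("outcome cohorts respect strata, controls and future-case exclusions", {
  co <- small_cohort(n = 8000, seed = 55)
  asg <- build_cohorts(co)
  prev_ids <- asg$id[asg$cohort == "prevalent"]
  tabs <- build_outcome_cohorts(co, prev_ids)
  expect_setequal(names(tabs), names(default_code_registry()))
  t2d <- tabs$t2d
  # early + late cases are subsets of any-onset cases
  expect_true(all(which(t2d$baseline_early == 1) %in% which(t2d$baseline_any == 1)))
  expect_true(all(which(t2d$baseline_late == 1) %in% which(t2d$baseline_any == 1)))
  # an individual cannot be early and late simultaneously
  expect_equal(sum(t2d$baseline_early == 1 & t2d$baseline_late == 1,
                   na.rm = TRUE), 0)
  # baseline cases are excluded from the future-onset outcomes
  expect_true(all(is.na(t2d$future_10y[t2d$baseline_any == 1])))
  # 10-year future cases are 20-year future cases
  expect_true(all(which(t2d$future_10y == 1) %in% which(t2d$future_20y == 1)))
  # controls who died of other causes are excluded from control pools
  dead <- co$baseline$id[co$baseline$death_other == 1]
  dead_rows <- which(t2d$id %in% dead)
  expect_true(all(is.na(t2d$baseline_any[dead_rows]) |
                    t2d$baseline_any[dead_rows] == 1))
})
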