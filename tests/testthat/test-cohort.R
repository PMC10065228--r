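ev_row <- function(pid, code, source, kind, date) {
  data.frame(patient_id = pid, code = code, source = source, kind = kind,
             event_date = as.Date(date), stringsAsFactors = FALSE)
}

test_that("case identification finds the earliest AS mention across sources", {
  ev <- rbind(
    ev_row("A", "N1001", "GP", "DIAG", "2005-03-01"),
    ev_row("B", "M45", "HOSP", "DIAG", "2006-07-01"),
    ev_row("B", "N1001", "GP", "DIAG", "2007-01-01"),
    ev_row("C", "24611", "GP", "PROC", "2004-01-01")
  )
  cases <- identify_cases(ev)
  expect_equal(cases$patient_id, c("A", "B"))
  expect_equal(cases$diagnosis_date, as.Date(c("2005-03-01", "2006-07-01")))
  expect_true(all(is.na(cases$suspected_date)))
})

test_that("anti-TNF or HLA-B27/spondyloarthropathy coding back-dates onset", {
  ev <- rbind(
    ev_row("A", "aTNF1", "GP", "MED", "2004-01-01"),
    ev_row("A", "N1001", "GP", "DIAG", "2005-03-01"),
    ev_row("B", "43F21", "GP", "TEST", "2003-06-15"),
    ev_row("B", "N1011", "GP", "DIAG", "2003-09-01"),
    ev_row("B", "M45", "HOSP", "DIAG", "2004-02-01"),
    # qualifying codes after the first AS mention do not back-date
    ev_row("C", "N1001", "GP", "DIAG", "2005-01-01"),
    ev_row("C", "aTNF1", "GP", "MED", "2006-01-01")
  )
  cases <- identify_cases(ev)
  expect_equal(cases$suspected_date[cases$patient_id == "A"], as.Date("2004-01-01"))
  expect_equal(cases$suspected_date[cases$patient_id == "B"], as.Date("2003-06-15"))
  expect_true(is.na(cases$suspected_date[cases$patient_id == "C"]))
})

test_that("diagnosis dates agree with a brute-force earliest-date scan", {
  pop <- small_pop(n_cases = 30, seed = 13)
  pop <- inject_suspected_pathway(pop, 0.4, seed = 13)
  cases <- identify_cases(pop$events)
  cl <- default_code_lists()
  for (i in sample(nrow(cases), 10)) {
    e <- pop$events[pop$events$patient_id == cases$patient_id[i], ]
    is_as <- (e$source == "GP" & startsWith(e$code, cl$as_gp)) |
      (e$source == "HOSP" & startsWith(e$code, cl$as_hosp)) |
      (e$source == "RHEUM" & startsWith(e$code, cl$as_rheum))
    expect_equal(cases$diagnosis_date[i], min(e$event_date[is_as]))
  }
})

make_patient <- function(pid, sex, wob, reg_start, reg_end) {
  data.frame(patient_id = pid, sex = sex, week_of_birth = as.Date(wob),
             reg_start = as.Date(reg_start), reg_end = as.Date(reg_end),
             true_status = "control", diagnosis_date = as.Date(NA),
             stringsAsFactors = FALSE)
}

test_that("eligibility boundaries are inclusive as documented", {
  pats <- rbind(
    make_patient("young", "male", "1991-01-07", "1995-01-01", "2010-01-01"),
    make_patient("ok3y", "male", "1980-01-07", "2002-03-01", "2012-01-01"),
    make_patient("short", "male", "1980-01-07", "2002-03-02", "2012-01-01"),
    make_patient("early", "male", "1980-01-07", "1990-01-01", "2012-01-01"),
    make_patient("old", "male", "1960-01-07", "1980-01-01", "2012-01-01")
  )
  cases <- data.frame(
    patient_id = c("young", "ok3y", "short", "early", "old"),
    # "young" diagnosed at age 14; "ok3y" has exactly 3 years of prior data;
    # "short" one day less; "early" diagnosed before 2000; "old" at age 45
    diagnosis_date = as.Date(c("2005-06-01", NA, NA, "1999-06-01", "2005-03-01")),
    suspected_date = as.Date(NA), stringsAsFactors = FALSE)
  cases$diagnosis_date[2] <- as.Date("2002-03-01") + round(3 * 365.25)
  cases$diagnosis_date[3] <- as.Date("2002-03-02") + round(3 * 365.25) - 1
  out <- apply_eligibility(cases, pats, match_config())
  expect_setequal(out$eligible$patient_id, "ok3y")
  expect_equal(sum(out$attrition$removed), nrow(cases) - nrow(out$eligible))
  expect_equal(out$attrition$remaining[nrow(out$attrition)], nrow(out$eligible))
})

test_that("eligibility matches an independent filter recount on synthetic data", {
  pop <- small_pop(n_cases = 40, seed = 17)
  cases <- identify_cases(pop$events)
  cfg <- match_config()
  out <- apply_eligibility(cases, pop$patients, cfg)

  x <- merge(cases, pop$patients[, c("patient_id", "week_of_birth", "reg_start")])
  age <- as.numeric(x$diagnosis_date - (x$week_of_birth + 3.5)) / 365.25
  manual <- x$patient_id[
    age >= 15 & age <= 35 &
      as.integer(format(x$diagnosis_date, "%Y")) >= 2000 &
      x$reg_start <= x$diagnosis_date - round(3 * 365.25)]
  expect_setequal(out$eligible$patient_id, manual)
})

test_that("matched pairs satisfy every constraint (independent verifier)", {
  pop <- small_pop(n_cases = 20, ratio = 10, seed = 23)
  cases <- identify_cases(pop$events)
  cfg <- match_config(ratio = 10, seed = 23)
  elig <- apply_eligibility(cases, pop$patients, cfg)$eligible
  ch <- match_controls(elig, pop$patients, pop$events, cfg)

  cl <- default_code_lists()
  excl <- unique(pop$events$patient_id[
    startsWith(pop$events$code, "N100") | startsWith(pop$events$code, "N101") |
      startsWith(pop$events$code, "M45")])
  ctrl <- ch[ch$role == "control", ]
  expect_false(any(ctrl$patient_id %in% excl))

  p <- pop$patients
  for (i in seq_len(nrow(ctrl))) {
    me <- p[p$patient_id == ctrl$patient_id[i], ]
    case <- p[p$patient_id == ctrl$matched_case_id[i], ]
    expect_equal(me$sex, case$sex)
    expect_lte(abs(as.numeric(me$week_of_birth - case$week_of_birth)), 26 * 7)
    expect_lte(me$reg_start, ctrl$index_date[i] - round(3 * 365.25))
    expect_gte(me$reg_end, ctrl$index_date[i] + round(3 * 365.25))
  }
  # within each control set, controls are distinct; each case has 10 distinct
  for (k in unique(ctrl$control_set)) {
    expect_false(any(duplicated(ctrl$patient_id[ctrl$control_set == k])))
  }
  for (cid in unique(ctrl$matched_case_id)) {
    expect_false(any(duplicated(ctrl$patient_id[ctrl$matched_case_id == cid])))
  }

  ch2 <- match_controls(elig, pop$patients, pop$events, cfg)
  expect_identical(as.data.frame(ch), as.data.frame(ch2))
})

test_that("controls need registration spanning the index date by 3y each side", {
  # 5 years of total registration can never satisfy 3y before + 3y after
  pats <- rbind(
    make_patient("case1", "male", "1980-01-07", "1995-01-01", "2010-01-01"),
    make_patient("short5y", "male", "1980-01-14", "2000-01-01", "2005-01-01"),
    make_patient("long", "male", "1980-01-07", "1996-01-01", "2012-01-01"),
    make_patient("long2", "male", "1980-02-04", "1996-01-01", "2012-01-01")
  )
  cases <- data.frame(patient_id = "case1",
                      diagnosis_date = as.Date("2003-06-01"),
                      suspected_date = as.Date(NA), stringsAsFactors = FALSE)
  cases <- merge(cases, pats[, c("patient_id", "sex", "week_of_birth",
                                 "reg_start", "reg_end")])
  ev <- ev_row("case1", "N1001", "GP", "DIAG", "2003-06-01")
  ch <- match_controls(cases, pats, ev, match_config(ratio = 2, seed = 1))
  expect_false("short5y" %in% ch$patient_id)

  # zero tolerance: only exact-week matches are allowed
  expect_error(
    match_controls(cases, pats, ev,
                   match_config(ratio = 2, birth_tolerance_weeks = 0, seed = 1)),
    "eligible controls")
  ch0 <- match_controls(cases, pats, ev,
                        match_config(ratio = 1, birth_tolerance_weeks = 0, seed = 1))
  expect_true(all(ch0$patient_id[ch0$role == "control"] %in% c("long")))
})

test_that("train/test split is case-level with inherited control labels", {
  fake_cohort <- function(n_cases) {
    cases <- sprintf("C%03d", seq_len(n_cases))
    rbind(
      data.frame(patient_id = cases, role = "case", control_set = NA_integer_,
                 matched_case_id = cases, index_date = as.Date("2005-01-01")),
      data.frame(patient_id = paste0("X", cases), role = "control",
                 control_set = 1L, matched_case_id = cases,
                 index_date = as.Date("2005-01-01"))
    )
  }
  ch <- split_train_test(fake_cohort(543), 0.7, seed = 2)
  tr_cases <- ch$patient_id[ch$role == "case" & ch$split == "train"]
  expect_length(tr_cases, 380)
  expect_equal(sum(ch$role == "case" & ch$split == "test"), 163)

  ch2 <- split_train_test(fake_cohort(250), 0.7, seed = 2)
  expect_equal(sum(ch2$role == "case" & ch2$split == "train"), 175)
  expect_equal(sum(ch2$role == "case" & ch2$split == "test"), 75)

  # controls always carry their case's label
  m <- match(ch$matched_case_id, ch$patient_id[ch$role == "case"])
  case_split <- ch$split[ch$role == "case"][m]
  expect_equal(ch$split, case_split)

  expect_error(split_train_test(fake_cohort(10), 1.0), "train_fraction")
  expect_error(split_train_test(fake_cohort(10), 0), "train_fraction")
})
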