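# Cohort construction: incident AS case identification with back-dated
# "suspected" onset, eligibility filtering with attrition accounting, 1:100
# matched control-set construction, and the case-level 70/30 split.

#' Matching and eligibility configuration
#'
#' @param ratio controls matched per case (default 100).
#' @param birth_tolerance_weeks week-of-birth matching tolerance; 26 weeks
#'   implements "within 6 months" on a week-resolution field.
#' @param case_pre_years minimum years of registration before diagnosis for a
#'   case (closed boundary: exactly this much is eligible).
#' @param control_pre_years,control_post_years years of registration a control
#'   must have before and after its index date.
#' @param diagnosis_age_range inclusive age-at-diagnosis range.
#' @param earliest_diagnosis_year cases diagnosed before this year excluded.
#' @param index_mode how a control's index date is assigned: `"case_date"`
#'   (default) uses the matched case's diagnosis date, keeping calendar time
#'   and — via birth matching — age at index equivalent between arms;
#'   `"random"` draws uniformly from the control's feasible interval
#'   `[reg_start + pre, reg_end - post]`.
#' @param seed integer seed for match tie-breaking and random index dates.
#' @return list of class `match_config`.
#' @export
match_config <- function(ratio = 100,
                         birth_tolerance_weeks = 26,
                         case_pre_years = 3,
                         control_pre_years = 3,
                         control_post_years = 3,
                         diagnosis_age_range = c(15, 35),
                         earliest_diagnosis_year = 2000,
                         index_mode = c("case_date", "random"),
                         seed = 1) {
  if (ratio < 1) stop("`ratio` must be >= 1", call. = FALSE)
  if (birth_tolerance_weeks < 0) stop("`birth_tolerance_weeks` must be >= 0", call. = FALSE)
  if (case_pre_years <= 0 || control_pre_years <= 0 || control_post_years <= 0) {
    stop("all window durations must be > 0", call. = FALSE)
  }
  structure(list(ratio = as.integer(ratio),
                 birth_tolerance_weeks = birth_tolerance_weeks,
                 case_pre_years = case_pre_years,
                 control_pre_years = control_pre_years,
                 control_post_years = control_post_years,
                 diagnosis_age_range = diagnosis_age_range,
                 earliest_diagnosis_year = earliest_diagnosis_year,
                 index_mode = match.arg(index_mode),
                 seed = as.integer(seed)),
            class = "match_config")
}

#' Identify AS cases and back-date suspected onset
#'
#' A patient is a case if they carry an AS code in any source (the GP
#' analogue of Read N100, the hospital analogue of ICD-10 M45, or the
#' rheumatology system). The diagnosis date is the earliest AS-code date
#' across sources. An earlier "suspected AS" date is recorded if an anti-TNF
#' prescription, an HLA-B27 test, or a spondyloarthropathy diagnosis precedes
#' the first AS mention: the suspected date is the earliest such qualifying
#' date.
#'
#' @param events event table (patient_id, code, source, kind, event_date).
#' @param codes code lists as from [default_code_lists()].
#' @return data.frame (patient_id, diagnosis_date, suspected_date), one row
#'   per identified case; `suspected_date` is `NA` where absent.
#' @export
identify_cases <- function(events, codes = default_code_lists()) {
  is_as <- (events$source == "GP" & code_matches(events$code, codes$as_gp)) |
    (events$source == "HOSP" & code_matches(events$code, codes$as_hosp)) |
    (events$source == "RHEUM" & code_matches(events$code, codes$as_rheum))
  as_ev <- events[is_as, c("patient_id", "event_date")]
  if (!nrow(as_ev)) {
    return(data.frame(patient_id = character(0),
                      diagnosis_date = as.Date(character(0)),
                      suspected_date = as.Date(character(0))))
  }
  diag <- stats::aggregate(event_date ~ patient_id, data = as_ev, FUN = min)
  names(diag)[2] <- "diagnosis_date"

  pre_prefixes <- unique(c(codes$anti_tnf, codes$hla_b27,
                           codes$spondyloarthropathy))
  pre_ev <- events[code_matches(events$code, pre_prefixes),
                   c("patient_id", "event_date")]
  pre_ev <- merge(pre_ev, diag, by = "patient_id")
  pre_ev <- pre_ev[pre_ev$event_date < pre_ev$diagnosis_date, ]
  if (nrow(pre_ev)) {
    susp <- stats::aggregate(event_date ~ patient_id, data = pre_ev, FUN = min)
    names(susp)[2] <- "suspected_date"
  } else {
    susp <- data.frame(patient_id = character(0),
                       suspected_date = as.Date(character(0)))
  }
  out <- merge(diag, susp, by = "patient_id", all.x = TRUE)
  out$suspected_date <- as.Date(out$suspected_date, origin = "1970-01-01")
  out[order(out$patient_id), ]
}

#' Apply case eligibility filters with attrition accounting
#'
#' Retains cases diagnosed within the inclusive age range, in or after the
#' earliest diagnosis year, and with at least `case_pre_years` of
#' registration before diagnosis (closed boundary: exactly the minimum
#' qualifies). Filters are applied in that order and a per-filter attrition
#' table is returned.
#'
#' @param cases output of [identify_cases()].
#' @param patients patient table.
#' @param cfg a [match_config()].
#' @return list with `eligible` (filtered cases joined with demographics) and
#'   `attrition` (filter, removed, remaining).
#' @export
apply_eligibility <- function(cases, patients, cfg = match_config()) {
  demo_cols <- c("patient_id", "sex", "week_of_birth", "reg_start", "reg_end")
  x <- merge(cases, patients[, demo_cols], by = "patient_id")
  att <- data.frame(filter = character(0), removed = integer(0),
                    remaining = integer(0))
  note <- function(name, keep) {
    att <<- rbind(att, data.frame(filter = name, removed = sum(!keep),
                                  remaining = sum(keep)))
    x[keep, ]
  }
  age <- age_at(x$diagnosis_date, x$week_of_birth)
  x <- note("age_at_diagnosis",
            age >= cfg$diagnosis_age_range[1] & age <= cfg$diagnosis_age_range[2])
  yr <- as.integer(format(x$diagnosis_date, "%Y"))
  x <- note("diagnosis_year", yr >= cfg$earliest_diagnosis_year)
  x <- note("prior_registration",
            x$reg_start <= x$diagnosis_date - years_to_days(cfg$case_pre_years))
  list(eligible = x, attrition = att)
}

#' Build 1:ratio matched control sets
#'
#' For each eligible case, `ratio` distinct controls are drawn from patients
#' with no AS or axial-SpA code anywhere in their record, matching on sex and
#' week of birth within tolerance, and holding at least `control_pre_years`
#' of registration before and `control_post_years` after their index date
#' (so at least 6 years of data in total under the defaults). Controls are
#' partitioned into `ratio` control sets: set k holds the k-th match of every
#' case and no control appears twice within a set. A control may serve
#' different cases in different sets.
#'
#' @param cases eligible cases (from [apply_eligibility()]).
#' @param patients patient table.
#' @param events full event table (used to exclude AS/axSpA carriers).
#' @param cfg a [match_config()].
#' @param codes code lists for the exclusion scan.
#' @return object of class `matched_cohort`: a data.frame with one row per
#'   participant slot (patient_id, role, control_set, matched_case_id,
#'   index_date) and the config as an attribute.
#' @export
match_controls <- function(cases, patients, events, cfg = match_config(),
                           codes = default_code_lists()) {
  set.seed(derive_seed(cfg$seed, 3))
  excl_prefix <- unique(c(codes$as_gp, codes$as_hosp, codes$as_rheum, codes$axspa))
  carriers <- unique(events$patient_id[code_matches(events$code, excl_prefix)])
  pool <- patients[!(patients$patient_id %in% carriers) &
                     !(patients$patient_id %in% cases$patient_id), ]
  n_pool <- nrow(pool)
  if (!n_pool) stop("control pool is empty after AS/axSpA exclusion", call. = FALSE)

  tol_days <- cfg$birth_tolerance_weeks * 7
  pre_d <- years_to_days(cfg$control_pre_years)
  post_d <- years_to_days(cfg$control_post_years)
  ratio <- cfg$ratio

  used <- matrix(FALSE, n_pool, ratio)  # control already taken in set k
  rows <- vector("list", nrow(cases) * 2)

  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ok_sex <- pool$sex == cs$sex
    ok_wob <- abs(as.numeric(pool$week_of_birth - cs$week_of_birth)) <= tol_days
    if (cfg$index_mode == "case_date") {
      idx_date <- cs$diagnosis_date
      ok_win <- pool$reg_start <= idx_date - pre_d & pool$reg_end >= idx_date + post_d
    } else {
      # feasible interval must be non-empty (>= 6 years of data)
      ok_win <- pool$reg_start + pre_d <= pool$reg_end - post_d
    }
    elig <- which(ok_sex & ok_wob & ok_win)
    if (length(elig) < ratio) {
      stop(sprintf(paste0("case %s: only %d eligible controls for ratio %d ",
                          "(sex-matched: %d; within %g-week birth tolerance: %d; ",
                          "with %g+%gy around the index date: %d)"),
                   cs$patient_id, length(elig), ratio, sum(ok_sex),
                   cfg$birth_tolerance_weeks, sum(ok_sex & ok_wob),
                   cfg$control_pre_years, cfg$control_post_years,
                   sum(ok_sex & ok_wob & ok_win)),
           call. = FALSE)
    }
    ord <- elig[sample.int(length(elig))]
    picked <- integer(ratio)        # pool row chosen for each set
    unfilled <- seq_len(ratio)
    for (j in ord) {
      k <- unfilled[!used[j, unfilled]][1]
      if (is.na(k)) next
      picked[k] <- j
      used[j, k] <- TRUE
      unfilled <- unfilled[unfilled != k]
      if (!length(unfilled)) break
    }
    if (length(unfilled)) {
      stop(sprintf(paste0("case %s: could not fill %d of %d control sets with ",
                          "distinct-in-set controls (pool exhausted by earlier ",
                          "cases sharing the birth window)"),
                   cs$patient_id, length(unfilled), ratio), call. = FALSE)
    }
    if (cfg$index_mode == "case_date") {
      ctrl_index <- rep(cs$diagnosis_date, ratio)
    } else {
      lo <- as.numeric(pool$reg_start[picked]) + pre_d
      hi <- as.numeric(pool$reg_end[picked]) - post_d
      ctrl_index <- as.Date(lo + floor(stats::runif(ratio) * (hi - lo + 1)),
                            origin = "1970-01-01")
    }
    rows[[2 * i - 1]] <- data.frame(
      patient_id = cs$patient_id, role = "case", control_set = NA_integer_,
      matched_case_id = cs$patient_id, index_date = cs$diagnosis_date,
      stringsAsFactors = FALSE)
    rows[[2 * i]] <- data.frame(
      patient_id = pool$patient_id[picked], role = "control",
      control_set = seq_len(ratio), matched_case_id = cs$patient_id,
      index_date = ctrl_index, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("matched_cohort", "data.frame")
  out
}

#' Split the matched cohort into training and testing groups
#'
#' The split is at the case level; each case's matched controls inherit its
#' label so matched pairs stay intact.
#'
#' @param cohort a `matched_cohort`.
#' @param train_fraction fraction of cases assigned to training (must lie
#'   strictly inside (0, 1)).
#' @param seed integer seed.
#' @return the cohort with a `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(cohort, train_fraction = 0.7, seed = 1) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  case_ids <- unique(cohort$patient_id[cohort$role == "case"])
  n_train <- round(length(case_ids) * train_fraction)
  set.seed(derive_seed(seed, 4))
  train_ids <- sample(case_ids, n_train)
  cohort$split <- ifelse(cohort$matched_case_id %in% train_ids, "train", "test")
  cohort
}

#' Write / read the cohort table
#' @param cohort a `matched_cohort`.
#' @param path CSV path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$index_date <- as.Date(x$index_date)
  class(x) <- c("matched_cohort", "data.frame")
  x
}
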