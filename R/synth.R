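# Synthetic longitudinal coded-EHR generator.
#
# Emulates the structure of linked routine health data: 5-character
# hierarchical codes from three sources (GP primary care, hospital
# admissions, a rheumatology clinical system), per-patient registration
# windows, and plantable sex- and age-band-specific prodromal signatures for
# ankylosing spondylitis (AS). Only binary presence of a code in a time
# window matters downstream, so background events follow a homogeneous
# Poisson process and signature events are Bernoulli presence draws.

#' Configuration for the synthetic population generator
#'
#' @param n_cases number of true AS cases to generate. May be omitted in
#'   population mode, where it is derived as
#'   `round(population_size * case_prevalence)`.
#' @param controls_per_case matching ratio the population must be able to
#'   support (default 100, the study's 1:100 design).
#' @param population_size total number of patients (cases plus
#'   control-eligible). Default `n_cases * 53`, enough birth-week density for
#'   100 matched control sets.
#' @param case_prevalence fraction of the population that are cases in
#'   population mode (default 0.0009, the general-population AS prevalence).
#' @param sex_ratio fraction of patients that are male. Analyses are run
#'   separately per sex; use 1 (or 0) for a single-sex stratum.
#' @param seed integer seed; identical config + seed gives identical output.
#' @param signature_strength scalar multiplier applied to case penetrances of
#'   planted signature items (capped at 1). 1 = the stated penetrances.
#' @param background_code_rate mean background events per patient per year.
#' @param birth_range character or Date length-2: weeks of birth are drawn
#'   uniformly from the Mondays in this interval.
#' @param diagnosis_age_range numeric length-2: case diagnosis age drawn
#'   uniformly in this range (years).
#' @param reg_start_age numeric length-2: age at GP registration start.
#' @param control_reg_end_age numeric length-2: age at registration end for
#'   control-eligible patients (must allow the 3-years-either-side rule).
#' @param case_post_reg_years numeric length-2: years of registration a case
#'   retains after diagnosis.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_cases = NULL,
                         controls_per_case = 100,
                         population_size = NULL,
                         case_prevalence = 0.0009,
                         sex_ratio = 1,
                         seed = 1,
                         signature_strength = 1,
                         background_code_rate = 2,
                         birth_range = c("1982-01-04", "1987-12-28"),
                         diagnosis_age_range = c(18, 32),
                         reg_start_age = c(8, 12),
                         control_reg_end_age = c(34, 40),
                         case_post_reg_years = c(0, 2)) {
  if (is.null(n_cases) && is.null(population_size)) {
    stop("supply `n_cases` (matched mode) or `population_size` (population mode)",
         call. = FALSE)
  }
  stopifnot_fraction(case_prevalence, "case_prevalence")
  stopifnot_fraction(sex_ratio, "sex_ratio")
  if (is.null(n_cases)) n_cases <- max(1L, round(population_size * case_prevalence))
  if (is.null(population_size)) population_size <- n_cases * 53
  if (n_cases < 1 || controls_per_case < 1 || population_size < 1) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  if (population_size <= n_cases) {
    stop("`population_size` must exceed `n_cases`", call. = FALSE)
  }
  if (signature_strength < 0) stop("`signature_strength` must be >= 0", call. = FALSE)
  if (background_code_rate < 0) stop("`background_code_rate` must be >= 0", call. = FALSE)
  cfg <- list(
    n_cases = as.integer(n_cases),
    controls_per_case = as.integer(controls_per_case),
    population_size = as.integer(population_size),
    case_prevalence = case_prevalence,
    sex_ratio = sex_ratio,
    seed = as.integer(seed),
    signature_strength = signature_strength,
    background_code_rate = background_code_rate,
    birth_range = as.Date(birth_range),
    diagnosis_age_range = diagnosis_age_range,
    reg_start_age = reg_start_age,
    control_reg_end_age = control_reg_end_age,
    case_post_reg_years = case_post_reg_years
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Sex-specific prodromal signature specification
#'
#' A signature is a set of (concept, age band, case penetrance, control
#' penetrance) items planted into the generated records. Concepts are code
#' prefixes; an item with penetrance p plants at least one event with that
#' prefix, dated inside the age band (and before diagnosis for a case), in a
#' fraction p of the patients exposed to the band.
#'
#' @param sex `"male"` or `"female"`.
#' @param items data.frame with columns `concept`, `age_lo`, `age_hi`,
#'   `penetrance_case`, `penetrance_control`, `source`, `kind`.
#' @return object of class `signature_spec`.
#' @export
signature_spec <- function(sex, items) {
  sex <- match.arg(sex, c("male", "female"))
  need <- c("concept", "age_lo", "age_hi", "penetrance_case",
            "penetrance_control", "source", "kind")
  if (!all(need %in% names(items))) {
    stop("items must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(items$age_lo < 15 | items$age_hi > 35 | items$age_lo >= items$age_hi)) {
    stop("age bands must be within [15, 35) with age_lo < age_hi", call. = FALSE)
  }
  stopifnot_fraction(items$penetrance_case, "penetrance_case")
  stopifnot_fraction(items$penetrance_control, "penetrance_control")
  structure(list(sex = sex, items = items), class = "signature_spec")
}

sig_item <- function(concept, lo, hi, pc, p0, source = "GP", kind = "DIAG") {
  data.frame(concept = concept, age_lo = lo, age_hi = hi,
             penetrance_case = pc, penetrance_control = p0,
             source = source, kind = kind, stringsAsFactors = FALSE)
}

#' Default male prodromal signature
#'
#' Transcribes the narrative male profile: lower back pain and diclofenac in
#' the teens with uveitis appearing in the early twenties (Group 1), back
#' disorders, NSAIDs and blood tests at 20-25 (Group 2), and repeated blood
#' tests, back pain and spinal radiology at 25-30 (Group 3).
#'
#' @return a `signature_spec` for males.
#' @export
male_signatures <- function() {
  items <- rbind(
    sig_item("N142", 15, 20, 0.60, 0.12, "GP", "DIAG"),  # lower back pain
    sig_item("j612", 15, 20, 0.45, 0.08, "GP", "MED"),   # diclofenac
    sig_item("F451", 20, 25, 0.25, 0.02, "GP", "DIAG"),  # uveitis
    sig_item("N13",  20, 25, 0.50, 0.10, "GP", "DIAG"),  # vertebral column syndromes
    sig_item("j61",  20, 25, 0.55, 0.15, "GP", "MED"),   # NSAIDs
    sig_item("44F",  20, 25, 0.60, 0.25, "GP", "TEST"),  # blood tests
    sig_item("44F",  25, 30, 0.55, 0.20, "GP", "TEST"),
    sig_item("N142", 25, 30, 0.45, 0.12, "GP", "DIAG"),
    sig_item("521",  25, 30, 0.35, 0.07, "GP", "PROC")   # spinal x-ray
  )
  signature_spec("male", items)
}

#' Default female prodromal signature
#'
#' Transcribes the narrative female profile: arthropathies at 15-20 followed
#' by lumbar pain, co-dydramol and sciatica at 25-30 (Group 1), multiple pain
#' medications and blood tests at 20-25 evolving to back-disorder codes
#' (Group 2), pain at 20-25 with x-rays at 25-30 and diclofenac at 30-35
#' (Group 3), and backache symptoms plus blood tests at 25-30 (Group 4).
#' Uveitis is deliberately absent: it was a male-only feature.
#'
#' @return a `signature_spec` for females.
#' @export
female_signatures <- function() {
  items <- rbind(
    sig_item("N06",  15, 20, 0.40, 0.08, "GP", "DIAG"),  # arthropathies
    sig_item("N142", 25, 30, 0.50, 0.12, "GP", "DIAG"),  # pain in lumbar spine
    sig_item("j811", 25, 30, 0.45, 0.10, "GP", "MED"),   # co-dydramol
    sig_item("N143", 25, 30, 0.35, 0.06, "GP", "DIAG"),  # sciatica
    sig_item("j81",  20, 25, 0.50, 0.12, "GP", "MED"),   # pain-relief medication
    sig_item("44F",  20, 25, 0.50, 0.20, "GP", "TEST"),
    sig_item("N13",  25, 30, 0.45, 0.10, "GP", "DIAG"),
    sig_item("N06",  20, 25, 0.40, 0.08, "GP", "DIAG"),
    sig_item("521",  25, 30, 0.35, 0.07, "GP", "PROC"),
    sig_item("j612", 30, 35, 0.40, 0.10, "GP", "MED"),
    sig_item("16C",  25, 30, 0.45, 0.10, "GP", "DIAG"),  # backache symptoms
    sig_item("44F",  25, 30, 0.50, 0.20, "GP", "TEST")
  )
  signature_spec("female", items)
}

# Specific (full 5-character) codes available under each signature concept
# prefix. Events are planted with a specific code so that truncation levels
# above the concept's own length stay meaningful.
signature_code_pool <- function() {
  list(
    "N142" = c("N1421", "N1422"),
    "j612" = "j6121",
    "F451" = c("F4511", "F4512"),
    "N13"  = c("N1311", "N1321"),
    "j61"  = c("j6111", "j6121"),
    "44F"  = c("44F11", "44F21", "44F31"),
    "521"  = "52121",
    "N06"  = "N0611",
    "j811" = "j8111",
    "N143" = "N1431",
    "j81"  = c("j8111", "j8121"),
    "16C"  = "16C11"
  )
}

# Background codes occur in cases and controls at identical rates, giving the
# null features against which stability selection's type-I behaviour is
# checked. Prefixes are disjoint from the signature concepts at level >= 3.
background_dictionary <- function() {
  data.frame(
    code   = c("24611", "65E21", "H0511", "171A1", "8B316", "M1611",
               "1B1G1", "44J31", "53611", "K1901", "S5211", "J4501"),
    source = c("GP", "GP", "GP", "GP", "GP", "GP",
               "GP", "GP", "GP", "GP", "HOSP", "HOSP"),
    kind   = c("PROC", "PROC", "DIAG", "PROC", "PROC", "DIAG",
               "DIAG", "TEST", "PROC", "DIAG", "DIAG", "DIAG"),
    weight = c(3, 1, 2, 1.5, 2, 1, 1.5, 1, 0.8, 1, 0.8, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Clinical code lists used by case identification
#'
#' Prefix lists per source for AS diagnosis codes (the GP analogue of Read
#' N100 and the hospital analogue of ICD-10 M45), axial spondyloarthritis
#' codes that exclude a patient from the control pool, anti-TNF prescription
#' codes, HLA-B27 test codes, and spondyloarthropathy diagnosis codes used
#' for suspected-AS back-dating.
#'
#' @return a named list of character prefix vectors.
#' @export
default_code_lists <- function() {
  list(
    as_gp = "N100",
    as_hosp = "M45",
    as_rheum = "N100",
    axspa = "N101",
    anti_tnf = "aTNF",
    hla_b27 = "43F2",
    spondyloarthropathy = "N101"
  )
}

code_matches <- function(code, prefixes) {
  out <- rep(FALSE, length(code))
  for (p in prefixes) out <- out | startsWith(code, p)
  out
}

#' Generate a synthetic population of patients and coded events
#'
#' Draws demographics and registration windows, a homogeneous-Poisson
#' background event stream identical in distribution for cases and controls,
#' planted signature events at the stated penetrances, and an AS diagnosis
#' code (GP, hospital or rheumatology source) for every case at its
#' diagnosis date.
#'
#' @param config a [synth_config()].
#' @param signatures list of [signature_spec()] objects (at most one per sex);
#'   default ships the study-style male and female profiles.
#' @return object of class `synth_population`: a list with `patients`
#'   (patient_id, sex, week_of_birth, reg_start, reg_end, true_status,
#'   diagnosis_date) and `events` (patient_id, code, source, kind,
#'   event_date), plus the config and signatures used.
#' @export
generate_population <- function(config,
                                signatures = list(male_signatures(),
                                                  female_signatures())) {
  stopifnot(inherits(config, "synth_config"))
  if (inherits(signatures, "signature_spec")) signatures <- list(signatures)
  sig_by_sex <- list()
  for (s in signatures) sig_by_sex[[s$sex]] <- s

  set.seed(derive_seed(config$seed, 1))
  n <- config$population_size
  n_cases <- config$n_cases

  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  for (sx in unique(sex[seq_len(n_cases)])) {
    # cases are the first n_cases ids; every case sex needs a signature
    if (is.null(sig_by_sex[[sx]]) && any(sex[seq_len(n_cases)] == sx)) {
      stop(sprintf("cases of sex '%s' requested but no signature supplied", sx),
           call. = FALSE)
    }
  }
  status <- c(rep("case", n_cases), rep("control", n - n_cases))
  # enough same-sex controls must exist for 1:ratio matching to be possible
  for (sx in c("male", "female")) {
    nc <- sum(sex == sx & status == "case")
    np <- sum(sex == sx & status == "control")
    if (nc > 0 && np < config$controls_per_case) {
      stop(sprintf(paste0("population too small: %d %s controls available but ",
                          "controls_per_case = %d"),
                   np, sx, config$controls_per_case), call. = FALSE)
    }
  }

  mondays <- seq(config$birth_range[1], config$birth_range[2], by = "7 days")
  wob <- sample(mondays, n, replace = TRUE)
  reg_start <- date_at_age(wob, stats::runif(n, config$reg_start_age[1],
                                             config$reg_start_age[2]))
  diag_age <- stats::runif(n, config$diagnosis_age_range[1],
                           config$diagnosis_age_range[2])
  diagnosis_date <- as.Date(ifelse(status == "case",
                                   date_at_age(wob, diag_age), NA),
                            origin = "1970-01-01")
  reg_end <- as.Date(ifelse(
    status == "case",
    diagnosis_date + years_to_days(stats::runif(n, config$case_post_reg_years[1],
                                                config$case_post_reg_years[2])),
    date_at_age(wob, stats::runif(n, config$control_reg_end_age[1],
                                  config$control_reg_end_age[2]))),
    origin = "1970-01-01")

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = sex,
    week_of_birth = wob,
    reg_start = reg_start,
    reg_end = reg_end,
    true_status = status,
    diagnosis_date = diagnosis_date,
    stringsAsFactors = FALSE
  )

  # --- background events: Poisson count over the registration span -------
  span_years <- as.numeric(reg_end - reg_start) / DAYS_PER_YEAR
  n_ev <- stats::rpois(n, config$background_code_rate * pmax(span_years, 0))
  idx <- rep.int(seq_len(n), n_ev)
  bg <- background_dictionary()
  pick <- sample.int(nrow(bg), length(idx), replace = TRUE, prob = bg$weight)
  ev_bg <- data.frame(
    patient_id = patients$patient_id[idx],
    code = bg$code[pick],
    source = bg$source[pick],
    kind = bg$kind[pick],
    event_date = as.Date(round(as.numeric(reg_start[idx]) +
                               stats::runif(length(idx)) *
                               as.numeric(reg_end[idx] - reg_start[idx])),
                         origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  # --- planted signature events ------------------------------------------
  pool <- signature_code_pool()
  sig_frames <- list()
  for (s in sig_by_sex) {
    who_sex <- which(patients$sex == s$sex)
    if (!length(who_sex)) next
    for (r in seq_len(nrow(s$items))) {
      it <- s$items[r, ]
      band_lo <- date_at_age(wob[who_sex], it$age_lo)
      band_hi <- date_at_age(wob[who_sex], it$age_hi)
      w_lo <- pmax(band_lo, reg_start[who_sex])
      w_hi <- pmin(band_hi - 1, reg_end[who_sex])
      is_case <- status[who_sex] == "case"
      w_hi[is_case] <- pmin(w_hi[is_case], diagnosis_date[who_sex][is_case] - 1)
      exposed <- as.numeric(w_hi - w_lo) >= 0
      pen <- ifelse(is_case,
                    pmin(1, it$penetrance_case * config$signature_strength),
                    it$penetrance_control)
      hit <- exposed & stats::runif(length(who_sex)) < pen
      if (!any(hit)) next
      hi <- who_sex[hit]
      codes <- pool[[it$concept]]
      if (is.null(codes)) codes <- it$concept
      sig_frames[[length(sig_frames) + 1L]] <- data.frame(
        patient_id = patients$patient_id[hi],
        code = sample(codes, length(hi), replace = TRUE),
        source = it$source,
        kind = it$kind,
        event_date = as.Date(round(as.numeric(w_lo[hit]) +
                                   stats::runif(length(hi)) *
                                   as.numeric(w_hi[hit] - w_lo[hit])),
                             origin = "1970-01-01"),
        stringsAsFactors = FALSE
      )
    }
  }

  # --- AS diagnosis codes for cases --------------------------------------
  ci <- which(status == "case")
  src_draw <- stats::runif(length(ci))
  as_source <- ifelse(src_draw < 0.60, "GP", ifelse(src_draw < 0.85, "HOSP", "RHEUM"))
  as_code <- ifelse(as_source == "HOSP", "M45",
                    sample(c("N1001", "N1002"), length(ci), replace = TRUE))
  ev_as <- data.frame(
    patient_id = patients$patient_id[ci],
    code = as_code,
    source = as_source,
    kind = "DIAG",
    event_date = diagnosis_date[ci],
    stringsAsFactors = FALSE
  )
  # some cases accrue a repeat AS mention later in their record
  rep_gap <- as.numeric(reg_end[ci] - diagnosis_date[ci])
  has_rep <- stats::runif(length(ci)) < 0.4 & rep_gap > 0
  if (any(has_rep)) {
    ri <- which(has_rep)
    ev_rep <- data.frame(
      patient_id = patients$patient_id[ci][ri],
      code = "N1001",
      source = "GP",
      kind = "DIAG",
      event_date = diagnosis_date[ci][ri] +
        ceiling(stats::runif(length(ri)) * rep_gap[ri]),
      stringsAsFactors = FALSE
    )
    ev_as <- rbind(ev_as, ev_rep)
  }

  events <- rbind(ev_bg, do.call(rbind, sig_frames), ev_as)
  events <- events[order(events$patient_id, events$event_date, events$code), ]
  rownames(events) <- NULL

  structure(list(patients = patients, events = events,
                 config = config, signatures = sig_by_sex),
            class = "synth_population")
}

#' @export
print.synth_population <- function(x, ...) {
  cat("Synthetic coded-EHR population\n")
  cat(sprintf("  patients: %d (%d cases, %d control-eligible)\n",
              nrow(x$patients), sum(x$patients$true_status == "case"),
              sum(x$patients$true_status == "control")))
  cat(sprintf("  events:   %d (%s)\n", nrow(x$events),
              paste(names(table(x$events$source)), table(x$events$source),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Insert pre-diagnosis suspected-AS coding for a fraction of cases
#'
#' For each selected case, either an anti-TNF prescription code or an
#' HLA-B27-test plus spondyloarthropathy code pair is inserted strictly
#' before the first AS code, so that case identification's back-dating rule
#' ("suspected AS" onset) is exercised.
#'
#' @param pop a `synth_population`.
#' @param fraction fraction of cases (Bernoulli per case) to back-date.
#' @param seed integer seed.
#' @return the population with modified events.
#' @export
inject_suspected_pathway <- function(pop, fraction, seed = 1) {
  stopifnot(inherits(pop, "synth_population"))
  stopifnot_fraction(fraction, "fraction")
  cases <- pop$patients[pop$patients$true_status == "case", ]
  if (!nrow(cases)) stop("population contains no cases", call. = FALSE)
  if (fraction == 0) return(pop)
  set.seed(derive_seed(seed, 2))
  chosen <- stats::runif(nrow(cases)) < fraction
  if (!any(chosen)) return(pop)
  cs <- cases[chosen, ]
  lead <- pmin(900, pmax(1, as.numeric(cs$diagnosis_date - cs$reg_start) - 1))
  offset <- ceiling(stats::runif(nrow(cs)) * lead)  # days before diagnosis
  d <- cs$diagnosis_date - offset
  use_tnf <- stats::runif(nrow(cs)) < 0.5
  new_ev <- rbind(
    data.frame(patient_id = cs$patient_id[use_tnf], code = "aTNF1",
               source = "GP", kind = "MED", event_date = d[use_tnf],
               stringsAsFactors = FALSE),
    data.frame(patient_id = rep(cs$patient_id[!use_tnf], 2),
               code = rep(c("43F21", "N1011"), each = sum(!use_tnf)),
               source = "GP",
               kind = rep(c("TEST", "DIAG"), each = sum(!use_tnf)),
               event_date = rep(d[!use_tnf], 2),
               stringsAsFactors = FALSE)
  )
  ev <- rbind(pop$events, new_ev)
  ev <- ev[order(ev$patient_id, ev$event_date, ev$code), ]
  rownames(ev) <- NULL
  pop$events <- ev
  pop
}

#' Observed penetrance of a signature concept in an age band
#'
#' Among patients whose usable window (registration, truncated at diagnosis
#' for cases) intersects the band, the fraction carrying at least one event
#' with the concept prefix dated inside the band. The binomial check of the
#' generator's planted penetrances.
#'
#' @param pop a `synth_population`.
#' @param concept code prefix.
#' @param age_band numeric length-2, `[lo, hi)` in years.
#' @return list with `case`, `control` observed fractions and the exposed
#'   denominators `n_case`, `n_control`.
#' @export
observed_penetrance <- function(pop, concept, age_band) {
  p <- pop$patients
  band_lo <- date_at_age(p$week_of_birth, age_band[1])
  band_hi <- date_at_age(p$week_of_birth, age_band[2])
  w_lo <- pmax(band_lo, p$reg_start)
  w_hi <- pmin(band_hi - 1, p$reg_end)
  is_case <- p$true_status == "case"
  w_hi[is_case] <- pmin(w_hi[is_case], p$diagnosis_date[is_case] - 1)
  exposed <- as.numeric(w_hi - w_lo) >= 0

  ev <- pop$events[startsWith(pop$events$code, concept), ]
  m <- match(ev$patient_id, p$patient_id)
  in_band <- ev$event_date >= band_lo[m] & ev$event_date < band_hi[m]
  carriers <- unique(ev$patient_id[in_band])
  has <- p$patient_id %in% carriers

  list(case = mean(has[exposed & is_case]),
       control = mean(has[exposed & !is_case]),
       n_case = sum(exposed & is_case),
       n_control = sum(exposed & !is_case))
}

#' Write a synthetic population to delimited files
#'
#' Writes `patients.csv` and `events.csv` (RFC-4180, UTF-8, ISO-8601 dates)
#' plus `provenance.txt` recording the seed, the config, and the MD5 of both
#' tables.
#'
#' @param pop a `synth_population`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- file.path(dir, "patients.csv")
  ef <- file.path(dir, "events.csv")
  utils::write.csv(pop$patients, pf, row.names = FALSE, quote = FALSE)
  utils::write.csv(pop$events, ef, row.names = FALSE, quote = FALSE)
  prov <- c(
    sprintf("generator: aspredict %s", as.character(utils::packageVersion("aspredict"))),
    sprintf("seed: %d", pop$config$seed),
    sprintf("patients_md5: %s", unname(tools::md5sum(pf))),
    sprintf("events_md5: %s", unname(tools::md5sum(ef))),
    "config:",
    utils::capture.output(utils::str(unclass(pop$config)))
  )
  writeLines(prov, file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' Read a population written by [write_population()]
#' @param dir directory containing `patients.csv` and `events.csv`.
#' @return a `synth_population` (config and signatures absent).
#' @export
read_population <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  for (col in c("week_of_birth", "reg_start", "reg_end", "diagnosis_date")) {
    patients[[col]] <- as.Date(patients[[col]])
  }
  events$event_date <- as.Date(events$event_date)
  if (any(events$code == "" | is.na(events$code))) {
    stop("invalid events table: empty codes", call. = FALSE)
  }
  structure(list(patients = patients, events = events,
                 config = NULL, signatures = NULL),
            class = "synth_population")
}

#' Recovery of planted signature items by a stability screen
#'
#' For each (concept, age band) item of a signature, checks whether the
#' screen passed the feature keyed by exactly that concept (at its own
#' truncation level) in that band.
#'
#' @param stability a `stability_result`.
#' @param signature a `signature_spec`.
#' @return list: `recovered` logical per item, `rate` the mean.
#' @export
signal_recovery <- function(stability, signature) {
  sel <- stability$feature_key[stability$pass]
  parts <- strsplit(sel, "|", fixed = TRUE)
  concepts <- vapply(parts, `[`, "", 1)
  windows <- vapply(parts, `[`, "", 4)
  it <- signature$items
  band <- sprintf("age%g_%g", it$age_lo, it$age_hi)
  recovered <- mapply(function(con, b) any(concepts == con & windows == b),
                      it$concept, band)
  list(recovered = unname(recovered), rate = mean(recovered))
}

#' Selection rate of null (background-only) features
#'
#' A feature is null when its concept prefix covers only background codes —
#' no planted signature code, aggregate group, AS/axSpA code, or
#' suspected-pathway code falls under it. Under the generator's null these
#' features differ between arms only by sampling noise, so their selection
#' rate measures the stability screen's realised type-I behaviour.
#'
#' @param stability a `stability_result`.
#' @param aggmap the aggregation map used when building features.
#' @return list: `n_null` features under test, `n_selected` of them passing,
#'   `rate` their ratio (0 when `n_null` is 0).
#' @export
null_selection <- function(stability, aggmap = default_aggmap()) {
  signal_codes <- c(unlist(signature_code_pool()),
                    "aTNF1", "43F21", "N1011", "N1001", "N1002", "M45")
  concepts <- vapply(strsplit(stability$feature_key, "|", fixed = TRUE),
                     `[`, "", 1)
  is_null <- !concepts %in% names(aggmap) &
    !vapply(concepts, function(con) any(startsWith(signal_codes, con)), TRUE)
  n_null <- sum(is_null)
  n_sel <- sum(is_null & stability$pass)
  list(n_null = n_null, n_selected = n_sel,
       rate = if (n_null) n_sel / n_null else 0)
}
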