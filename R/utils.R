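#' @keywords internal
"_PACKAGE"

# Days per Julian year; used for all age arithmetic on calendar dates.
DAYS_PER_YEAR <- 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base [round()] rounds half to even; published clinical tables round half
#' up, so reports use this variant.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stream-specific seed from a run seed. Keeps results < 2^31 so the
# value is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483647L)
}

# Age in years at `date` for a patient born in the week starting `wob`
# (week midpoint convention: wob + 3.5 days).
age_at <- function(date, wob) {
  as.numeric(as.Date(date) - (as.Date(wob) + 3.5)) / DAYS_PER_YEAR
}

# Date at which a patient born in week `wob` reaches `age` years.
date_at_age <- function(wob, age) {
  as.Date(round(as.numeric(as.Date(wob) + 3.5) + age * DAYS_PER_YEAR),
          origin = "1970-01-01")
}

years_to_days <- function(y) round(y * DAYS_PER_YEAR)

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
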