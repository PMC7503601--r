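#' Age-predicted maximal heart rate for sedentary adults
#'
#' Tanaka's regression for sedentary people: HRmax = 211 - 0.8 x age.
#' Used to anchor heart-rate-reserve exercise prescriptions when no maximal
#' test is available.
#'
#' @param age Age in years; positive finite numeric (vectorised).
#' @return Predicted maximal heart rate in beats per minute.
#' @examples
#' tanaka_hrmax(70)   # 155
#' @export
tanaka_hrmax <- function(age) {
  if (!is.numeric(age) || length(age) == 0 || any(!is.finite(age)) || any(age <= 0)) {
    stop("`age` must be positive and finite", call. = FALSE)
  }
  211 - 0.8 * age
}

#' Cardiovascular parameters for one participant
#'
#' Bundles resting heart rate with an age-predicted maximal heart rate
#' (via [tanaka_hrmax()]). Ages outside the 60-90 band typical of older-adult
#' exercise cohorts raise a warning; ages outside 18-110 are rejected.
#'
#' @param age Age in years.
#' @param hr_rest Resting heart rate, beats per minute.
#' @return An object of class `cardio_params`: list with `age`, `hr_rest`,
#'   `hr_max`.
#' @export
cardio_params <- function(age, hr_rest) {
  if (!is.numeric(age) || length(age) != 1 || !is.finite(age))
    stop("`age` must be a finite scalar", call. = FALSE)
  if (age < 18 || age > 110)
    stop("`age` outside the supported 18-110 range", call. = FALSE)
  if (age < 60 || age > 90)
    warning("age outside the 60-90 older-adult band; formulas were derived for seniors")
  if (!is.numeric(hr_rest) || length(hr_rest) != 1 || !is.finite(hr_rest) || hr_rest <= 0)
    stop("`hr_rest` must be a positive scalar", call. = FALSE)
  hr_max <- tanaka_hrmax(age)
  if (hr_max <= hr_rest)
    stop("derived hr_max does not exceed hr_rest; inputs implausible", call. = FALSE)
  structure(list(age = age, hr_rest = hr_rest, hr_max = hr_max),
            class = "cardio_params")
}

#' @export
print.cardio_params <- function(x, ...) {
  cat(sprintf("cardio_params: age %.1f yr, HRrest %.0f bpm, HRmax %.1f bpm (Tanaka)\n",
              x$age, x$hr_rest, x$hr_max))
  invisible(x)
}

#' Heart-rate-reserve (Karvonen) target zone
#'
#' Places target heart-rate bounds at `hr_rest + frac * (hr_max - hr_rest)`.
#' The default 50-80% band is the moderate-to-vigorous prescription band used
#' for heart-rate-guided exercise in older adults.
#'
#' @param hr_rest Resting heart rate, bpm.
#' @param hr_max Maximal heart rate, bpm; must exceed `hr_rest`.
#' @param lower_frac,upper_frac Fractions of the heart-rate reserve, with
#'   `0 < lower_frac < upper_frac <= 1`. Defaults 0.50 and 0.80.
#' @return An object of class `hr_zone`: list with `lower`, `upper` (bpm) and
#'   the fractions used.
#' @examples
#' hrr_zone(60, 160)  # 110-140 bpm
#' @export
hrr_zone <- function(hr_rest, hr_max, lower_frac = 0.50, upper_frac = 0.80) {
  for (v in list(hr_rest, hr_max, lower_frac, upper_frac))
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("all arguments must be finite scalars", call. = FALSE)
  if (hr_max <= hr_rest)
    stop("invalid physiology: hr_max must exceed hr_rest", call. = FALSE)
  if (!(lower_frac >= 0 && lower_frac < upper_frac && upper_frac <= 1))
    stop("fractions must satisfy 0 <= lower_frac < upper_frac <= 1", call. = FALSE)
  hrr <- hr_max - hr_rest
  structure(list(lower = hr_rest + lower_frac * hrr,
                 upper = hr_rest + upper_frac * hrr,
                 lower_frac = lower_frac, upper_frac = upper_frac),
            class = "hr_zone")
}

#' @export
print.hr_zone <- function(x, ...) {
  cat(sprintf("hr_zone: %.1f-%.1f bpm (%.0f-%.0f%% HRR)\n",
              x$lower, x$upper, 100 * x$lower_frac, 100 * x$upper_frac))
  invisible(x)
}

is_hr_zone <- function(x) inherits(x, "hr_zone")

#' Estimate cardiorespiratory fitness from a six-minute walk test
#'
#' Kervio's linear equation predicting absolute VO2max (mL/min) from age,
#' body mass, height, distance covered in the 6-MWT, seated resting oxygen
#' consumption, and heart rate:
#' 2830.6 - 45.2*age + 4.70*BW + 12.3*height + 1.75*distance
#' + 0.309*VO2 - 12.4*HR.
#'
#' The heart-rate and VO2 terms are interpreted as the seated-rest
#' measurements taken alongside the walk test; `hr_test` can be given an
#' end-of-walk value instead if that is the convention in use. The formula is
#' linear and unguarded: implausible (non-positive) outputs are flagged via
#' the `implausible` field, never altered.
#'
#' @param age Age, years.
#' @param body_mass_kg Body mass, kg (current-visit value; also the
#'   denominator of the relative estimate).
#' @param height_cm Height, cm.
#' @param distance_m Distance covered in 6 minutes, m (sanity bound: <= 1000).
#' @param vo2_rest_ml_min Seated resting oxygen consumption, mL/min.
#' @param hr_bpm Heart rate entering the equation, bpm (seated-rest by
#'   convention here).
#' @return Object of class `crf_estimate`: list with `absolute` (mL/min),
#'   `relative` (mL/kg/min), and `implausible` flag.
#' @examples
#' kervio_crf(74, 80, 170, 508, 300, 73)
#' @export
kervio_crf <- function(age, body_mass_kg, height_cm, distance_m,
                       vo2_rest_ml_min, hr_bpm) {
  vals <- list(age = age, body_mass_kg = body_mass_kg, height_cm = height_cm,
               distance_m = distance_m, vo2_rest_ml_min = vo2_rest_ml_min,
               hr_bpm = hr_bpm)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a positive finite scalar", nm), call. = FALSE)
  }
  if (distance_m > 1000)
    stop("`distance_m` exceeds the 1000 m sanity bound for a 6-minute walk",
         call. = FALSE)
  absolute <- 2830.6 - 45.2 * age + 4.70 * body_mass_kg + 12.3 * height_cm +
    1.75 * distance_m + 0.309 * vo2_rest_ml_min - 12.4 * hr_bpm
  out <- list(absolute = absolute,
              relative = absolute / body_mass_kg,
              implausible = absolute <= 0)
  if (out$implausible)
    warning("estimated VO2max is non-positive; inputs likely out of the model's range")
  structure(out, class = "crf_estimate")
}

#' @export
print.crf_estimate <- function(x, ...) {
  cat(sprintf("Estimated CRF: %.1f mL/min (%.1f mL/kg/min)%s\n",
              x$absolute, x$relative,
              if (x$implausible) " [implausible]" else ""))
  invisible(x)
}

#' Read a participant physiology record
#'
#' Flat key-value record with unit-suffixed names (`age_yr`, `body_mass_kg`,
#' `height_cm`, `distance_m`, `vo2_rest_ml_min`, `hr_bpm`, optionally
#' `hr_rest_bpm`), as JSON or a single-row CSV (decided by extension).
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return Named list of numeric fields.
#' @export
read_physiology_record <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    csv  = as.list(utils::read.csv(path, nrows = 1)),
    stop("unsupported extension: ", ext, call. = FALSE))
  lapply(rec, as.numeric)
}

#' Write a participant physiology record
#'
#' @param record Named list of numeric fields (unit-suffixed names).
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_physiology_record <- function(record, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  } else stop("unsupported extension: ", ext, call. = FALSE)
  invisible(path)
}
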