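#' Cohort specification for the synthetic generator
#'
#' Defaults emulate a healthy older-adult cohort enrolled in a walking and
#' exercise program: ages near 74, resting heart rate near 73 bpm overall,
#' and questionnaire scores (SF-12 physical/mental components, fatigue
#' severity, exercise self-efficacy, activity-pacing engagement and
#' perceived risk of over-activity, self-reported activity minutes) at
#' published older-adult levels. Two latent adherence phenotypes are
#' generated; the adherent phenotype is shifted on the features named in
#' `effect_sizes` (by default lower resting HR and lower perceived risk of
#' over-activity, each by one SD, reproducing the observed split of roughly
#' 65 vs 78 bpm).
#'
#' Self-reported activity-minute features (`squash_*`) have SDs comparable
#' to or larger than their means; they are drawn from gamma distributions
#' matched to the target mean and SD (always non-negative, right-skewed as
#' such self-reports are). All other features are Gaussian, clamped to
#' instrument ranges.
#'
#' @param n_participants Cohort size (>= 2).
#' @param seed Integer seed; every generator call is reproducible.
#' @param phenotype_mix Fraction of adherent participants (default 0.4).
#' @param exact_split If `TRUE`, exactly `round(n * mix)` adherent
#'   participants; otherwise phenotype is Bernoulli per participant.
#' @param feature_distributions Named list of `c(mean, sd)` pairs for the
#'   generated features (see defaults for the full set; `hr_rest` default is
#'   the non-adherent phenotype's level).
#' @param effect_sizes Named numeric vector of phenotype shifts, in SD units
#'   of the named feature, applied to the adherent phenotype.
#' @param prop_male Probability of male sex.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 10, seed = 1,
                        phenotype_mix = 0.4, exact_split = FALSE,
                        feature_distributions = list(
                          age = c(73.8, 2.3),
                          height_cm = c(170, 11),
                          body_mass_kg = c(81.6, 13.8),
                          hr_rest = c(78, 13),
                          sixmwt_m = c(508, 60),
                          pcs12 = c(53.5, 3.2),
                          mcs12 = c(58.4, 2.1),
                          fss = c(2.50, 0.77),
                          ese = c(62.7, 23.6),
                          apq_engagement = c(2.68, 0.92),
                          apq_risk = c(2.45, 0.98),
                          squash_walking = c(153, 180),
                          squash_cycling = c(136, 56),
                          squash_other = c(120, 108)
                        ),
                        effect_sizes = c(hr_rest = -1, apq_risk = -1),
                        prop_male = 0.6) {
  if (n_participants < 2) stop("invalid spec: need at least 2 participants",
                               call. = FALSE)
  if (phenotype_mix < 0 || phenotype_mix > 1)
    stop("phenotype_mix must be in [0, 1]", call. = FALSE)
  sds <- vapply(feature_distributions, `[`, numeric(1), 2)
  if (any(sds <= 0)) stop("feature SDs must be positive", call. = FALSE)
  bad <- setdiff(names(effect_sizes), names(feature_distributions))
  if (length(bad)) stop("effect_sizes name unknown features: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_participants = n_participants, seed = seed,
                 phenotype_mix = phenotype_mix, exact_split = exact_split,
                 feature_distributions = feature_distributions,
                 effect_sizes = effect_sizes, prop_male = prop_male),
            class = "cohort_spec")
}

GAMMA_FEATURES <- c("squash_walking", "squash_cycling", "squash_other")

FEATURE_RANGES <- list(
  age = c(60, 95), height_cm = c(120, 220), body_mass_kg = c(35, 200),
  hr_rest = c(40, 120), sixmwt_m = c(50, 1000),
  fss = c(1, 7), ese = c(0, 100),
  apq_engagement = c(0, 5), apq_risk = c(0, 5)
)

#' Generate a baseline cohort with known phenotype labels
#'
#' Draws a participant feature table from a [cohort_spec()] together with
#' the ground-truth phenotype assignment. Derived columns (BMI, estimated
#' absolute and relative CRF via [kervio_crf()]) are computed from the drawn
#' primitives; resting oxygen consumption and the walk-test heart rate are
#' drawn near seated-rest levels.
#'
#' @param spec A [cohort_spec()].
#' @return List with `profiles` (data frame, one row per participant) and
#'   `truth` (data frame `participant_id`, `phenotype`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  set.seed(spec$seed)
  if (spec$exact_split) {
    n_adh <- round(n * spec$phenotype_mix)
    phen <- sample(rep(c("adherent", "nonadherent"), c(n_adh, n - n_adh)))
  } else {
    phen <- ifelse(stats::runif(n) < spec$phenotype_mix,
                   "adherent", "nonadherent")
  }
  adh <- phen == "adherent"
  draw <- function(name) {
    ms <- spec$feature_distributions[[name]]
    mu <- rep(ms[1], n)
    if (name %in% names(spec$effect_sizes))
      mu[adh] <- mu[adh] + spec$effect_sizes[[name]] * ms[2]
    if (name %in% GAMMA_FEATURES) {
      shape <- (mu / ms[2])^2
      x <- stats::rgamma(n, shape = shape, rate = mu / ms[2]^2)
    } else {
      x <- stats::rnorm(n, mu, ms[2])
    }
    rg <- FEATURE_RANGES[[name]]
    if (!is.null(rg)) x <- pmin(pmax(x, rg[1]), rg[2])
    x
  }
  feats <- lapply(names(spec$feature_distributions), draw)
  names(feats) <- names(spec$feature_distributions)
  profiles <- data.frame(participant_id = sprintf("P%03d", seq_len(n)), feats)
  profiles$sex_male <- as.integer(stats::runif(n) < spec$prop_male)
  profiles$bmi <- profiles$body_mass_kg / (profiles$height_cm / 100)^2
  vo2_rest <- pmax(stats::rnorm(n, 300, 25), 150)
  hr_test <- pmax(profiles$hr_rest + stats::rnorm(n, 0, 3), 40)
  crf <- mapply(function(a, bw, h, d, v, hr)
    kervio_crf(a, bw, h, d, v, hr)$absolute,
    profiles$age, profiles$body_mass_kg, profiles$height_cm,
    profiles$sixmwt_m, vo2_rest, hr_test)
  profiles$crf_abs_ml_min <- crf
  profiles$crf_rel_ml_kg_min <- crf / profiles$body_mass_kg
  list(profiles = profiles,
       truth = data.frame(participant_id = profiles$participant_id,
                          phenotype = phen))
}

#' Behavioural model for the stream generator
#'
#' Per-phenotype session behaviour: probability of attempting a planned
#' session, probability of an unplanned session on a non-planned day,
#' session-duration distribution as a multiplier of the daily target
#' (truncated normal, whole minutes), and heart-rate fidelity (the fraction
#' of exercise-session minutes actually driven into the target zone).
#' Incidental in-zone minutes per day (Poisson, outside sessions) model the
#' short heart-rate excursions that are counted as exercise because exercise
#' minutes carry no minimum-bout rule. A shared day-level weather dropout
#' cancels all sessions on affected days (cold or bad weather keeping
#' everyone indoors).
#'
#' @param adherent,nonadherent Named lists with elements `walk_attempt_p`,
#'   `exercise_attempt_p`, `unplanned_walk_p`, `unplanned_exercise_p`,
#'   `walk_duration_mult` (`c(mean, sd)`), `exercise_duration_mult`,
#'   `hr_fidelity`, `incidental_zone_per_day`.
#' @param weather_p Daily probability that weather cancels all sessions.
#' @param hr_noise_sd SD of minute-mean heart-rate noise around its
#'   setpoint, bpm.
#' @param missing_hr_p Probability a non-session minute has no HR reading.
#' @return Object of class `behavior_spec`.
#' @export
behavior_spec <- function(
    adherent = list(walk_attempt_p = 0.85, exercise_attempt_p = 0.90,
                    unplanned_walk_p = 0.15, unplanned_exercise_p = 0.10,
                    walk_duration_mult = c(1.2, 0.3),
                    exercise_duration_mult = c(1.1, 0.3),
                    hr_fidelity = 0.9, incidental_zone_per_day = 15),
    nonadherent = list(walk_attempt_p = 0.45, exercise_attempt_p = 0.50,
                       unplanned_walk_p = 0.05, unplanned_exercise_p = 0.05,
                       walk_duration_mult = c(0.8, 0.3),
                       exercise_duration_mult = c(0.8, 0.3),
                       hr_fidelity = 0.85, incidental_zone_per_day = 8),
    weather_p = 0.10, hr_noise_sd = 4, missing_hr_p = 0.02) {
  chk <- function(b, who) {
    ps <- c(b$walk_attempt_p, b$exercise_attempt_p, b$unplanned_walk_p,
            b$unplanned_exercise_p, b$hr_fidelity)
    if (any(ps < 0 | ps > 1))
      stop(who, ": probabilities must be in [0, 1]", call. = FALSE)
    if (b$walk_duration_mult[1] <= 0 || b$exercise_duration_mult[1] <= 0)
      stop(who, ": duration multipliers must be positive", call. = FALSE)
  }
  chk(adherent, "adherent"); chk(nonadherent, "nonadherent")
  if (weather_p < 0 || weather_p > 1)
    stop("weather_p must be in [0, 1]", call. = FALSE)
  structure(list(adherent = adherent, nonadherent = nonadherent,
                 weather_p = weather_p, hr_noise_sd = hr_noise_sd,
                 missing_hr_p = missing_hr_p),
            class = "behavior_spec")
}

#' Deterministic full-compliance behaviour
#'
#' Every planned session attempted, exact-target durations, perfect
#' heart-rate fidelity, no unplanned sessions, no incidental in-zone
#' minutes, no weather dropout, no missing heart rate. Under this behaviour
#' the pipeline must report exactly 100% program and volume adherence.
#'
#' @return A [behavior_spec()].
#' @export
closed_loop_behavior <- function() {
  full <- list(walk_attempt_p = 1, exercise_attempt_p = 1,
               unplanned_walk_p = 0, unplanned_exercise_p = 0,
               walk_duration_mult = c(1, 0), exercise_duration_mult = c(1, 0),
               hr_fidelity = 1, incidental_zone_per_day = 0)
  behavior_spec(adherent = full, nonadherent = full,
                weather_p = 0, missing_hr_p = 0)
}

draw_duration <- function(n, mult, target, min_min = 3, max_min = 180) {
  d <- round(target * stats::rnorm(n, mult[1], mult[2]))
  pmin(pmax(d, min_min), max_min)
}

#' Plan sessions for a cohort over a study calendar
#'
#' Day-level session placement: for each participant, program and study day,
#' draws whether a session happens (planned-attempt or unplanned
#' probability, suppressed on shared weather-dropout days), its duration in
#' whole minutes, and for exercise sessions the number of minutes actually
#' in the heart-rate zone (binomial at the phenotype's fidelity). This table
#' is the ground truth the minute streams are expanded from.
#'
#' @param cohort Output of [generate_cohort()].
#' @param behavior A [behavior_spec()].
#' @param rx A [prescription()].
#' @param n_weeks Number of Monday-anchored study weeks (>= 1).
#' @param seed Integer seed.
#' @param start_date First study day; must be a Monday.
#' @return List with `sessions` (one row per session), `incidental`
#'   (per participant-day incidental in-zone minutes) and `calendar`
#'   (study dates with the weather indicator).
#' @export
plan_sessions <- function(cohort, behavior, rx, n_weeks, seed,
                          start_date = as.Date("2020-01-06")) {
  stopifnot(inherits(behavior, "behavior_spec"), inherits(rx, "prescription"),
            n_weeks >= 1)
  start_date <- as.Date(start_date)
  if (iso_weekday(start_date) != 1L) stop("start_date must be a Monday",
                                          call. = FALSE)
  set.seed(seed)
  dates <- seq(start_date, by = 1, length.out = 7 * n_weeks)
  weather <- stats::runif(length(dates)) < behavior$weather_p
  truth <- cohort$truth
  programs <- if (rx$walking_only) "walking" else c("walking", "exercise")
  ses <- list(); inc <- list()
  for (i in seq_len(nrow(truth))) {
    b <- behavior[[truth$phenotype[i]]]
    for (pg in programs) {
      planned <- iso_weekday(dates) %in% rx_planned(rx, pg)
      p_attempt <- ifelse(planned,
                          if (pg == "walking") b$walk_attempt_p else b$exercise_attempt_p,
                          if (pg == "walking") b$unplanned_walk_p else b$unplanned_exercise_p)
      happens <- stats::runif(length(dates)) < p_attempt & !weather
      if (!any(happens)) next
      target <- rx_daily_target(rx, pg)
      mult <- if (pg == "walking") b$walk_duration_mult else b$exercise_duration_mult
      dur <- draw_duration(sum(happens), mult, target)
      in_zone <- if (pg == "exercise")
        stats::rbinom(sum(happens), dur, b$hr_fidelity) else NA_integer_
      ses[[length(ses) + 1L]] <- data.frame(
        participant_id = truth$participant_id[i], date = dates[happens],
        program = pg, planned = planned[happens], duration_min = dur,
        in_zone_min = in_zone)
    }
    k <- stats::rpois(length(dates), b$incidental_zone_per_day)
    inc[[length(inc) + 1L]] <- data.frame(
      participant_id = truth$participant_id[i], date = dates,
      incidental_zone_min = ifelse(weather, 0L, k))
  }
  sessions <- if (length(ses)) do.call(rbind, ses) else
    data.frame(participant_id = character(), date = as.Date(character()),
               program = character(), planned = logical(),
               duration_min = integer(), in_zone_min = integer())
  list(sessions = sessions, incidental = do.call(rbind, inc),
       calendar = data.frame(date = dates, weather_dropout = weather))
}

#' Ground-truth daily minutes implied by a session plan
#'
#' Applies the counting rules directly to the session bookkeeping: walking
#' sessions below the minimum-bout threshold are dropped, exercise minutes
#' are the in-zone session minutes plus incidental in-zone minutes. Under
#' lossless stream expansion this equals what the stream pipeline derives.
#'
#' @param plan Output of [plan_sessions()].
#' @param min_bout_seconds Walking bout threshold, seconds (default 110).
#' @return Daily-minutes data frame (`participant_id`, `date`,
#'   `walking_minutes`, `exercise_minutes`) covering every study day.
#' @export
true_daily_minutes <- function(plan, min_bout_seconds = 110) {
  grid <- expand.grid(participant_id = unique(plan$incidental$participant_id),
                      date = plan$calendar$date, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant_id, grid$date), ]
  key <- function(p, d) paste(p, d)
  grid$walking_minutes <- 0
  grid$exercise_minutes <- 0
  s <- plan$sessions
  if (nrow(s)) {
    sw <- s[s$program == "walking" & s$duration_min * 60 >= min_bout_seconds, ]
    if (nrow(sw)) {
      agg <- tapply(sw$duration_min, key(sw$participant_id, sw$date), sum)
      i <- match(names(agg), key(grid$participant_id, grid$date))
      grid$walking_minutes[i] <- as.numeric(agg)
    }
    se <- s[s$program == "exercise", ]
    if (nrow(se)) {
      agg <- tapply(se$in_zone_min, key(se$participant_id, se$date), sum)
      i <- match(names(agg), key(grid$participant_id, grid$date))
      grid$exercise_minutes[i] <- as.numeric(agg)
    }
  }
  ii <- match(key(plan$incidental$participant_id, plan$incidental$date),
              key(grid$participant_id, grid$date))
  grid$exercise_minutes[ii] <- grid$exercise_minutes[ii] +
    plan$incidental$incidental_zone_min
  rownames(grid) <- NULL
  grid
}

#' Personalised heart-rate zones for a cohort
#'
#' Karvonen zones from each participant's resting HR and age-predicted
#' maximal HR ([tanaka_hrmax()]).
#'
#' @param profiles Cohort profile table (needs `participant_id`, `age`,
#'   `hr_rest`).
#' @param lower_frac,upper_frac Heart-rate-reserve fractions.
#' @return Named list of [hrr_zone()] objects keyed by participant id.
#' @export
participant_zones <- function(profiles, lower_frac = 0.5, upper_frac = 0.8) {
  z <- lapply(seq_len(nrow(profiles)), function(i)
    hrr_zone(profiles$hr_rest[i], tanaka_hrmax(profiles$age[i]),
             lower_frac, upper_frac))
  names(z) <- profiles$participant_id
  z
}

#' Expand a session plan into minute-level streams
#'
#' Builds the wrist-device stream the pipeline consumes: one record per wear
#' minute (default wear window 08:00-21:59). Walking sessions become
#' contiguous runs of `walking_seconds = 60` starting at 09:30; exercise
#' sessions start at 15:00, with exactly the planned number of in-zone
#' minutes placed at the session head (mean HR inside the participant's
#' zone) and the remainder just below the zone. Non-session minutes draw HR
#' near resting level and never reach the zone; incidental in-zone minutes
#' are scattered over free minutes. Walking-session HR sits at moderate
#' intensity below the exercise zone, so walking and exercise minutes do not
#' double-count.
#'
#' @param plan Output of [plan_sessions()].
#' @param cohort Output of [generate_cohort()] (for resting HR and zones).
#' @param behavior A [behavior_spec()] (noise and missingness levels).
#' @param seed Integer seed for the HR noise.
#' @param zones Optional named zone list; defaults to
#'   [participant_zones()] of the cohort.
#' @param wear_start,wear_end Wear window, minutes of day.
#' @return Minute-stream data frame in the dialect of
#'   [read_minute_stream()].
#' @export
sessions_to_streams <- function(plan, cohort, behavior, seed,
                                zones = NULL,
                                wear_start = 480L, wear_end = 1319L) {
  set.seed(seed)
  profiles <- cohort$profiles
  if (is.null(zones)) zones <- participant_zones(profiles)
  dates <- plan$calendar$date
  n_min <- wear_end - wear_start + 1L
  out <- vector("list", nrow(profiles) * length(dates))
  k <- 0L
  key <- function(p, d) paste(p, d)
  inc_k <- key(plan$incidental$participant_id, plan$incidental$date)
  for (i in seq_len(nrow(profiles))) {
    pid <- profiles$participant_id[i]
    hr_rest <- profiles$hr_rest[i]
    zone <- zones[[pid]]
    reserve <- zone$upper - zone$lower  # within-zone span
    walk_hr <- min(hr_rest + 0.35 * (zone$lower - hr_rest) / 0.5,
                   zone$lower - 3)
    ses_p <- plan$sessions[plan$sessions$participant_id == pid, , drop = FALSE]
    for (d in seq_along(dates)) {
      minute <- wear_start:wear_end
      ws <- numeric(n_min)
      hr <- stats::rnorm(n_min, hr_rest, behavior$hr_noise_sd)
      hr <- pmin(hr, zone$lower - 3)  # ambient HR never strays into the zone
      in_session <- logical(n_min)
      sd_d <- ses_p[ses_p$date == dates[d], , drop = FALSE]
      for (j in seq_len(nrow(sd_d))) {
        dur <- sd_d$duration_min[j]
        if (sd_d$program[j] == "walking") {
          idx <- seq.int(570L - wear_start + 1L, length.out = min(dur, 300L))
          ws[idx] <- 60
          hr[idx] <- pmin(walk_hr + stats::rnorm(length(idx), 0, 2),
                          zone$lower - 1)
          in_session[idx] <- TRUE
        } else {
          idx <- seq.int(900L - wear_start + 1L, length.out = min(dur, 300L))
          nz <- min(sd_d$in_zone_min[j], length(idx))
          if (nz > 0) {
            zi <- idx[seq_len(nz)]
            mid <- (zone$lower + zone$upper) / 2
            hr[zi] <- pmin(pmax(mid + stats::rnorm(nz, 0, reserve / 6),
                                zone$lower + 0.5), zone$upper - 0.5)
          }
          if (length(idx) > nz)
            hr[idx[(nz + 1L):length(idx)]] <-
              zone$lower - 5 - abs(stats::rnorm(length(idx) - nz, 0, 3))
          in_session[idx] <- TRUE
        }
      }
      n_inc <- plan$incidental$incidental_zone_min[
        match(key(pid, dates[d]), inc_k)]
      if (!is.na(n_inc) && n_inc > 0) {
        free <- which(!in_session)
        pick <- sample(free, min(n_inc, length(free)))
        hr[pick] <- stats::runif(length(pick), zone$lower + 0.5, zone$upper - 0.5)
        in_session[pick] <- TRUE
      }
      if (behavior$missing_hr_p > 0) {
        m <- !in_session & stats::runif(n_min) < behavior$missing_hr_p
        hr[m] <- NA_real_
      }
      k <- k + 1L
      out[[k]] <- data.frame(participant_id = pid, date = dates[d],
                             minute = minute, walking_seconds = ws,
                             mean_hr = round(hr, 1))
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' One-call synthetic study generator
#'
#' Generates a cohort, plans sessions, expands them to minute streams, and
#' returns the ground truth alongside, so the whole pipeline can be tested
#' closed-loop against known answers.
#'
#' @param spec A [cohort_spec()].
#' @param behavior A [behavior_spec()].
#' @param rx A [prescription()].
#' @param n_weeks Study length in weeks.
#' @param seed Integer seed (stage seeds derived as seed, seed+1, seed+2).
#' @param start_date First study Monday.
#' @return List: `cohort`, `plan`, `streams`, `truth_daily` (ground-truth
#'   daily minutes), `zones`.
#' @export
generate_study <- function(spec, behavior = behavior_spec(),
                           rx = prescription(), n_weeks = 3, seed = spec$seed,
                           start_date = as.Date("2020-01-06")) {
  spec$seed <- seed
  cohort <- generate_cohort(spec)
  plan <- plan_sessions(cohort, behavior, rx, n_weeks, seed + 1L, start_date)
  zones <- participant_zones(cohort$profiles,
                             if (is.null(rx$zone)) 0.5 else rx$zone$lower_frac,
                             if (is.null(rx$zone)) 0.8 else rx$zone$upper_frac)
  streams <- sessions_to_streams(plan, cohort, behavior, seed + 2L, zones)
  list(cohort = cohort, plan = plan, streams = streams,
       truth_daily = true_daily_minutes(plan), zones = zones)
}

#' Write the pieces of a synthetic study to disk
#'
#' Streams and cohort tables as CSV, ground truth as JSON, using the same
#' dialects the ingestion functions read.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(streams = file.path(dir, "minute_streams.csv"),
             profiles = file.path(dir, "cohort_profiles.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write_minute_stream(study$streams, paths[["streams"]])
  utils::write.csv(study$cohort$profiles, paths[["profiles"]], row.names = FALSE)
  jsonlite::write_json(
    list(phenotypes = study$cohort$truth, truth_daily = study$truth_daily),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
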