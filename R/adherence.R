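WEEKDAYS3 <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

weekday_index <- function(days) {
  if (is.numeric(days)) {
    if (any(days < 1 | days > 7)) stop("weekday indices must be 1 (Mon) - 7 (Sun)",
                                       call. = FALSE)
    return(as.integer(days))
  }
  idx <- match(days, WEEKDAYS3)
  if (any(is.na(idx))) stop("unknown weekday name(s): ",
                            paste(days[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

# ISO weekday 1 = Monday ... 7 = Sunday, locale-independent
iso_weekday <- function(date) as.integer(format(as.Date(date), "%u"))

#' Monday of the week containing `date`
#' @param date A `Date` vector.
#' @return `Date` vector of the corresponding Mondays.
#' @export
week_monday <- function(date) as.Date(date) - (iso_weekday(date) - 1L)

#' Weekly activity prescription
#'
#' The program prescribes daily walking minutes on a set number of days per
#' week and daily heart-rate-zone exercise minutes on another, following the
#' 150 min/week moderate (30 x 5) and 75 min/week vigorous (25 x 3)
#' activity guidelines. Participants may be prescribed the walking program
#' only (`walking_only = TRUE`), in which case exercise metrics are reported
#' as missing.
#'
#' @param walk_target_min Daily walking target, minutes (default 30).
#' @param walk_days_per_week Walking frequency target, days (default 5).
#' @param exercise_target_min Daily exercise target, minutes (default 25).
#' @param exercise_days_per_week Exercise frequency target, days (default 3).
#' @param zone Optional [hrr_zone()] giving the exercise heart-rate band.
#' @param planned_walk_days,planned_exercise_days Weekdays planned for each
#'   program (names `"Mon"`..`"Sun"` or indices 1-7); sizes must equal the
#'   corresponding days-per-week.
#' @param walking_only If `TRUE`, exercise targets are ignored.
#' @return Object of class `prescription`.
#' @export
prescription <- function(walk_target_min = 30, walk_days_per_week = 5,
                         exercise_target_min = 25, exercise_days_per_week = 3,
                         zone = NULL,
                         planned_walk_days = c("Mon", "Tue", "Wed", "Thu", "Fri"),
                         planned_exercise_days = c("Mon", "Wed", "Fri"),
                         walking_only = FALSE) {
  if (walk_target_min < 0 || exercise_target_min < 0)
    stop("targets must be non-negative", call. = FALSE)
  pw <- sort(unique(weekday_index(planned_walk_days)))
  pe <- sort(unique(weekday_index(planned_exercise_days)))
  if (length(pw) != walk_days_per_week)
    stop("planned_walk_days must contain exactly walk_days_per_week weekdays",
         call. = FALSE)
  if (!walking_only && length(pe) != exercise_days_per_week)
    stop("planned_exercise_days must contain exactly exercise_days_per_week weekdays",
         call. = FALSE)
  if (!is.null(zone)) stopifnot(is_hr_zone(zone))
  structure(list(walk_target_min = walk_target_min,
                 walk_days_per_week = walk_days_per_week,
                 exercise_target_min = exercise_target_min,
                 exercise_days_per_week = exercise_days_per_week,
                 zone = zone, planned_walk_days = pw,
                 planned_exercise_days = pe, walking_only = walking_only),
            class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("prescription: walking %d min/day x %d d/wk (%d min/wk)",
              x$walk_target_min, x$walk_days_per_week,
              weekly_volume_target(x, "walking")))
  if (x$walking_only) cat("; walking only\n")
  else cat(sprintf("; exercise %d min/day x %d d/wk (%d min/wk)\n",
                   x$exercise_target_min, x$exercise_days_per_week,
                   weekly_volume_target(x, "exercise")))
  invisible(x)
}

#' Weekly volume target implied by a prescription
#'
#' Daily minutes times days per week: the denominator of volume adherence
#' (e.g. 30 x 5 = 150 walking minutes, 25 x 3 = 75 exercise minutes).
#'
#' @param rx A [prescription()].
#' @param program `"walking"` or `"exercise"`.
#' @return Weekly target volume in minutes.
#' @export
weekly_volume_target <- function(rx, program = c("walking", "exercise")) {
  program <- match.arg(program)
  if (program == "walking") rx$walk_target_min * rx$walk_days_per_week
  else rx$exercise_target_min * rx$exercise_days_per_week
}

rx_daily_target <- function(rx, program) {
  if (program == "walking") rx$walk_target_min else rx$exercise_target_min
}
rx_frequency <- function(rx, program) {
  if (program == "walking") rx$walk_days_per_week else rx$exercise_days_per_week
}
rx_planned <- function(rx, program) {
  if (program == "walking") rx$planned_walk_days else rx$planned_exercise_days
}

# Expand a Monday-anchored week of daily minutes to exactly 7 rows,
# zero-filling absent days. `week` needs columns date, walking_minutes,
# exercise_minutes; all dates must fall in one Monday-Sunday span.
expand_week <- function(week) {
  week$date <- as.Date(week$date)
  monday <- week_monday(min(week$date))
  if (iso_weekday(min(week$date)) != 1L && nrow(week) == 7L)
    stop("week must start on Monday", call. = FALSE)
  days <- seq(monday, by = 1, length.out = 7)
  if (any(!week$date %in% days))
    stop("week spans more than one Monday-Sunday window", call. = FALSE)
  full <- data.frame(date = days, walking_minutes = 0, exercise_minutes = 0)
  i <- match(week$date, days)
  full$walking_minutes[i] <- week$walking_minutes
  full$exercise_minutes[i] <- week$exercise_minutes
  full
}

#' Per-day target states for the weekly progress display
#'
#' For each day of a Monday-Sunday week and each program, computes the
#' fraction of the daily target achieved, whether the target was met, and
#' the display mark: a `check` on planned days whose target was met, an
#' `opaque_check` on unplanned days whose target was met (unplanned
#' achievement is acknowledged), `none` otherwise. Exceeding the daily
#' target earns no further reward: `achieved_fraction` is reported uncapped
#' for analysis, but the mark logic saturates at target-met.
#'
#' @param week Data frame of daily minutes (`date`, `walking_minutes`,
#'   `exercise_minutes`) within one Monday-anchored week; missing days are
#'   zero-activity.
#' @param rx A [prescription()].
#' @return Data frame with one row per day x program: `date`, `program`,
#'   `planned`, `achieved_fraction`, `target_met`, `mark`.
#' @export
day_states <- function(week, rx) {
  full <- expand_week(week)
  programs <- if (rx$walking_only) "walking" else c("walking", "exercise")
  out <- do.call(rbind, lapply(programs, function(pg) {
    target <- rx_daily_target(rx, pg)
    mins <- if (pg == "walking") full$walking_minutes else full$exercise_minutes
    planned <- iso_weekday(full$date) %in% rx_planned(rx, pg)
    frac <- if (target > 0) mins / target else rep(NA_real_, 7)
    met <- !is.na(frac) & frac >= 1
    mark <- ifelse(met & planned, "check",
                   ifelse(met & !planned, "opaque_check", "none"))
    data.frame(date = full$date, program = pg, planned = planned,
               achieved_fraction = frac, target_met = met, mark = mark)
  }))
  rownames(out) <- NULL
  out
}

#' Program adherence for one week
#'
#' Number of days in the week on which the daily target was reached
#' (planned or not) divided by the prescribed frequency. Step-valued in
#' units of 1/frequency and uncapped: qualifying unplanned days can push it
#' past 100%.
#'
#' @inheritParams day_states
#' @param program `"walking"` or `"exercise"`.
#' @return Adherence fraction (1 = 100%).
#' @export
program_adherence <- function(week, rx, program = c("walking", "exercise")) {
  program <- match.arg(program)
  if (rx$walking_only && program == "exercise") return(NA_real_)
  freq <- rx_frequency(rx, program)
  if (freq <= 0) stop("undefined adherence: target frequency is zero", call. = FALSE)
  full <- expand_week(week)
  target <- rx_daily_target(rx, program)
  mins <- if (program == "walking") full$walking_minutes else full$exercise_minutes
  sum(mins >= target) / freq
}

#' Volume adherence for one week
#'
#' Total qualifying minutes over the week divided by the weekly target
#' volume (daily target x days per week). Continuous and uncapped.
#'
#' @inheritParams program_adherence
#' @return Adherence fraction (1 = 100%).
#' @export
volume_adherence <- function(week, rx, program = c("walking", "exercise")) {
  program <- match.arg(program)
  if (rx$walking_only && program == "exercise") return(NA_real_)
  vol <- weekly_volume_target(rx, program)
  if (vol <= 0) stop("undefined adherence: weekly target volume is zero", call. = FALSE)
  full <- expand_week(week)
  mins <- if (program == "walking") full$walking_minutes else full$exercise_minutes
  sum(mins) / vol
}

#' Weekly adherence summaries over a study period
#'
#' Partitions daily minutes into Monday-anchored calendar weeks and computes
#' both adherence definitions for both programs in each week, plus the
#' counts of days meeting each daily target. Partial first/last weeks (weeks
#' not fully covered by the observed date range) are flagged via `complete`.
#'
#' @param daily Data frame of daily minutes (`date`, `walking_minutes`,
#'   `exercise_minutes`), one participant, sorted or not.
#' @param rx A [prescription()].
#' @param week_labels Optional character labels, one per calendar week in
#'   order (e.g. `c("baseline", "week1", "week2")`).
#' @return Data frame, one row per calendar week: `week_start`, `label`,
#'   `complete`, `walk_program_adherence`, `walk_volume_adherence`,
#'   `exercise_program_adherence`, `exercise_volume_adherence`,
#'   `days_meeting_walk_target`, `days_meeting_exercise_target`. Adherences
#'   are fractions; exercise fields are `NA` for walking-only prescriptions.
#' @export
summarize_weeks <- function(daily, rx, week_labels = NULL) {
  daily$date <- as.Date(daily$date)
  daily <- daily[order(daily$date), , drop = FALSE]
  wk <- week_monday(daily$date)
  weeks <- sort(unique(wk))
  rows <- lapply(seq_along(weeks), function(i) {
    w <- daily[wk == weeks[i], , drop = FALSE]
    full <- expand_week(w)
    walking_only <- rx$walking_only
    data.frame(
      week_start = weeks[i],
      label = if (!is.null(week_labels) && i <= length(week_labels))
        week_labels[i] else paste0("week", i),
      complete = min(daily$date) <= weeks[i] &&
        (weeks[i] + 6) <= max(daily$date),
      walk_program_adherence = program_adherence(w, rx, "walking"),
      walk_volume_adherence = volume_adherence(w, rx, "walking"),
      exercise_program_adherence = program_adherence(w, rx, "exercise"),
      exercise_volume_adherence = volume_adherence(w, rx, "exercise"),
      days_meeting_walk_target = sum(full$walking_minutes >= rx$walk_target_min),
      days_meeting_exercise_target = if (walking_only) NA_integer_ else
        sum(full$exercise_minutes >= rx$exercise_target_min)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tidy percent-scale adherence table
#'
#' Long format (`participant_id`, `week`, `metric`, `value_percent`) for
#' reporting; adherence fractions are scaled to percent.
#'
#' @param summaries Data frame as returned by [summarize_weeks()], with an
#'   optional `participant_id` column.
#' @return Long data frame.
#' @export
adherence_long <- function(summaries) {
  metrics <- c("walk_program_adherence", "walk_volume_adherence",
               "exercise_program_adherence", "exercise_volume_adherence")
  pid <- if ("participant_id" %in% names(summaries))
    summaries$participant_id else NA_character_
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(participant_id = pid, week = summaries$label, metric = m,
               value_percent = 100 * summaries[[m]])
  }))
}
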