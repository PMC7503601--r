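#' Validate a minute-level activity stream
#'
#' A minute stream is a data frame with columns `participant_id`, `date`
#' (ISO-8601), `minute` (minute of day, 0-1439), `walking_seconds` (0-60),
#' and `mean_hr` (bpm, `NA` when the optical sensor had no reading).
#' Within each participant-day, minutes must be strictly increasing; gaps are
#' non-wear and are treated as zero walking, no heart rate.
#'
#' @param stream Data frame in the stream dialect.
#' @return The validated stream (dates coerced to `Date`), invisibly usable.
#' @export
validate_stream <- function(stream) {
  req <- c("participant_id", "date", "minute", "walking_seconds", "mean_hr")
  miss <- setdiff(req, names(stream))
  if (length(miss))
    stop("stream missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  stream$date <- as.Date(stream$date)
  if (any(is.na(stream$date))) stop("unparseable dates in stream", call. = FALSE)
  if (any(stream$minute < 0 | stream$minute > 1439))
    stop("`minute` must be in 0-1439", call. = FALSE)
  ws <- stream$walking_seconds
  if (any(is.na(ws)) || any(ws < 0 | ws > 60))
    stop("`walking_seconds` must be in [0, 60]", call. = FALSE)
  hr <- stream$mean_hr
  if (any(!is.na(hr) & (hr < 25 | hr > 230)))
    stop("`mean_hr` outside the plausible 25-230 bpm band", call. = FALSE)
  key <- interaction(stream$participant_id, stream$date, drop = TRUE)
  ok <- tapply(stream$minute, key, function(m) all(diff(m) > 0))
  if (!all(unlist(ok)))
    stop("non-chronological stream: minutes must be strictly increasing within a day",
         call. = FALSE)
  stream
}

#' Detect walking bouts in one participant-day
#'
#' A bout is a maximal run of consecutive minutes with `walking_seconds > 0`,
#' optionally bridging up to `max_gap_minutes` non-walking minutes. Bouts
#' whose accumulated walking seconds fall below `min_bout_seconds` are
#' discarded, mirroring the device rule that walking bouts shorter than
#' 2 min (with a 10 s tolerance, hence the 110 s default) do not count as
#' walking activity. Exercise minutes carry no such minimum.
#'
#' @param day_stream Stream rows of a single participant-day, ordered by
#'   minute.
#' @param min_bout_seconds Minimum accumulated walking seconds for a bout to
#'   count (default 110).
#' @param max_gap_minutes Non-walking minutes tolerated inside a bout
#'   (default 0: one zero-walking minute ends the bout).
#' @return Data frame with one row per candidate bout: `start_minute`,
#'   `end_minute`, `n_minutes`, `walking_seconds`, `kept`.
#' @export
detect_walking_bouts <- function(day_stream, min_bout_seconds = 110,
                                 max_gap_minutes = 0) {
  if (min_bout_seconds <= 0) stop("`min_bout_seconds` must be positive", call. = FALSE)
  if (nrow(day_stream) == 0) {
    return(data.frame(start_minute = integer(), end_minute = integer(),
                      n_minutes = integer(), walking_seconds = numeric(),
                      kept = logical()))
  }
  if (any(diff(day_stream$minute) <= 0))
    stop("non-chronological stream: minutes must be strictly increasing",
         call. = FALSE)
  walk <- day_stream[day_stream$walking_seconds > 0, , drop = FALSE]
  if (nrow(walk) == 0) {
    return(data.frame(start_minute = integer(), end_minute = integer(),
                      n_minutes = integer(), walking_seconds = numeric(),
                      kept = logical()))
  }
  # new bout whenever the jump between successive walking minutes exceeds
  # the tolerated gap (absent minutes count as non-walking)
  bout_id <- cumsum(c(1L, as.integer(diff(walk$minute) > max_gap_minutes + 1L)))
  agg <- data.frame(
    start_minute = tapply(walk$minute, bout_id, min),
    end_minute = tapply(walk$minute, bout_id, max),
    n_minutes = as.integer(table(bout_id)),
    walking_seconds = tapply(walk$walking_seconds, bout_id, sum)
  )
  agg$kept <- agg$walking_seconds >= min_bout_seconds
  rownames(agg) <- NULL
  agg
}

#' Count exercise minutes in one participant-day
#'
#' Counts every minute whose mean heart rate lies inside the target zone
#' (closed interval). There is no minimum-bout filter: a single isolated
#' in-zone minute counts. Minutes with missing heart rate never count.
#'
#' @param day_stream Stream rows of a single participant-day.
#' @param zone An [hrr_zone()] object.
#' @return Number of exercise minutes (integer).
#' @export
count_exercise_minutes <- function(day_stream, zone) {
  stopifnot(is_hr_zone(zone))
  hr <- day_stream$mean_hr
  sum(!is.na(hr) & hr >= zone$lower & hr <= zone$upper)
}

#' Summarize one participant-day of wear
#'
#' Applies the walking-bout rule and the heart-rate-zone rule and returns
#' both daily tallies plus the bout inventory.
#'
#' @inheritParams detect_walking_bouts
#' @param zone An [hrr_zone()] object.
#' @return List of class `daily_minutes`: `date`, `walking_minutes`
#'   (surviving bouts' walking seconds / 60), `exercise_minutes`, `bouts`.
#' @export
summarize_day <- function(day_stream, zone, min_bout_seconds = 110,
                          max_gap_minutes = 0) {
  bouts <- detect_walking_bouts(day_stream, min_bout_seconds, max_gap_minutes)
  structure(list(
    date = if (nrow(day_stream)) as.Date(day_stream$date[1]) else as.Date(NA),
    walking_minutes = sum(bouts$walking_seconds[bouts$kept]) / 60,
    exercise_minutes = count_exercise_minutes(day_stream, zone),
    bouts = bouts
  ), class = "daily_minutes")
}

#' Derive daily walking and exercise minutes for a whole stream
#'
#' Splits a multi-participant, multi-day stream into participant-days and
#' applies [summarize_day()] to each. Heart-rate zones are personalised:
#' supply either a single zone for everyone or a named list keyed by
#' participant id.
#'
#' @param stream Validated minute stream (see [validate_stream()]).
#' @param zones One [hrr_zone()] or a named list of them per participant.
#' @inheritParams detect_walking_bouts
#' @return Data frame with `participant_id`, `date`, `walking_minutes`,
#'   `exercise_minutes`, one row per participant-day present in the stream.
#' @export
derive_daily_minutes <- function(stream, zones, min_bout_seconds = 110,
                                 max_gap_minutes = 0) {
  stream <- validate_stream(stream)
  zone_for <- function(pid) {
    if (is_hr_zone(zones)) return(zones)
    z <- zones[[as.character(pid)]]
    if (is.null(z)) stop("no heart-rate zone supplied for participant ", pid,
                         call. = FALSE)
    z
  }
  pieces <- split(stream, list(stream$participant_id, stream$date), drop = TRUE)
  rows <- lapply(pieces, function(d) {
    s <- summarize_day(d, zone_for(d$participant_id[1]),
                       min_bout_seconds, max_gap_minutes)
    data.frame(participant_id = as.character(d$participant_id[1]),
               date = s$date,
               walking_minutes = s$walking_minutes,
               exercise_minutes = s$exercise_minutes)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write minute streams
#'
#' CSV dialect: header `participant_id,date,minute,walking_seconds,mean_hr`,
#' ISO-8601 dates, minute-of-day 0-1439, missing heart rate as an empty
#' field.
#'
#' @param path CSV path.
#' @return `read_minute_stream`: validated stream data frame.
#' @export
read_minute_stream <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    participant_id = "character", date = "character", minute = "integer",
    walking_seconds = "numeric", mean_hr = "numeric"))
  validate_stream(df)
}

#' @rdname read_minute_stream
#' @param stream Stream data frame.
#' @export
write_minute_stream <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE, na = "")
  invisible(path)
}
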