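# Fixture builders and independent oracles shared across the suite.

# one participant-day of minute records; walking_seconds / mean_hr recycled
make_stream <- function(minutes, walking_seconds = 0, mean_hr = NA_real_,
                        date = as.Date("2020-01-06"), pid = "P001") {
  data.frame(participant_id = rep_len(pid, length(minutes)),
             date = rep_len(date, length(minutes)), minute = minutes,
             walking_seconds = rep_len(walking_seconds, length(minutes)),
             mean_hr = rep_len(mean_hr, length(minutes)))
}

# a Monday-anchored week of daily minutes (7-vectors, recycled)
make_week <- function(walk = 0, exercise = 0,
                      monday = as.Date("2020-01-06")) {
  data.frame(date = seq(monday, by = 1, length.out = 7),
             walking_minutes = rep_len(walk, 7),
             exercise_minutes = rep_len(exercise, 7))
}

# Exhaustive bout oracle: enumerate every maximal run of walking minutes by
# linear scan over the full minute grid, then filter by accumulated seconds.
oracle_walking_minutes <- function(day_stream, min_bout_seconds = 110) {
  if (nrow(day_stream) == 0) return(0)
  grid <- rep(0, 1440)
  grid[day_stream$minute + 1] <- day_stream$walking_seconds
  total <- 0; run <- 0
  for (m in 1:1440) {
    if (grid[m] > 0) run <- run + grid[m]
    else { if (run >= min_bout_seconds) total <- total + run; run <- 0 }
  }
  if (run >= min_bout_seconds) total <- total + run
  total / 60
}

# Day-by-day adherence oracle, recomputed from first principles
oracle_adherence <- function(week, rx, program) {
  monday <- week_monday(min(as.Date(week$date)))
  days <- seq(monday, by = 1, length.out = 7)
  col <- if (program == "walking") "walking_minutes" else "exercise_minutes"
  mins <- numeric(7)
  for (i in 1:7) {
    j <- which(as.Date(week$date) == days[i])
    if (length(j)) mins[i] <- week[[col]][j]
  }
  target <- if (program == "walking") rx$walk_target_min else rx$exercise_target_min
  freq <- if (program == "walking") rx$walk_days_per_week else rx$exercise_days_per_week
  met <- 0; tot <- 0
  for (i in 1:7) {
    if (mins[i] >= target) met <- met + 1
    tot <- tot + mins[i]
  }
  c(program = met / freq, volume = tot / (target * freq))
}
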