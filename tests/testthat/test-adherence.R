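rx <- prescription()  # 30 x 5 walking, 25 x 3 exercise, Mon-Fri / Mon-Wed-Fri

test_that("weekly volume targets follow from the prescription", {
  expect_equal(weekly_volume_target(rx, "walking"), 150)
  expect_equal(weekly_volume_target(rx, "exercise"), 75)
})

test_that("day states assign display marks by plan and achievement", {
  week <- make_week(walk = c(30, 0, 15, 0, 0, 35, 0))
  st <- day_states(week, rx)
  w <- st[st$program == "walking", ]
  expect_equal(w$mark[1], "check")            # planned Monday, exactly on target
  expect_equal(w$achieved_fraction[3], 0.5)   # planned Wednesday, half target
  expect_equal(w$mark[3], "none")
  expect_equal(w$mark[6], "opaque_check")     # unplanned Saturday, over target
  expect_true(w$target_met[6])
  # marks respect the invariants everywhere
  expect_true(all(st$target_met == (st$achieved_fraction >= 1), na.rm = TRUE))
  expect_true(all(st$mark[st$mark == "check"] ==
                    "check" & st$planned[st$mark == "check"]))
  expect_true(all(!st$planned[st$mark == "opaque_check"]))
})

test_that("program adherence is the uncapped met-days over frequency ratio", {
  wk <- make_week(walk = c(30, 0, 30, 30, 0, 0, 0))   # Mon, Wed, Thu
  expect_equal(program_adherence(wk, rx, "walking"), 0.6)
  wk6 <- make_week(walk = c(30, 30, 30, 30, 30, 30, 0))
  expect_equal(program_adherence(wk6, rx, "walking"), 1.2)
  expect_equal(program_adherence(make_week(), rx, "walking"), 0)
  expect_error(program_adherence(wk, prescription(walk_days_per_week = 0,
                                                  planned_walk_days = integer()),
                                 "walking"),
               "frequency")
})

test_that("volume adherence is the uncapped minutes over weekly-volume ratio", {
  expect_equal(volume_adherence(make_week(walk = c(60, 60, 60, 0, 0, 0, 0)),
                                rx, "walking"), 1.2)
  expect_equal(volume_adherence(make_week(walk = c(30, 30, 30, 30, 30, 0, 0)),
                                rx, "walking"), 1)
  expect_equal(volume_adherence(make_week(exercise = c(25, 25, 25, 0, 0, 0, 0)),
                                rx, "exercise"), 1)
})

test_that("weekly summaries partition the study into Monday-anchored weeks", {
  daily <- rbind(make_week(walk = 30, exercise = 25),
                 make_week(walk = 0, monday = as.Date("2020-01-13")),
                 make_week(walk = 15, monday = as.Date("2020-01-20")))
  s <- summarize_weeks(daily, rx, c("baseline", "week1", "week2"))
  expect_equal(nrow(s), 3)
  expect_equal(s$label, c("baseline", "week1", "week2"))
  expect_true(all(s$complete))
  expect_equal(s$walk_program_adherence[2], 0)
  expect_equal(s$walk_volume_adherence[3], 15 * 7 / 150)
  # a week meeting every target exactly scores 1.0 on all four metrics
  exact <- make_week(walk = c(30, 30, 30, 30, 30, 0, 0),
                     exercise = c(25, 0, 25, 0, 25, 0, 0))
  se <- summarize_weeks(exact, rx)
  expect_equal(unlist(se[1, 4:7]), rep(1, 4), ignore_attr = TRUE)
  expect_equal(se$days_meeting_walk_target, 5)
})

test_that("meeting targets on exactly the planned days gives adherence 1 and planned-only checks", {
  wk <- make_week(walk = c(30, 30, 30, 30, 30, 0, 0),
                  exercise = c(25, 0, 25, 0, 25, 0, 0))
  expect_equal(program_adherence(wk, rx, "walking"), 1)
  expect_equal(program_adherence(wk, rx, "exercise"), 1)
  st <- day_states(wk, rx)
  expect_true(all(st$mark[st$target_met] == "check"))
})

test_that("partial weeks are flagged incomplete", {
  daily <- data.frame(date = seq(as.Date("2020-01-08"), by = 1, length.out = 15),
                      walking_minutes = 30, exercise_minutes = 0)
  s <- summarize_weeks(daily, rx)
  expect_equal(s$complete, c(FALSE, TRUE, FALSE))
})

test_that("walking-only prescriptions report missing exercise metrics", {
  rxw <- prescription(walking_only = TRUE)
  wk <- make_week(walk = 30, exercise = 25)
  expect_true(is.na(program_adherence(wk, rxw, "exercise")))
  s <- summarize_weeks(wk, rxw)
  expect_true(is.na(s$exercise_volume_adherence))
  expect_false(is.na(s$walk_program_adherence))
})

test_that("weeks must be Monday-anchored", {
  tue <- data.frame(date = seq(as.Date("2020-01-07"), by = 1, length.out = 7),
                    walking_minutes = 0, exercise_minutes = 0)
  expect_error(day_states(tue, rx), "Monday|spans")
})

test_that("both adherence definitions match day-by-day recomputation on random weeks", {
  set.seed(99)
  for (i in 1:200) {
    n_days <- sample(1:7, 1)
    monday <- as.Date("2020-01-06") + 7 * sample(0:10, 1)
    days <- sort(sample(0:6, n_days))
    wk <- data.frame(date = monday + days,
                     walking_minutes = round(runif(n_days, 0, 90), 1),
                     exercise_minutes = round(runif(n_days, 0, 60), 1))
    for (pg in c("walking", "exercise")) {
      o <- oracle_adherence(wk, rx, pg)
      expect_identical(program_adherence(wk, rx, pg), o[["program"]])
      expect_equal(volume_adherence(wk, rx, pg), o[["volume"]], tolerance = 1e-14)
    }
  }
})

test_that("program adherence is step-valued and bounded by 7/frequency", {
  for (mins in seq(0, 60, by = 2.5)) {
    pa <- program_adherence(make_week(walk = mins), rx, "walking")
    expect_true(pa %in% (0:7 / 5))
    expect_lte(pa, 7 / 5)
  }
  # volume adherence is linear in any single day's minutes
  va <- sapply(c(10, 20, 30), function(m)
    volume_adherence(make_week(walk = c(m, 0, 0, 0, 0, 0, 0)), rx, "walking"))
  expect_equal(diff(va), rep(10 / 150, 2))
})

test_that("percent-scale long output matches the summaries", {
  wk <- make_week(walk = c(30, 30, 30, 30, 30, 30, 0))
  s <- summarize_weeks(wk, rx)
  long <- adherence_long(s)
  expect_equal(long$value_percent[long$metric == "walk_program_adherence"], 120)
})
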