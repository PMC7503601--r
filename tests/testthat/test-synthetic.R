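test_that("generation is deterministic for a fixed seed", {
  spec <- cohort_spec(n_participants = 8, seed = 3)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  s1 <- generate_study(spec, behavior_spec(), prescription(), n_weeks = 1, seed = 3)
  s2 <- generate_study(spec, behavior_spec(), prescription(), n_weeks = 1, seed = 3)
  expect_identical(s1$streams, s2$streams)
  expect_identical(s1$truth_daily, s2$truth_daily)
})

test_that("cohort spec is validated", {
  expect_error(cohort_spec(n_participants = 1), "at least 2")
  expect_error(cohort_spec(phenotype_mix = 1.5), "phenotype_mix")
  expect_error(cohort_spec(effect_sizes = c(nope = 1)), "unknown features")
})

test_that("phenotype mix controls the split", {
  spec <- cohort_spec(n_participants = 10, seed = 5, phenotype_mix = 0.5,
                      exact_split = TRUE)
  co <- generate_cohort(spec)
  expect_equal(sum(co$truth$phenotype == "adherent"), 5)
  expect_equal(nrow(co$profiles), 10)
  expect_setequal(co$truth$participant_id, co$profiles$participant_id)
})

test_that("zero effect sizes leave the phenotypes indistinguishable", {
  # under the null the between-phenotype location test should reject ~5%
  pvals <- sapply(1:100, function(s) {
    spec <- cohort_spec(n_participants = 40, seed = s, phenotype_mix = 0.5,
                        exact_split = TRUE, effect_sizes = c(hr_rest = 0))
    co <- generate_cohort(spec)
    adh <- co$truth$phenotype == "adherent"
    t.test(co$profiles$hr_rest[adh], co$profiles$hr_rest[!adh])$p.value
  })
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("generated features track the spec's means and SDs at n = 1000", {
  spec <- cohort_spec(n_participants = 1000, seed = 17, effect_sizes = numeric())
  co <- generate_cohort(spec)
  z <- sapply(names(spec$feature_distributions), function(f) {
    ms <- spec$feature_distributions[[f]]
    (mean(co$profiles[[f]]) - ms[1]) / (ms[2] / sqrt(1000))
  })
  # a 2-SE band is a ~95% coverage statement per feature; allow one excursion
  expect_lte(sum(abs(z) > 2), 1)
  expect_true(all(abs(z) < 4))
  sd_ratio <- sapply(names(spec$feature_distributions), function(f)
    sd(co$profiles[[f]]) / spec$feature_distributions[[f]][2])
  expect_true(all(sd_ratio > 0.9 & sd_ratio < 1.1))
})

test_that("the adherent phenotype is shifted on the designated features", {
  spec <- cohort_spec(n_participants = 400, seed = 8, phenotype_mix = 0.5,
                      exact_split = TRUE)
  co <- generate_cohort(spec)
  adh <- co$truth$phenotype == "adherent"
  expect_lt(mean(co$profiles$hr_rest[adh]), mean(co$profiles$hr_rest[!adh]) - 8)
  expect_lt(mean(co$profiles$apq_risk[adh]), mean(co$profiles$apq_risk[!adh]) - 0.5)
  # undesignated features unshifted (within noise)
  expect_lt(abs(mean(co$profiles$pcs12[adh]) - mean(co$profiles$pcs12[!adh])), 1)
})

test_that("perfect-fidelity exercise sessions are fully recovered by the counter", {
  spec <- cohort_spec(n_participants = 2, seed = 12, phenotype_mix = 1)
  cohort <- generate_cohort(spec)
  plan <- plan_sessions(cohort, closed_loop_behavior(), prescription(),
                        n_weeks = 1, seed = 12)
  streams <- sessions_to_streams(plan, cohort, closed_loop_behavior(), seed = 13)
  zones <- participant_zones(cohort$profiles)
  pid <- cohort$profiles$participant_id[1]
  ses <- plan$sessions
  one <- ses[ses$participant_id == pid & ses$program == "exercise", ][1, ]
  day <- streams[streams$participant_id == pid & streams$date == one$date, ]
  expect_equal(count_exercise_minutes(day, zones[[pid]]), one$duration_min)
  expect_equal(one$in_zone_min, one$duration_min)  # fidelity 1
})

test_that("zero attempt probabilities yield zero adherence", {
  none <- list(walk_attempt_p = 0, exercise_attempt_p = 0,
               unplanned_walk_p = 0, unplanned_exercise_p = 0,
               walk_duration_mult = c(1, 0), exercise_duration_mult = c(1, 0),
               hr_fidelity = 1, incidental_zone_per_day = 0)
  beh <- behavior_spec(adherent = none, nonadherent = none, weather_p = 0,
                       missing_hr_p = 0)
  spec <- cohort_spec(n_participants = 3, seed = 21)
  study <- generate_study(spec, beh, prescription(), n_weeks = 1, seed = 21)
  daily <- derive_daily_minutes(study$streams, study$zones)
  rx <- prescription()
  for (d in split(daily, daily$participant_id)) {
    s <- summarize_weeks(d, rx)
    expect_equal(unlist(s[1, 4:7]), rep(0, 4), ignore_attr = TRUE)
  }
})

test_that("ground-truth daily minutes equal the stream-derived pipeline output", {
  spec <- cohort_spec(n_participants = 4, seed = 31, exact_split = TRUE,
                      phenotype_mix = 0.5)
  study <- generate_study(spec, closed_loop_behavior(), prescription(),
                          n_weeks = 2, seed = 31)
  daily <- derive_daily_minutes(study$streams, study$zones)
  m <- merge(daily, study$truth_daily, by = c("participant_id", "date"))
  expect_equal(nrow(m), 4 * 14)
  expect_equal(m$walking_minutes.x, m$walking_minutes.y)
  expect_equal(m$exercise_minutes.x, m$exercise_minutes.y)
})

test_that("study files round-trip through the documented dialects", {
  spec <- cohort_spec(n_participants = 2, seed = 41)
  study <- generate_study(spec, behavior_spec(), prescription(), n_weeks = 1,
                          seed = 41)
  dir <- tempfile()
  paths <- write_study(study, dir)
  expect_true(all(file.exists(paths)))
  back <- read_minute_stream(paths[["streams"]])
  expect_equal(nrow(back), nrow(study$streams))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$phenotypes$participant_id,
                  study$cohort$truth$participant_id)
  unlink(dir, recursive = TRUE)
})
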