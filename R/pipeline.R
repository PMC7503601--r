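#' Default study configuration
#'
#' One nested list drives the whole pipeline: cohort spec, behaviour spec,
#' prescription, study calendar (one baseline week plus intervention weeks,
#' Monday-anchored), a single top-level seed (fanned out to stage seeds as
#' seed + stage index), output directory and analysis toggles.
#'
#' @param seed Top-level integer seed.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = "wearadhere-out") {
  list(
    seed = seed,
    output_dir = out_dir,
    calendar = list(start_monday = "2020-01-06", baseline_weeks = 1,
                    intervention_weeks = 2),
    cohort = list(n_participants = 10, phenotype_mix = 0.4,
                  exact_split = TRUE),
    behavior = list(preset = "default"),
    prescription = list(walk_target_min = 30, walk_days_per_week = 5,
                        exercise_target_min = 25, exercise_days_per_week = 3,
                        planned_walk_days = c("Mon", "Tue", "Wed", "Thu", "Fri"),
                        planned_exercise_days = c("Mon", "Wed", "Fri"),
                        zone_lower_frac = 0.5, zone_upper_frac = 0.8),
    analysis = list(profiling = TRUE, statistics = TRUE,
                    profiling_target = "exercise_program_adherence",
                    min_bout_seconds = 110)
  )
}

#' Read / write a study configuration
#'
#' YAML or JSON by extension.
#'
#' @param path Config file path.
#' @return `read_config`: configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::read_yaml(path),
         json = jsonlite::read_json(path, simplifyVector = TRUE),
         stop("unsupported config extension: ", ext, call. = FALSE))
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(config, path)
  else if (ext == "json")
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported config extension: ", ext, call. = FALSE)
  invisible(path)
}

#' Validate a study configuration
#'
#' Structural checks returning a data frame of issues (field, message); an
#' empty frame means the configuration is runnable.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Data frame with columns `field`, `issue`.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(field, msg) issues[[length(issues) + 1]] <<-
    data.frame(field = field, issue = msg)
  for (f in c("seed", "calendar", "cohort", "prescription"))
    if (is.null(config[[f]])) add(f, "missing required section")
  rx <- config$prescription
  if (!is.null(rx)) {
    if (!is.null(rx$walk_target_min) && rx$walk_target_min < 0)
      add("prescription.walk_target_min", "negative walking target")
    if (!is.null(rx$exercise_target_min) && rx$exercise_target_min < 0)
      add("prescription.exercise_target_min", "negative exercise target")
    lo <- rx$zone_lower_frac; hi <- rx$zone_upper_frac
    if (!is.null(lo) && !is.null(hi) && hi <= lo)
      add("prescription.zone_upper_frac",
          "zone fractions out of order (upper <= lower)")
    if (!is.null(rx$planned_walk_days) && !is.null(rx$walk_days_per_week) &&
        length(rx$planned_walk_days) != rx$walk_days_per_week)
      add("prescription.planned_walk_days",
          "planned day count does not match days per week")
  }
  cal <- config$calendar
  if (!is.null(cal$start_monday) &&
      iso_weekday(as.Date(cal$start_monday)) != 1L)
    add("calendar.start_monday", "study calendar must start on a Monday")
  if (!is.null(config$cohort$n_participants) &&
      config$cohort$n_participants < 2)
    add("cohort.n_participants", "need at least 2 participants")
  if (length(issues)) do.call(rbind, issues)
  else data.frame(field = character(), issue = character())
}

sort_recursive <- function(x) {
  if (is.list(x) && !is.null(names(x)))
    x <- lapply(x[order(names(x))], sort_recursive)
  x
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sort_recursive(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

config_to_objects <- function(config) {
  rxc <- config$prescription
  rx <- prescription(
    walk_target_min = rxc$walk_target_min %||% 30,
    walk_days_per_week = rxc$walk_days_per_week %||% 5,
    exercise_target_min = rxc$exercise_target_min %||% 25,
    exercise_days_per_week = rxc$exercise_days_per_week %||% 3,
    planned_walk_days = rxc$planned_walk_days %||% c("Mon", "Tue", "Wed", "Thu", "Fri"),
    planned_exercise_days = rxc$planned_exercise_days %||% c("Mon", "Wed", "Fri"))
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  beh <- if (identical(config$behavior$preset, "closed_loop"))
    closed_loop_behavior() else behavior_spec()
  list(rx = rx, spec = spec, behavior = beh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full adherence pipeline
#'
#' Simulate (or load) minute streams, derive daily minutes under the bout
#' rules, score weekly adherence for both definitions and both programs,
#' optionally run the profiling chain and the week-by-week statistics, and
#' write every table plus a run manifest to the output directory. A failed
#' stage leaves earlier outputs intact and marks the manifest
#' `failed_at_stage`.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   first.
#' @param out_dir Overrides `config$output_dir` when given.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  issues <- validate_config(config)
  if (nrow(issues))
    stop("invalid config: ", paste(issues$field, issues$issue, sep = ": ",
                                   collapse = "; "), call. = FALSE)
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("wearadhere")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = config$seed, files = character(),
                   failed_at_stage = NULL)
  emit <- function(name, df) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    manifest$files <<- c(manifest$files, name)
    p
  }
  obj <- config_to_objects(config)
  n_weeks <- config$calendar$baseline_weeks + config$calendar$intervention_weeks
  labels <- c(rep("baseline", config$calendar$baseline_weeks),
              paste0("week", seq_len(config$calendar$intervention_weeks)))
  stage <- "simulate"
  res <- tryCatch({
    study <- generate_study(obj$spec, obj$behavior, obj$rx, n_weeks,
                            seed = config$seed + 1L,
                            start_date = as.Date(config$calendar$start_monday))
    emit("cohort_profiles.csv", study$cohort$profiles)
    emit("ground_truth_phenotypes.csv", study$cohort$truth)
    emit("minute_streams.csv", study$streams)

    stage <- "derive"
    daily <- derive_daily_minutes(
      study$streams, study$zones,
      min_bout_seconds = config$analysis$min_bout_seconds %||% 110)
    emit("daily_minutes.csv", daily)

    stage <- "adhere"
    wo_ids <- config$prescription$walking_only_ids %||% character()
    rx_wo <- prescription(walk_target_min = obj$rx$walk_target_min,
                          walk_days_per_week = obj$rx$walk_days_per_week,
                          planned_walk_days = obj$rx$planned_walk_days,
                          walking_only = TRUE)
    summaries <- do.call(rbind, lapply(split(daily, daily$participant_id),
      function(d) {
        rx_i <- if (d$participant_id[1] %in% wo_ids) rx_wo else obj$rx
        s <- summarize_weeks(d, rx_i, labels)
        cbind(participant_id = d$participant_id[1], s)
      }))
    rownames(summaries) <- NULL
    emit("adherence_weekly.csv", summaries)
    emit("adherence_long_percent.csv", adherence_long(summaries))
    emit("adherence_group_table.csv", adherence_group_table(summaries))

    prof <- NULL
    if (isTRUE(config$analysis$profiling)) {
      stage <- "profile"
      target_name <- config$analysis$profiling_target %||%
        "exercise_program_adherence"
      tgt <- tapply(summaries[[target_name]],
                    summaries$participant_id, mean)
      profiles <- study$cohort$profiles
      tgt <- as.numeric(tgt[profiles$participant_id])
      # walking-only participants have no exercise outcome; profile the rest
      keep <- !is.na(tgt)
      profiles <- profiles[keep, , drop = FALSE]
      tgt <- tgt[keep]
      feature_cols <- setdiff(
        names(profiles)[vapply(profiles, is.numeric, logical(1))],
        c("crf_abs_ml_min"))  # keep one CRF scale; absolute tracks body size
      prof <- profile_adherence(profiles, tgt, feature_cols,
                                seed = config$seed + 3L)
      sel <- data.frame(feature = names(prof$selection$status),
                        status = as.character(prof$selection$status),
                        hits = prof$selection$hits,
                        n_iter = prof$selection$n_iter)
      emit("profiling_selection.csv", sel)
      if (!is.null(prof$cluster))
        emit("profiling_clusters.csv",
             data.frame(participant_id = profiles$participant_id,
                        cluster = prof$cluster$assignments))
      p <- file.path(out_dir, "profiling_result.json")
      jsonlite::write_json(
        list(target = target_name, features_used = prof$features_used,
             n_iter = prof$selection$n_iter,
             cluster_sizes = if (!is.null(prof$cluster))
               as.integer(table(prof$cluster$assignments))),
        p, auto_unbox = TRUE, digits = NA)
      manifest$files <- c(manifest$files, "profiling_result.json")
    }

    if (isTRUE(config$analysis$statistics)) {
      stage <- "stats"
      emit("adherence_time_tests.csv", adherence_time_tests(summaries))
    }
    list(summaries = summaries, profiling = prof)
  }, error = function(e) {
    manifest$failed_at_stage <<- stage
    manifest$error <<- conditionMessage(e)
    NULL
  })
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Group-level adherence table (percent scale)
#'
#' Mean and SD of each adherence metric per study week across participants,
#' percentages rendered with 0 decimals, plus counts of participants
#' reaching each weekly target — the usual layout for reporting a cohort's
#' weekly adherence.
#'
#' @param summaries Per-participant weekly summaries (from the pipeline).
#' @return Data frame, one row per metric, one column per week.
#' @export
adherence_group_table <- function(summaries) {
  weeks <- unique(summaries$label)
  metrics <- c(`Walking program adherence (%)` = "walk_program_adherence",
               `Walking volume adherence (%)` = "walk_volume_adherence",
               `Exercise program adherence (%)` = "exercise_program_adherence",
               `Exercise volume adherence (%)` = "exercise_volume_adherence")
  rows <- lapply(names(metrics), function(lbl) {
    col <- metrics[[lbl]]
    vals <- vapply(weeks, function(w) {
      v <- summaries[[col]][summaries$label == w]
      sprintf("%.0f ± %.0f", mean(100 * v, na.rm = TRUE),
              stats::sd(100 * v, na.rm = TRUE))
    }, character(1))
    reach <- vapply(weeks, function(w) {
      v <- summaries[[col]][summaries$label == w]
      sprintf("%d/%d", sum(v >= 1, na.rm = TRUE), sum(!is.na(v)))
    }, character(1))
    rbind(stats::setNames(data.frame(lbl, t(vals)), c("Adherence", weeks)),
          stats::setNames(data.frame(paste0("  reaching target"), t(reach)),
                          c("Adherence", weeks)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Week-over-week adherence tests
#'
#' For each adherence metric: a normality-gated repeated-measures analysis
#' over the study weeks ([rm_anova()], which falls back to Friedman), in
#' the layout of a pre/post statistics table.
#'
#' @param summaries Per-participant weekly summaries.
#' @return Data frame: metric, test, statistic, df, p.
#' @export
adherence_time_tests <- function(summaries) {
  metrics <- c("walk_program_adherence", "walk_volume_adherence",
               "exercise_program_adherence", "exercise_volume_adherence")
  rows <- lapply(metrics, function(m) {
    long <- data.frame(id = summaries$participant_id, time = summaries$label,
                       value = summaries[[m]])
    res <- tryCatch(rm_anova(long), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(metric = m, test = NA, statistic = NA, df = NA, p = NA))
    data.frame(metric = m, test = res$test_name, statistic = res$statistic,
               df = paste(signif(res$df, 4), collapse = ";"),
               p = res$p_value)
  })
  do.call(rbind, rows)
}
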