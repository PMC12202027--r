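# End-to-end pipeline driver: clean -> quality -> locomotion -> motion
# index -> swings -> tremor, routed by task, with the full configuration
# echoed into every report for provenance.

#' Pipeline configuration with all analysis defaults
#'
#' Every threshold of the analysis chain in one place, overridable per
#' call: gap filling below 50 frames; jitter 0.05 mm / up to 3 frames;
#' locomotory episodes above 40 mm/s for at least 100 frames with dips up
#' to 50 frames; a 100-frame onset-detection speed window and a 1 s
#' reporting window; 10-frame motion-index window; 30-frame swing speed
#' window; 6-18 Hz tremor band with a 10% derivative threshold and a
#' 150-frame amplitude window; 10 mm/s movement split.
#'
#' @param ... named overrides of any default.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    gap_fill_max_frames = 50,
    jitter_prominence_mm = 0.05,
    jitter_max_width_frames = 3,
    episode_threshold_mm_s = 40,
    episode_min_frames = 100,
    episode_max_dip_frames = 50,
    onset_speed_window_frames = 100,
    report_speed_window_s = 1,
    mi_window_frames = 10,
    mi_dims = 3,
    swing_speed_window_frames = 30,
    treadmill_min_prominence_mm = 1,
    tremor_band_hz = c(6, 18),
    tremor_deriv_frac = 0.1,
    amplitude_window_frames = 150,
    movement_split_mm_s = 10,
    bin_s = 10,
    hip_labels = c("hip_L", "hip_R"),
    ankle_labels = c("ankle_L", "ankle_R")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Run the full analysis pipeline on one trial
#'
#' Stages are routed by task: cleaning, quality report and locomotion run
#' for every task; surface-relative correction precedes locomotion for CLB
#' and TRM; swings use the vertical-minima detector for TRM and the
#' acceleration-peak detector for OF/CLB; the tremor scan runs for every
#' task and reports "no band" per marker-axis where none is found. Stage
#' failures are caught and recorded; completed stages are preserved.
#'
#' @param trial a [trial_recording()] or a path to a trial TSV (with a
#'   `.yaml` metadata sidecar next to it).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory to write the report files (summary
#'   JSON, episode and swing CSVs) into.
#' @return object of class `mocap_report`; `$ok` is TRUE iff no stage
#'   errored.
#' @export
run_pipeline <- function(trial, config = pipeline_config(), out_dir = NULL) {
  if (is.character(trial)) {
    side <- sub("\\.tsv$", ".yaml", trial)
    trial <- read_trial(trial, meta_path = if (file.exists(side)) side)
  }
  stopifnot(inherits(trial, "trial_recording"))
  report <- list(
    trial_id = trial$trial_id, task = trial$task,
    frame_rate = trial$frame_rate, n_frames = trial_frames(trial),
    config = unclass(config), errors = list()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  fr <- trial$frame_rate

  cleaned <- stage("clean", clean_trial(
    trial, config$gap_fill_max_frames,
    config$jitter_prominence_mm, config$jitter_max_width_frames
  ))
  work <- if (is.null(cleaned)) trial else cleaned$trial
  report$repair <- if (!is.null(cleaned)) {
    list(n_gaps = NROW(cleaned$gaps),
         n_gaps_filled = sum(cleaned$gaps$filled %||% logical(0)),
         n_jitter_events = NROW(cleaned$jitter))
  }

  rel <- if (trial$task %in% c("CLB", "TRM")) {
    stage("surface_relative", surface_relative(work))
  } else {
    work
  }

  loco <- stage("locomotion", {
    ref_trial <- rel %||% work
    ref <- hip_midpoint(ref_trial, config$hip_labels)
    onset_speed <- windowed_speed(ref, config$onset_speed_window_frames, fr)
    episodes <- detect_locomotion_episodes(
      onset_speed, config$episode_threshold_mm_s,
      config$episode_min_frames, config$episode_max_dip_frames
    )
    report_speed <- windowed_speed(
      ref, as.integer(round(config$report_speed_window_s * fr)), fr
    )
    list(
      reference = ref, episodes = episodes, speed = report_speed,
      summary = trial_locomotion_summary(ref, episodes, report_speed, fr,
        bin_s = config$bin_s
      )
    )
  })
  episodes <- loco$episodes %||% data.frame(
    start = integer(), end = integer(),
    duration_frames = integer(), mean_speed = numeric()
  )
  report$episodes <- episodes
  report$locomotion <- loco$summary

  report$quality <- stage("qc", quality_report(
    work, episodes,
    gaps = if (!is.null(cleaned) && NROW(cleaned$gaps)) cleaned$gaps
  ))

  report$motion_index <- stage("mi", motion_index(
    work, episodes, config$mi_window_frames,
    dims = config$mi_dims, bin_s = config$bin_s
  ))

  report$swings <- stage("swings", {
    sw_trial <- if (trial$task %in% c("CLB", "TRM")) {
      if (is.null(rel)) stop("surface-relative correction failed; swings need surface markers")
      rel
    } else {
      work
    }
    out <- list()
    for (lab in intersect(config$ankle_labels, names(sw_trial$markers))) {
      ankle <- sw_trial$markers[[lab]]
      ev <- if (trial$task == "TRM") {
        detect_swings_treadmill(ankle, fr,
          prominence_mm = config$treadmill_min_prominence_mm
        )
      } else {
        detect_swings_accel(ankle, fr, config$swing_speed_window_frames,
          context = trial$task
        )
      }
      out[[lab]] <- swing_metrics(ev, ankle, fr)
    }
    out
  })

  report$tremor <- stage("tremor", {
    scan <- tremor_scan(work,
      band = config$tremor_band_hz,
      deriv_frac = config$tremor_deriv_frac,
      amplitude_window_frames = config$amplitude_window_frames
    )
    list(scan = scan, summary = tremor_summary(
      scan, loco$speed, config$movement_split_mm_s
    ))
  })

  report$ok <- length(report$errors) == 0
  class(report) <- "mocap_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    trial_id = report$trial_id, task = report$task,
    frame_rate = report$frame_rate, n_frames = report$n_frames,
    config = report$config, repair = report$repair,
    locomotion = if (!is.null(report$locomotion)) {
      report$locomotion[c("distance_mm", "time_locomoting_s", "mean_locomotory_speed")]
    },
    motion_index = if (!is.null(report$motion_index)) {
      report$motion_index[c("mean_mi", "mean_mi_locomotory", "mean_mi_stationary")]
    },
    tremor = if (!is.null(report$tremor)) {
      df <- report$tremor$scan$table
      lapply(split(df, seq_len(nrow(df))), as.list)
    },
    errors = report$errors, ok = report$ok
  )
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  utils::write.csv(report$episodes, file.path(out_dir, "episodes.csv"),
    row.names = FALSE
  )
  if (!is.null(report$swings)) {
    sw <- do.call(rbind, lapply(names(report$swings), function(lab) {
      d <- report$swings[[lab]]
      if (NROW(d)) cbind(ankle = lab, d)
    }))
    if (!is.null(sw)) utils::write.csv(sw, file.path(out_dir, "swings.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.mocap_report <- function(x, ...) {
  cat(sprintf(
    "<mocap_report '%s' (%s): %d frames @ %g fps; %s>\n",
    x$trial_id, x$task, x$n_frames, x$frame_rate,
    if (x$ok) "all stages ok" else paste("errors in:", paste(names(x$errors), collapse = ", "))
  ))
  if (!is.null(x$locomotion)) print(x$locomotion)
  if (!is.null(x$motion_index)) print(x$motion_index)
  if (!is.null(x$tremor)) print(x$tremor$scan)
  invisible(x)
}

#' @export
summary.mocap_report <- function(object, ...) {
  n_sw <- if (!is.null(object$swings)) {
    sum(vapply(object$swings, function(d) sum(d$valid %||% logical(0)), numeric(1)))
  } else {
    NA
  }
  cat(sprintf(
    "Trial '%s' (%s): %d locomotory episodes, %s valid swings\n",
    object$trial_id, object$task, NROW(object$episodes),
    if (is.na(n_sw)) "no" else n_sw
  ))
  invisible(object)
}
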