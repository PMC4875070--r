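# Graded exercise test (GXT) data model: CSV dialects, stage-level VO2
# derivation from breath-by-breath traces, and protocol validation.
#
# A cohort is a single tidy tibble in the stage-level dialect: one row per
# protocol stage, with the participant-level peak values repeated on each of
# that participant's rows. Breath-by-breath traces, when present, travel in
# the "breaths" attribute.

# Column dictionaries for the two CSV dialects.
.stage_cols <- c(
  "participant_id", "stage_index", "speed_kmh", "stage_vo2",
  "cert_rpe", "ep_rpe", "vo2peak_measured", "hr_peak", "peak_speed_kmh",
  "terminal_cert", "terminal_ep"
)
.breath_cols <- c("participant_id", "time_s", "vo2")
.schedule_cols <- c(
  "participant_id", "stage_index", "speed_kmh", "start_s", "end_s",
  "cert_rpe", "ep_rpe"
)

#' Coerce a data frame to a GXT cohort
#'
#' A GXT cohort is a tibble with one row per exercise stage. Mandatory
#' columns are `participant_id`, `stage_index`, `speed_kmh` (km/h),
#' `stage_vo2` (ml/kg/min, mean of the final 10 s of each stage),
#' `cert_rpe` and `ep_rpe` (the stage's ratings of perceived exertion on the
#' CERT 1-10 and Eston-Parfitt 0-10 scales, `NA` when not reported), and the
#' per-participant peak values `vo2peak_measured`, `hr_peak`,
#' `peak_speed_kmh`, `terminal_cert`, `terminal_ep`, repeated on every row
#' of that participant.
#'
#' @param x A data frame with the stage-level columns above.
#' @return A `gxt_cohort` tibble ordered by participant and stage.
#' @export
as_gxt_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  missing <- setdiff(.stage_cols, names(x))
  if (length(missing) > 0) {
    stop_format(paste0(
      "missing mandatory column(s): ", paste(missing, collapse = ", ")
    ))
  }
  dup <- x |>
    dplyr::count(.data$participant_id, .data$stage_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_format(paste0(
      "duplicated (participant, stage) pairs: ",
      paste(dup$participant_id, dup$stage_index, sep = "/", collapse = ", ")
    ))
  }
  x <- dplyr::arrange(x, .data$participant_id, .data$stage_index)
  class(x) <- unique(c("gxt_cohort", class(x)))
  x
}

#' @export
print.gxt_cohort <- function(x, ...) {
  cat(sprintf(
    "<gxt_cohort> %d participants, %d stage records\n",
    dplyr::n_distinct(x$participant_id), nrow(x)
  ))
  NextMethod()
}

#' Participant-level view of a cohort
#'
#' Collapses a stage-level cohort to one row per participant, keeping the
#' peak/terminal columns.
#'
#' @param cohort A `gxt_cohort` tibble.
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_stages`, `vo2peak_measured`, `hr_peak`, `peak_speed_kmh`,
#'   `terminal_cert`, `terminal_ep`.
#' @export
gxt_participants <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_stages = dplyr::n(),
      vo2peak_measured = .data$vo2peak_measured[1],
      hr_peak = .data$hr_peak[1],
      peak_speed_kmh = .data$peak_speed_kmh[1],
      terminal_cert = .data$terminal_cert[1],
      terminal_ep = .data$terminal_ep[1],
      .groups = "drop"
    )
}

#' Read a GXT cohort from CSV
#'
#' Two dialects are supported. `"stage_level"` reads a single CSV in the
#' [as_gxt_cohort()] column dictionary. `"breath_level"` reads a
#' breath-by-breath CSV (`participant_id`, `time_s`, `vo2`, optional `hr`,
#' `ve`, `rer`) together with a stage-schedule CSV (`participant_id`,
#' `stage_index`, `speed_kmh`, `start_s`, `end_s`, `cert_rpe`, `ep_rpe`);
#' stage VO2 values are then derived with [stage_vo2()] over the final 10 s
#' of each stage, and participant peak values are derived from the trace
#' (VO2peak as the highest stage VO2, terminal RPEs as the last reported
#' rating on each scale).
#'
#' @param path Path to the stage-level CSV, or to the breath-level CSV when
#'   `format = "breath_level"`.
#' @param format One of `"stage_level"`, `"breath_level"`.
#' @param schedule Path to the stage-schedule CSV (breath-level only).
#' @return A `gxt_cohort` tibble; for breath-level input the raw trace is
#'   attached as the `"breaths"` attribute.
#' @export
read_gxt_cohort <- function(path,
                            format = c("stage_level", "breath_level"),
                            schedule = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_format(paste0("input file does not exist: ", path))
  }
  if (format == "stage_level") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(as_gxt_cohort(df))
  }

  if (is.null(schedule)) {
    stop_format("breath-level input requires a `schedule` CSV")
  }
  breaths <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sched <- readr::read_csv(schedule, show_col_types = FALSE, progress = FALSE)
  miss_b <- setdiff(.breath_cols, names(breaths))
  miss_s <- setdiff(.schedule_cols, names(sched))
  if (length(miss_b) > 0 || length(miss_s) > 0) {
    stop_format(paste0(
      "missing mandatory column(s): ",
      paste(c(miss_b, miss_s), collapse = ", ")
    ))
  }

  sched <- dplyr::arrange(sched, .data$participant_id, .data$stage_index)
  split_breaths <- split(breaths, breaths$participant_id)
  sched$stage_vo2 <- purrr::pmap_dbl(
    list(sched$participant_id, sched$start_s, sched$end_s),
    function(pid, start_s, end_s) {
      b <- split_breaths[[as.character(pid)]]
      if (is.null(b) || (end_s - start_s) < 10) {
        return(NA_real_)
      }
      stage_vo2(b, start_s, end_s)
    }
  )

  last_reported <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else x[length(x)]
  }
  per_part <- sched |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      vo2peak_measured = max(.data$stage_vo2, na.rm = TRUE),
      peak_speed_kmh = max(.data$speed_kmh),
      terminal_cert = last_reported(.data$cert_rpe),
      terminal_ep = last_reported(.data$ep_rpe),
      .groups = "drop"
    )
  hr_peak <- breaths |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      hr_peak = if ("hr" %in% names(breaths) && any(!is.na(.data$hr))) {
        max(.data$hr, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  cohort <- sched |>
    dplyr::left_join(per_part, by = "participant_id") |>
    dplyr::left_join(hr_peak, by = "participant_id")
  cohort <- as_gxt_cohort(cohort)
  attr(cohort, "breaths") <- tibble::as_tibble(breaths)
  cohort
}

#' Write a GXT cohort to CSV
#'
#' @param cohort A `gxt_cohort` tibble.
#' @param path Output path for the stage-level CSV, or for the breath-level
#'   CSV when `format = "breath_level"`.
#' @param format One of `"stage_level"`, `"breath_level"`.
#' @param schedule Output path for the stage-schedule CSV (breath-level
#'   only).
#' @return The input `cohort`, invisibly.
#' @export
write_gxt_cohort <- function(cohort, path,
                             format = c("stage_level", "breath_level"),
                             schedule = NULL) {
  format <- match.arg(format)
  if (nrow(cohort) == 0) {
    abort("refusing to write an empty cohort")
  }
  if (format == "stage_level") {
    out <- dplyr::select(tibble::as_tibble(cohort), dplyr::all_of(.stage_cols))
    write_atomic(path, function(p) readr::write_csv(out, p, progress = FALSE))
    return(invisible(cohort))
  }

  breaths <- attr(cohort, "breaths")
  if (is.null(breaths)) {
    abort("cohort carries no breath-by-breath trace; simulate with `emit_breath_level = TRUE` or read breath-level input")
  }
  if (is.null(schedule)) {
    abort("breath-level output requires a `schedule` path")
  }
  if (!all(c("start_s", "end_s") %in% names(cohort))) {
    abort("breath-level output requires `start_s`/`end_s` stage columns")
  }
  sched <- dplyr::select(
    tibble::as_tibble(cohort),
    dplyr::all_of(.schedule_cols)
  )
  write_atomic(path, function(p) readr::write_csv(tibble::as_tibble(breaths), p, progress = FALSE))
  write_atomic(schedule, function(p) readr::write_csv(sched, p, progress = FALSE))
  invisible(cohort)
}

#' Stage VO2 from a breath-by-breath trace
#'
#' Averages VO2 over the final 10 s of a stage. The averaging window is the
#' half-open interval `(window_end_s - 10, window_end_s]` (clipped below at
#' `window_start_s`), so a sample falling exactly on a stage boundary
#' belongs to the ending stage and is never double counted by the next one.
#'
#' @param breaths A data frame with columns `time_s` (seconds from test
#'   start) and `vo2` (ml/kg/min).
#' @param window_start_s,window_end_s Stage boundaries in seconds.
#' @return The mean VO2 (ml/kg/min) over the window, or `NA` (with a
#'   `peakrpe_no_samples_in_window` warning) when the window holds no
#'   samples.
#' @export
stage_vo2 <- function(breaths, window_start_s, window_end_s) {
  lower <- max(window_start_s, window_end_s - 10)
  sel <- breaths$time_s > lower & breaths$time_s <= window_end_s
  sel <- sel & !is.na(breaths$vo2)
  if (!any(sel, na.rm = TRUE)) {
    warn(
      sprintf(
        "no VO2 samples in (%g, %g]; returning NA (NO_SAMPLES_IN_WINDOW)",
        lower, window_end_s
      ),
      class = "peakrpe_no_samples_in_window"
    )
    return(NA_real_)
  }
  mean(breaths$vo2[sel])
}

#' Validate a GXT cohort against the incremental treadmill protocol
#'
#' Checks each participant's records against the protocol (7 km/h start,
#' +0.5 km/h per 1-min stage) and the type invariants, returning issues
#' rather than raising them. Issue codes: `PROTOCOL_SPEED_MISMATCH` (stage
#' speed off the 7 + 0.5 (stage - 1) schedule), `RPE_OUT_OF_RANGE` (CERT
#' outside 1-10 or EP outside 0-10), `NO_PEAK` (missing VO2peak, or VO2peak
#' below the highest stage VO2 by more than `peak_tol`), `TOO_FEW_STAGES`
#' (fewer than `min_stages` stages), `NON_MONOTONIC_TIME` (breath timestamps
#' not strictly increasing, checked when a trace is available).
#'
#' @param cohort A `gxt_cohort` tibble.
#' @param breaths Optional breath-by-breath tibble; defaults to the trace
#'   attached to `cohort`, if any.
#' @param speed_tol Tolerance (km/h) on the protocol speed schedule.
#' @param peak_tol Tolerance (ml/kg/min) on `vo2peak_measured` versus the
#'   highest stage VO2; measurement noise makes small exceedances benign.
#' @param min_stages Minimum number of stages for a usable test.
#' @return A tibble of issues (`participant_id`, `code`, `message`); zero
#'   rows when the cohort is clean.
#' @export
validate_gxt <- function(cohort, breaths = attr(cohort, "breaths"),
                         speed_tol = 0.01, peak_tol = 5, min_stages = 3) {
  issue <- function(pid, code, msg) {
    tibble::tibble(participant_id = pid, code = code, message = msg)
  }
  issues <- list()

  by_part <- split(tibble::as_tibble(cohort), cohort$participant_id)
  for (pid in names(by_part)) {
    p <- by_part[[pid]]
    expected <- 7 + 0.5 * (p$stage_index - 1)
    bad <- which(abs(p$speed_kmh - expected) > speed_tol)
    if (length(bad) > 0) {
      issues <- c(issues, list(issue(
        pid, "PROTOCOL_SPEED_MISMATCH",
        sprintf(
          "stage %s speed %s km/h off the 7 + 0.5 (stage - 1) schedule",
          paste(p$stage_index[bad], collapse = ","),
          paste(p$speed_kmh[bad], collapse = ",")
        )
      )))
    }
    cert_bad <- !is.na(p$cert_rpe) & (p$cert_rpe < 1 | p$cert_rpe > 10)
    ep_bad <- !is.na(p$ep_rpe) & (p$ep_rpe < 0 | p$ep_rpe > 10)
    if (any(cert_bad) || any(ep_bad)) {
      issues <- c(issues, list(issue(
        pid, "RPE_OUT_OF_RANGE",
        sprintf(
          "RPE outside scale range at stage %s",
          paste(p$stage_index[cert_bad | ep_bad], collapse = ",")
        )
      )))
    }
    peak <- p$vo2peak_measured[1]
    top_stage <- suppressWarnings(max(p$stage_vo2, na.rm = TRUE))
    if (is.na(peak) || (is.finite(top_stage) && peak < top_stage - peak_tol)) {
      issues <- c(issues, list(issue(
        pid, "NO_PEAK",
        "missing VO2peak or VO2peak below the highest stage VO2"
      )))
    }
    if (nrow(p) < min_stages) {
      issues <- c(issues, list(issue(
        pid, "TOO_FEW_STAGES",
        sprintf("only %d stage(s); need >= %d", nrow(p), min_stages)
      )))
    }
  }

  if (!is.null(breaths)) {
    mono <- breaths |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(ok = !is.unsorted(.data$time_s, strictly = TRUE),
                       .groups = "drop")
    for (pid in mono$participant_id[!mono$ok]) {
      issues <- c(issues, list(issue(
        as.character(pid), "NON_MONOTONIC_TIME",
        "breath timestamps not strictly increasing"
      )))
    }
  }

  if (length(issues) == 0) {
    return(tibble::tibble(
      participant_id = character(), code = character(), message = character()
    ))
  }
  dplyr::bind_rows(issues)
}
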