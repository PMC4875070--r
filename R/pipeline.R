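# End-to-end orchestration: simulate or load a cohort, validate it, run the
# eight-condition prediction design, and emit the agreement report plus the
# paired-t / ANOVA summaries as files.

#' Submaximal VO2 recorded at a given rating
#'
#' The stage VO2 recorded when a child reported a given rating: per
#' participant, the mean stage VO2 over the stages whose report on the
#' scale equals `rpe` (`NA` when the child never reported it). Used for the
#' paired comparison of the VO2 at CERT 5 versus EP 5 (and 7 versus 7).
#'
#' @param cohort A `gxt_cohort` tibble.
#' @param scale `"CERT"` or `"EP"`.
#' @param rpe The rating at which the VO2 was recorded.
#' @return A tibble `participant_id`, `vo2`.
#' @export
submax_vo2_at <- function(cohort, scale, rpe) {
  scale <- match_scale(scale)
  rpe_col <- if (scale == "CERT") "cert_rpe" else "ep_rpe"
  gxt_participants(cohort) |>
    dplyr::select("participant_id") |>
    dplyr::left_join(
      tibble::as_tibble(cohort) |>
        dplyr::filter(.data[[rpe_col]] == !!rpe, !is.na(.data$stage_vo2)) |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(vo2 = mean(.data$stage_vo2), .groups = "drop"),
      by = "participant_id"
    )
}

anova_family <- function(cohort, predictions, ceiling) {
  cl <- ceiling
  meas <- gxt_participants(cohort)$vo2peak_measured
  conds <- tidyr::crossing(scale = c("CERT", "EP"), endpoint = c(10L, 9L))
  groups <- purrr::pmap(conds, function(scale, endpoint) {
    sc <- scale
    ep <- endpoint
    predictions |>
      dplyr::filter(
        .data$scale == sc, .data$ceiling == cl, .data$endpoint == ep,
        .data$status == "OK"
      ) |>
      dplyr::pull("vo2peak_predicted")
  })
  names(groups) <- sprintf("%s %d -> %d", conds$scale, cl, conds$endpoint)
  oneway_anova_vs_measured(meas, groups)
}

stats_summary_tbl <- function(cohort, predictions) {
  parts <- gxt_participants(cohort)
  rows <- list()
  add <- function(analysis, statistic, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      analysis = analysis, statistic = statistic, value = value
    )
  }

  tt <- paired_t(parts$terminal_cert, parts$terminal_ep)
  add("paired_t terminal CERT vs EP", c("t", "df", "p"),
      c(tt$t, tt$df, tt$p))

  for (cl in c(5, 7)) {
    a <- submax_vo2_at(cohort, "CERT", cl)$vo2
    b <- submax_vo2_at(cohort, "EP", cl)$vo2
    if (sum(!is.na(a) & !is.na(b)) >= 2) {
      tt <- paired_t(a, b)
      add(sprintf("paired_t submax VO2 at CERT %d vs EP %d", cl, cl),
          c("t", "df", "p"), c(tt$t, tt$df, tt$p))
    }
  }

  for (cl in c(5, 7)) {
    an <- tryCatch(
      anova_family(cohort, predictions, cl),
      peakrpe_insufficient_data = function(e) NULL
    )
    if (!is.null(an)) {
      lab <- sprintf("anova ceiling-%d family", cl)
      add(lab, c("f", "df_between", "df_within", "p"),
          c(an$f_stat, an$df_between, an$df_within, an$p_value))
      add(paste(lab, "posthoc p_adj"), an$posthoc$condition, an$posthoc$p_adj)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full prediction-and-agreement pipeline
#'
#' Simulates (or loads) a cohort, validates it, fits all per-participant
#' perceptual regressions, extrapolates to both endpoints, and writes the
#' run artifacts to `outdir`: the cohort CSV (when simulated, with the
#' latent-truth CSV alongside), `predictions.csv`, the agreement report
#' (`agreement_report.csv` and/or `.txt`), `stats_summary.csv` (paired t
#' tests and the two five-group ANOVA families with Bonferroni post hoc
#' contrasts), and `run.log`. Artifacts are written atomically and the run
#' is a pure function of the input (or config seed).
#'
#' @param outdir Output directory, created if needed.
#' @param input Path to a stage-level cohort CSV. Exactly one of `input`
#'   and `config` must be given.
#' @param config A [cohort_config()] to simulate instead of loading.
#' @param formats Report formats, subset of `c("csv", "text")`.
#' @param plot Also write the predicted-versus-measured panel
#'   (`agreement_plot.pdf`).
#' @param quiet Suppress progress messages (the log file is always
#'   written).
#' @return Invisibly, a list with `cohort`, `issues`, `predictions`,
#'   `report`, `stats`, and `paths`.
#' @export
run_pipeline <- function(outdir, input = NULL, config = NULL,
                         formats = c("csv", "text"), plot = FALSE,
                         quiet = TRUE) {
  if (is.null(input) == is.null(config)) {
    abort("exactly one of `input` and `config` must be supplied")
  }
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_ <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  paths <- list()

  if (!is.null(config)) {
    log_(sprintf(
      "simulating cohort: n = %d, seed = %d",
      config$n_participants, config$seed
    ))
    cohort <- simulate_cohort(config)
    paths$cohort <- file.path(outdir, "cohort.csv")
    write_gxt_cohort(cohort, paths$cohort)
    paths$truth <- file.path(outdir, "cohort_truth.csv")
    write_atomic(paths$truth, function(p) {
      readr::write_csv(cohort_truth(cohort), p, progress = FALSE)
    })
  } else {
    log_(sprintf("reading cohort: %s", input))
    cohort <- read_gxt_cohort(input)
  }

  issues <- validate_gxt(cohort)
  for (i in seq_len(nrow(issues))) {
    log_(sprintf(
      "validation: %s %s (%s)",
      issues$participant_id[i], issues$code[i], issues$message[i]
    ))
  }

  usable <- gxt_participants(cohort) |>
    dplyr::filter(!is.na(.data$vo2peak_measured))
  if (nrow(usable) == 0) {
    abort("no usable participants in cohort", class = "peakrpe_infeasible")
  }

  predictions <- predict_all(cohort)
  insuff <- predictions |>
    dplyr::filter(.data$status == "INSUFFICIENT_DATA", .data$endpoint == 10)
  for (i in seq_len(nrow(insuff))) {
    log_(sprintf(
      "insufficient perceptual data: %s %s ceiling %d (%d point(s), %d distinct)",
      insuff$participant_id[i], insuff$scale[i], insuff$ceiling[i],
      insuff$n_points[i], insuff$n_distinct_rpe[i]
    ))
  }
  if (all(predictions$status == "INSUFFICIENT_DATA")) {
    abort("no participant has sufficient perceptual data",
      class = "peakrpe_infeasible"
    )
  }
  paths$predictions <- file.path(outdir, "predictions.csv")
  write_atomic(paths$predictions, function(p) {
    readr::write_csv(predictions, p, progress = FALSE)
  })

  report <- build_table1(cohort, predictions)
  if ("csv" %in% formats) {
    paths$report_csv <- file.path(outdir, "agreement_report.csv")
    write_agreement_report(report, paths$report_csv, "csv")
  }
  if ("text" %in% formats) {
    paths$report_txt <- file.path(outdir, "agreement_report.txt")
    write_agreement_report(report, paths$report_txt, "text")
  }

  stats <- stats_summary_tbl(cohort, predictions)
  paths$stats <- file.path(outdir, "stats_summary.csv")
  write_atomic(paths$stats, function(p) {
    readr::write_csv(stats, p, progress = FALSE)
  })

  if (plot) {
    paths$plot <- file.path(outdir, "agreement_plot.pdf")
    ggplot2::ggsave(
      paths$plot, plot_agreement(cohort, predictions),
      width = 10, height = 6
    )
  }

  paths$log <- file.path(outdir, "run.log")
  write_atomic(paths$log, function(p) writeLines(log_lines, p))
  log_(sprintf("wrote %d artifact(s) to %s", length(paths), outdir))

  invisible(list(
    cohort = cohort, issues = issues, predictions = predictions,
    report = report, stats = stats, paths = paths
  ))
}
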