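# Synthetic paediatric GXT cohorts. The generator reproduces the study
# conditions the analysis assumes: the incremental treadmill protocol
# (7 km/h start, +0.5 km/h per minute), peak physiology calibrated to
# VO2peak 55.2 +/- 10.8 ml/kg/min, HRpeak 203 +/- 7 bpm, peak speed
# 10.9 +/- 1.2 km/h, and a perceptual response that is linear on the CERT
# scale and a power curve on the EP scale, anchored so that CERT 5 falls
# near 78% and EP 5 near 83% of VO2peak (hence onset 0.604 and exponent
# 3.7198, the solutions of the two anchor equations).

#' Configuration of a synthetic GXT cohort
#'
#' Defaults encode the study conditions: peak-physiology targets from a
#' healthy 8-10-year-old treadmill cohort, the 7 km/h + 0.5 km/h/min
#' protocol, perceptual anchors placing CERT 5 at ~78% and EP 5 at ~83% of
#' VO2peak, report noise of 1 RPE unit (which, after rounding and top-of-
#' scale censoring, yields terminal ratings of ~9.6 +/- 0.7), and stage-VO2
#' measurement noise of 1.5 ml/kg/min.
#'
#' @param n_participants Number of children.
#' @param seed Integer seed; the generator touches no global RNG state.
#' @param vo2peak_mean,vo2peak_sd Target VO2peak distribution (ml/kg/min),
#'   truncated to 30-85.
#' @param hrpeak_mean,hrpeak_sd Target peak heart rate (bpm), truncated to
#'   170-230.
#' @param peak_speed_mean,peak_speed_sd Target peak treadmill speed (km/h),
#'   truncated to 8-14 and snapped to the protocol's 0.5 km/h stage grid.
#' @param start_intensity_fraction VO2 at the 7 km/h start as a fraction of
#'   VO2peak.
#' @param cert_onset_fraction Relative intensity x0 at which the CERT
#'   response leaves its floor of 1; above x0 the response is linear in
#'   relative intensity, reaching 10 at VO2peak.
#' @param ep_exponent Exponent gamma of the EP power response
#'   `RPE = 10 x^gamma`.
#' @param onset_jitter_sd,exponent_jitter_sd Between-child SD of the onset
#'   (additive, truncated below the start intensity) and of the exponent
#'   (multiplicative, log scale).
#' @param rpe_noise_sd SD of the report noise, in RPE units, added before
#'   rounding.
#' @param vo2_noise_sd SD of the stage-VO2 measurement noise (ml/kg/min).
#' @param breath_noise_sd SD of the per-breath noise around the stage value
#'   (ml/kg/min), used when `emit_breath_level`.
#' @param round_rpe Round reports to integers (disable for exact-recovery
#'   checks).
#' @param emit_breath_level Also generate a 1 Hz breath-by-breath trace.
#' @param insufficient_data_rate Probability that a child's perception runs
#'   "hot" (early onset, shallow EP curve) so their first reports start
#'   above RPE 5 and the ceiling-5 regressions may have too few points --
#'   the source of the differing per-condition n in the report.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 50,
                          seed = 1,
                          vo2peak_mean = 55.2, vo2peak_sd = 10.8,
                          hrpeak_mean = 203, hrpeak_sd = 7,
                          peak_speed_mean = 10.9, peak_speed_sd = 1.2,
                          start_intensity_fraction = 0.62,
                          cert_onset_fraction = 0.604,
                          ep_exponent = 3.7198,
                          onset_jitter_sd = 0.03,
                          exponent_jitter_sd = 0.06,
                          rpe_noise_sd = 1.0,
                          vo2_noise_sd = 1.5,
                          breath_noise_sd = 1.0,
                          round_rpe = TRUE,
                          emit_breath_level = FALSE,
                          insufficient_data_rate = 0.15) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    vo2peak_mean = vo2peak_mean, vo2peak_sd = vo2peak_sd,
    hrpeak_mean = hrpeak_mean, hrpeak_sd = hrpeak_sd,
    peak_speed_mean = peak_speed_mean, peak_speed_sd = peak_speed_sd,
    start_intensity_fraction = start_intensity_fraction,
    cert_onset_fraction = cert_onset_fraction,
    ep_exponent = ep_exponent,
    onset_jitter_sd = onset_jitter_sd,
    exponent_jitter_sd = exponent_jitter_sd,
    rpe_noise_sd = rpe_noise_sd, vo2_noise_sd = vo2_noise_sd,
    breath_noise_sd = breath_noise_sd,
    round_rpe = isTRUE(round_rpe),
    emit_breath_level = isTRUE(emit_breath_level),
    insufficient_data_rate = insufficient_data_rate
  )
  sds <- c(
    cfg$vo2peak_sd, cfg$hrpeak_sd, cfg$peak_speed_sd, cfg$onset_jitter_sd,
    cfg$exponent_jitter_sd, cfg$rpe_noise_sd, cfg$vo2_noise_sd,
    cfg$breath_noise_sd
  )
  if (any(sds < 0)) {
    abort("all SDs must be non-negative")
  }
  if (cfg$start_intensity_fraction <= 0 || cfg$start_intensity_fraction >= 1) {
    abort("`start_intensity_fraction` must lie in (0, 1)")
  }
  if (cfg$cert_onset_fraction <= 0 || cfg$cert_onset_fraction >= 1) {
    abort("`cert_onset_fraction` must lie in (0, 1)")
  }
  if (cfg$ep_exponent <= 0) {
    abort("`ep_exponent` must be positive")
  }
  if (cfg$insufficient_data_rate < 0 || cfg$insufficient_data_rate > 1) {
    abort("`insufficient_data_rate` must lie in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n = %d, seed = %d\n  VO2peak %.1f +/- %.1f, HRpeak %.0f +/- %.0f, peak speed %.1f +/- %.1f\n  onset %.3f, exponent %.3f, noise: rpe %.2f, vo2 %.2f\n",
    x$n_participants, x$seed, x$vo2peak_mean, x$vo2peak_sd, x$hrpeak_mean,
    x$hrpeak_sd, x$peak_speed_mean, x$peak_speed_sd, x$cert_onset_fraction,
    x$ep_exponent, x$rpe_noise_sd, x$vo2_noise_sd
  ))
  invisible(x)
}

#' Latent perceptual response at a relative intensity
#'
#' The generator's noise-free rating at relative intensity `x`
#' (VO2 / VO2peak). CERT: a floor of 1 up to the onset `x0`, then linear,
#' reaching 10 at `x = 1`. EP: the power curve `10 x^gamma`, reaching 10 at
#' `x = 1`. With the default constants the curves pass near the group
#' anchors of ~78% VO2peak at CERT 5, ~83% at EP 5, ~87% at CERT 7 and
#' ~91% at EP 7.
#'
#' @param x Relative intensity in (0, 1] (vectorised).
#' @param scale `"CERT"` or `"EP"`.
#' @param onset CERT onset fraction x0.
#' @param exponent EP exponent gamma.
#' @return Continuous (unrounded) rating.
#' @export
true_rpe <- function(x, scale, onset = 0.604, exponent = 3.7198) {
  scale <- match_scale(scale)
  if (any(x <= 0 | x > 1)) {
    abort("relative intensity `x` must lie in (0, 1]")
  }
  if (scale == "CERT") {
    1 + 9 * pmax(0, (x - onset) / (1 - onset))
  } else {
    10 * x^exponent
  }
}

#' Simulate a synthetic GXT cohort
#'
#' Draws each child's latent VO2peak, peak heart rate and peak speed from
#' truncated normals; VO2 rises linearly with speed from
#' `start_intensity_fraction * VO2peak` at 7 km/h to VO2peak at the final
#' stage, exhaustion being snapped to the protocol's 0.5 km/h stage grid so
#' relative intensity reaches exactly 1 on the final 60-s stage. Stage VO2
#' is the latent value plus measurement noise; ratings are [true_rpe()]
#' plus report noise, rounded to integers (unless disabled) and clipped to
#' each scale's range (CERT 1-10, EP 0-10). The measured VO2peak criterion
#' is the terminal stage's (noisy) VO2; terminal ratings are the final
#' stage's reports. With all noise at zero and rounding disabled the
#' perceptual responses are exact inverses of the two prediction models, so
#' endpoint-10 extrapolation recovers the latent VO2peak exactly.
#'
#' @param config A [cohort_config()].
#' @return A `gxt_cohort` tibble. The latent per-child parameters are
#'   attached as the `"truth"` attribute (see [cohort_truth()]); with
#'   `emit_breath_level = TRUE` a 1 Hz trace is attached as `"breaths"`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  if (n < 1) {
    abort("`n_participants` must be at least 1")
  }
  # seed locally, restoring the caller's RNG state on exit
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    },
    add = TRUE
  )
  set.seed(config$seed)

  vo2peak_true <- rnorm_trunc(n, config$vo2peak_mean, config$vo2peak_sd, 30, 85)
  hr_peak <- rnorm_trunc(n, config$hrpeak_mean, config$hrpeak_sd, 170, 230)
  speed_raw <- rnorm_trunc(
    n, config$peak_speed_mean, config$peak_speed_sd, 8, 14
  )
  # Snap exhaustion to the 0.5 km/h stage grid (nearest grid point keeps the
  # cohort mean unbiased); at least 3 stages.
  n_stages <- pmax(3L, as.integer(round((speed_raw - 7) / 0.5)) + 1L)
  peak_speed <- 7 + 0.5 * (n_stages - 1)

  f0 <- config$start_intensity_fraction
  onset <- rnorm_trunc(
    n, config$cert_onset_fraction, config$onset_jitter_sd,
    0.45, f0 - 0.005
  )
  exponent <- config$ep_exponent *
    exp(stats::rnorm(n, 0, config$exponent_jitter_sd))
  exponent <- pmin(pmax(exponent, 2.5), 5.5)

  # "Hot" reporters perceive the start as already hard: an early CERT onset
  # pushes their first CERT reports above 5, while a still-curvilinear EP
  # response keeps their first EP reports near 5, so insufficiency hits the
  # CERT ceiling-5 window far more often than the EP one.
  hot <- stats::runif(n) < config$insufficient_data_rate
  onset[hot] <- 0.05
  exponent[hot] <- 1.5

  ids <- sprintf("P%03d", seq_len(n))
  truth <- tibble::tibble(
    participant_id = ids,
    vo2peak_true = vo2peak_true,
    peak_speed_true = peak_speed,
    vo2_at_start = f0 * vo2peak_true,
    x0 = onset,
    gamma = exponent,
    hot_reporter = hot
  )

  clip_round <- function(r, lo, hi) {
    if (config$round_rpe) r <- round(r)
    pmin(pmax(r, lo), hi)
  }

  stages <- purrr::map(seq_len(n), function(i) {
    k <- n_stages[i]
    x <- f0 + (1 - f0) * (seq_len(k) - 1) / (k - 1)
    vo2_latent <- x * vo2peak_true[i]
    svo2 <- vo2_latent + stats::rnorm(k, 0, config$vo2_noise_sd)
    cert <- clip_round(
      true_rpe(x, "CERT", onset = onset[i]) +
        stats::rnorm(k, 0, config$rpe_noise_sd),
      1, 10
    )
    ep <- clip_round(
      true_rpe(x, "EP", exponent = exponent[i]) +
        stats::rnorm(k, 0, config$rpe_noise_sd),
      0, 10
    )
    tibble::tibble(
      participant_id = ids[i],
      stage_index = seq_len(k),
      speed_kmh = 7 + 0.5 * (seq_len(k) - 1),
      start_s = 60 * (seq_len(k) - 1),
      end_s = 60 * seq_len(k),
      rel_intensity = x,
      stage_vo2 = svo2,
      cert_rpe = cert,
      ep_rpe = ep,
      vo2peak_measured = svo2[k],
      hr_peak = hr_peak[i],
      peak_speed_kmh = peak_speed[i],
      terminal_cert = cert[k],
      terminal_ep = ep[k]
    )
  }) |> dplyr::bind_rows()

  cohort <- as_gxt_cohort(stages)
  attr(cohort, "truth") <- truth
  attr(cohort, "config") <- config

  if (config$emit_breath_level) {
    breaths <- stages |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_modify(function(df, key) {
        purrr::pmap_dfr(
          list(df$start_s, df$end_s, df$stage_vo2, df$rel_intensity),
          function(start_s, end_s, svo2, x) {
            t <- seq(start_s + 1, end_s)
            hrp <- df$hr_peak[1]
            tibble::tibble(
              time_s = t,
              vo2 = svo2 + stats::rnorm(length(t), 0, config$breath_noise_sd),
              hr = round(90 + (hrp - 90) * x),
              ve = round(8 + 65 * x^1.2, 1),
              rer = round(0.80 + 0.24 * x, 2)
            )
          }
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::relocate("participant_id")
    attr(cohort, "breaths") <- breaths
  }

  cohort
}

#' Latent truth of a simulated cohort
#'
#' @param cohort A cohort produced by [simulate_cohort()].
#' @return The tibble of latent per-child parameters (`participant_id`,
#'   `vo2peak_true`, `peak_speed_true`, `vo2_at_start`, `x0`, `gamma`,
#'   `hot_reporter`), for recovery tests.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) {
    abort("cohort carries no latent truth; was it produced by simulate_cohort()?")
  }
  truth
}
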