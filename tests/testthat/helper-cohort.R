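# Fixture builders: everything is generated in code, no data files.

# A tiny handcrafted stage-level cohort: two children, clean protocol.
make_toy_cohort <- function() {
  mk <- function(id, vo2s, certs, eps, peak) {
    k <- length(vo2s)
    tibble::tibble(
      participant_id = id,
      stage_index = seq_len(k),
      speed_kmh = 7 + 0.5 * (seq_len(k) - 1),
      stage_vo2 = vo2s,
      cert_rpe = certs,
      ep_rpe = eps,
      vo2peak_measured = peak,
      hr_peak = 200,
      peak_speed_kmh = 7 + 0.5 * (k - 1),
      terminal_cert = certs[k],
      terminal_ep = eps[k]
    )
  }
  as_gxt_cohort(dplyr::bind_rows(
    mk("A", c(30, 35, 40, 45, 50, 55), c(2, 3, 4, 5, 6, 8), c(1, 2, 3, 5, 7, 9), 56),
    mk("B", c(32, 36, 40, 44), c(1, 3, 5, 7), c(0, 1, 3, 5), 45)
  ))
}

# A 1 Hz breath trace with constant VO2 within each stage.
make_constant_breaths <- function(ids = c("A", "B"), n_stages = 3, vo2 = 40) {
  purrr::map_dfr(ids, function(id) {
    tibble::tibble(
      participant_id = id,
      time_s = seq_len(60 * n_stages),
      vo2 = vo2,
      hr = 150,
      ve = 40,
      rer = 0.95
    )
  })
}

make_schedule <- function(ids = c("A", "B"), n_stages = 3) {
  purrr::map_dfr(ids, function(id) {
    tibble::tibble(
      participant_id = id,
      stage_index = seq_len(n_stages),
      speed_kmh = 7 + 0.5 * (seq_len(n_stages) - 1),
      start_s = 60 * (seq_len(n_stages) - 1),
      end_s = 60 * seq_len(n_stages),
      cert_rpe = c(2, 4, 6)[seq_len(n_stages)],
      ep_rpe = c(1, 3, 6)[seq_len(n_stages)]
    )
  })
}

# Independent OLS oracle: closed-form normal equations, no lm().
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

canonical_cols <- function(cohort) {
  as.data.frame(cohort)[, c(
    "participant_id", "stage_index", "speed_kmh", "stage_vo2",
    "cert_rpe", "ep_rpe", "vo2peak_measured", "hr_peak", "peak_speed_kmh",
    "terminal_cert", "terminal_ep"
  )]
}
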