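test_that("submaximal point selection filters by value and excludes EP 0", {
  co <- make_toy_cohort()

  # participant A reports CERT 2,3,4,5,6,8: ceiling 5 keeps four stages
  pts <- submaximal_points(co, "CERT", 5)
  a <- dplyr::filter(pts, participant_id == "A")
  expect_equal(a$rpe, c(2, 3, 4, 5))
  expect_equal(a$vo2, c(30, 35, 40, 45))

  # participant B reports EP 0,1,3,5: the 0 is excluded (log domain)
  ep <- submaximal_points(co, "EP", 5)
  b <- dplyr::filter(ep, participant_id == "B")
  expect_equal(b$rpe, c(1, 3, 5))

  # ceiling-7 point set always contains the ceiling-5 set (simulated cohort)
  sim <- simulate_cohort(cohort_config(n_participants = 30, seed = 11))
  for (sc in c("CERT", "EP")) {
    p5 <- submaximal_points(sim, sc, 5)
    p7 <- submaximal_points(sim, sc, 7)
    key5 <- paste(p5$participant_id, p5$stage_index)
    key7 <- paste(p7$participant_id, p7$stage_index)
    expect_true(all(key5 %in% key7))
  }
})

test_that("linear fits recover exact relations and match the normal equations", {
  pts <- tibble::tibble(rpe = 2:5, vo2 = c(20, 30, 40, 50))
  m <- fit_linear_model(pts)
  expect_equal(m$slope_or_b, 10, tolerance = 1e-12)
  expect_equal(m$intercept_or_const, 0, tolerance = 1e-10)
  expect_equal(m$n_points, 4)
  expect_equal(m$n_distinct_rpe, 4)

  flat <- fit_linear_model(tibble::tibble(rpe = c(3, 5), vo2 = c(40, 40)))
  expect_equal(flat$slope_or_b, 0)
  expect_equal(flat$intercept_or_const, 40)

  withr::with_seed(101, {
    for (i in 1:5) {
      pts <- tibble::tibble(
        rpe = sample(1:7, 5, replace = TRUE) + runif(5, -0.2, 0.2),
        vo2 = runif(5, 20, 60)
      )
      m <- fit_linear_model(pts)
      cf <- ols_oracle(pts$rpe, pts$vo2)
      expect_equal(m$intercept_or_const, cf[1], tolerance = 1e-10)
      expect_equal(m$slope_or_b, cf[2], tolerance = 1e-10)
    }
  })

  expect_error(
    fit_linear_model(tibble::tibble(rpe = c(4, 4), vo2 = c(30, 40))),
    class = "peakrpe_insufficient_data"
  )
})

test_that("power fits recover exact power laws and match the log-domain normal equations", {
  pts <- tibble::tibble(rpe = c(1, 4, 9), vo2 = 5 * c(1, 4, 9)^0.5)
  m <- fit_power_model(pts)
  expect_equal(m$slope_or_b, 0.5, tolerance = 1e-12)
  expect_equal(m$intercept_or_const, 5, tolerance = 1e-12)

  const <- fit_power_model(tibble::tibble(rpe = c(2, 5), vo2 = c(30, 30)))
  expect_equal(const$slope_or_b, 0, tolerance = 1e-12)
  expect_equal(const$intercept_or_const, 30, tolerance = 1e-12)

  withr::with_seed(202, {
    for (i in 1:5) {
      pts <- tibble::tibble(
        rpe = runif(5, 1, 7), vo2 = runif(5, 20, 60)
      )
      m <- fit_power_model(pts)
      cf <- ols_oracle(log(pts$rpe), log(pts$vo2))
      expect_equal(m$intercept_or_const, exp(cf[1]), tolerance = 1e-10)
      expect_equal(m$slope_or_b, cf[2], tolerance = 1e-10)
    }
  })

  expect_error(
    fit_power_model(tibble::tibble(rpe = c(0, 3), vo2 = c(10, 30))),
    "RPE > 0"
  )
})

test_that("extrapolation evaluates the fitted form at the endpoint", {
  lin <- fit_linear_model(tibble::tibble(rpe = 1:4, vo2 = 10 * (1:4)))
  expect_equal(predict_vo2peak(lin, 10), 100, tolerance = 1e-10)

  pow <- fit_power_model(tibble::tibble(rpe = c(1, 4, 9), vo2 = 5 * c(1, 2, 3)))
  expect_equal(predict_vo2peak(pow, 9), 15, tolerance = 1e-10)

  # monotone extrapolation: positive slope/exponent means endpoint 10 > 9
  expect_gt(predict_vo2peak(lin, 10), predict_vo2peak(lin, 9))
  expect_gt(predict_vo2peak(pow, 10), predict_vo2peak(pow, 9))
})

test_that("power predictions are invariant to the logarithm base", {
  withr::with_seed(303, {
    pts <- tibble::tibble(rpe = runif(6, 1, 7), vo2 = runif(6, 25, 55))
  })
  m <- fit_power_model(pts)
  # base-10 refit by hand
  cf10 <- ols_oracle(log10(pts$rpe), log10(pts$vo2))
  pred10 <- function(endpoint) 10^(cf10[1] + cf10[2] * log10(endpoint))
  expect_equal(predict_vo2peak(m, 9), unname(pred10(9)), tolerance = 1e-10)
  expect_equal(predict_vo2peak(m, 10), unname(pred10(10)), tolerance = 1e-10)
})

test_that("rescaling VO2 rescales predictions proportionally", {
  withr::with_seed(404, {
    pts <- tibble::tibble(rpe = c(1, 2, 3, 5), vo2 = runif(4, 20, 50))
  })
  for (fitter in list(fit_linear_model, fit_power_model)) {
    m1 <- fitter(pts)
    m2 <- fitter(dplyr::mutate(pts, vo2 = 3 * vo2))
    expect_equal(
      3 * predict_vo2peak(m1, c(9, 10)),
      predict_vo2peak(m2, c(9, 10)),
      tolerance = 1e-10
    )
  }
})

test_that("tidy and glance summarise fitted perceptual models", {
  m <- fit_linear_model(
    tibble::tibble(rpe = c(2, 3, 4, 5), vo2 = c(31, 34, 42, 44)),
    scale = "CERT", ceiling = 5
  )
  td <- tidy(m)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], m$slope_or_b)
  gl <- glance(m)
  expect_equal(gl$n_points, 4)
  expect_true(gl$r.squared > 0 && gl$r.squared <= 1)
})

test_that("predict_all emits eight records per participant with correct statuses", {
  co <- make_toy_cohort()
  preds <- predict_all(co)
  expect_equal(nrow(preds), 2 * 8)
  expect_equal(sum(preds$endpoint == 10), 8)

  # a child whose lowest CERT report is 6: ceiling 5 insufficient, 7 OK
  high <- tibble::tibble(
    participant_id = "C",
    stage_index = 1:4,
    speed_kmh = 7 + 0.5 * (0:3),
    stage_vo2 = c(40, 45, 50, 55),
    cert_rpe = c(6, 7, 8, 10),
    ep_rpe = c(5, 6, 8, 10),
    vo2peak_measured = 56, hr_peak = 200, peak_speed_kmh = 8.5,
    terminal_cert = 10, terminal_ep = 10
  )
  p <- predict_all(as_gxt_cohort(high))
  cert5 <- dplyr::filter(p, scale == "CERT", ceiling == 5)
  cert7 <- dplyr::filter(p, scale == "CERT", ceiling == 7)
  expect_true(all(cert5$status == "INSUFFICIENT_DATA"))
  expect_true(all(is.na(cert5$vo2peak_predicted)))
  expect_true(all(cert7$status == "OK"))

  # noise-free generator inversion: endpoint-10 predictions hit the truth
  sim <- simulate_cohort(cohort_config(
    n_participants = 8, seed = 5, rpe_noise_sd = 0, vo2_noise_sd = 0,
    round_rpe = FALSE, insufficient_data_rate = 0
  ))
  truth <- cohort_truth(sim)
  p10 <- predict_all(sim) |>
    dplyr::filter(endpoint == 10, status == "OK") |>
    dplyr::left_join(truth, by = "participant_id")
  expect_gt(nrow(p10), 0)
  expect_lt(max(abs(p10$vo2peak_predicted - p10$vo2peak_true)), 1e-6)
})
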