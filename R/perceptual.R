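# Per-participant perceptual regressions: point selection below a submaximal
# RPE ceiling, the linear CERT model, the log-log power EP model, and
# extrapolation of the fitted response to an RPE endpoint.

#' Submaximal perceptual points below an RPE ceiling
#'
#' Selects, for every participant, the stages whose reported rating on the
#' given scale is at or below the ceiling ("up to and including" is a value
#' filter: a stage with a low rating after a higher one still contributes).
#' For the EP scale, ratings below 1 are additionally excluded because the
#' power model is fitted on logarithms. Stages without a rating on the
#' scale, or without a stage VO2, contribute nothing.
#'
#' @param cohort A `gxt_cohort` tibble with populated `stage_vo2`.
#' @param scale `"CERT"` or `"EP"` (case-insensitive).
#' @param ceiling Highest submaximal rating admitted to the regression
#'   (the study design uses 5 and 7).
#' @return A tibble `participant_id`, `stage_index`, `rpe`, `vo2`, ordered
#'   by participant and stage. An empty result is legal.
#' @export
submaximal_points <- function(cohort, scale, ceiling) {
  scale <- match_scale(scale)
  stopifnot(is.numeric(ceiling), length(ceiling) == 1, ceiling > 0)
  rpe_col <- if (scale == "CERT") "cert_rpe" else "ep_rpe"
  pts <- tibble::as_tibble(cohort) |>
    dplyr::filter(
      !is.na(.data[[rpe_col]]),
      !is.na(.data$stage_vo2),
      .data[[rpe_col]] <= !!ceiling
    )
  if (scale == "EP") {
    pts <- dplyr::filter(pts, .data[[rpe_col]] >= 1)
  }
  pts |>
    dplyr::transmute(
      .data$participant_id,
      .data$stage_index,
      rpe = .data[[rpe_col]],
      vo2 = .data$stage_vo2
    ) |>
    dplyr::arrange(.data$participant_id, .data$stage_index)
}

new_perceptual_model <- function(scale, form, ceiling, slope_or_b,
                                 intercept_or_const, n_points,
                                 n_distinct_rpe, coef_table, r_squared,
                                 sigma, points) {
  structure(
    list(
      scale = scale, form = form, ceiling = ceiling,
      slope_or_b = slope_or_b, intercept_or_const = intercept_or_const,
      n_points = n_points, n_distinct_rpe = n_distinct_rpe,
      coef_table = coef_table, r_squared = r_squared, sigma = sigma,
      points = points
    ),
    class = "perceptual_model"
  )
}

check_fit_points <- function(points) {
  if (!all(c("rpe", "vo2") %in% names(points))) {
    abort("`points` needs `rpe` and `vo2` columns (see submaximal_points())")
  }
  nd <- dplyr::n_distinct(points$rpe)
  if (nrow(points) < 2 || nd < 2) {
    stop_insufficient(sprintf(
      "need >= 2 points with >= 2 distinct RPE values (have %d point(s), %d distinct)",
      nrow(points), nd
    ))
  }
  nd
}

#' Fit the linear (CERT) perceptual model
#'
#' Ordinary least-squares regression of stage VO2 (response, ml/kg/min) on
#' the reported rating (predictor), the conventional model for the linear
#' CERT scale: VO2 = intercept + slope * RPE.
#'
#' @param points A tibble of one participant's submaximal points
#'   (`rpe`, `vo2`), e.g. one group from [submaximal_points()].
#' @param scale,ceiling Metadata recorded on the fitted object.
#' @return A `perceptual_model` object (`form = "linear"`) with elements
#'   `slope_or_b` (slope, ml/kg/min per RPE unit) and `intercept_or_const`
#'   (intercept, ml/kg/min).
#' @export
fit_linear_model <- function(points, scale = "CERT", ceiling = NA_integer_) {
  nd <- check_fit_points(points)
  fit <- stats::lm(vo2 ~ rpe, data = points)
  sm <- suppressWarnings(summary(fit)) # exact fits trip summary.lm's warning
  cf <- coef(fit)
  new_perceptual_model(
    scale = match_scale(scale), form = "linear", ceiling = ceiling,
    slope_or_b = unname(cf["rpe"]), intercept_or_const = unname(cf["(Intercept)"]),
    n_points = nrow(points), n_distinct_rpe = nd,
    coef_table = sm$coefficients, r_squared = sm$r.squared, sigma = sm$sigma,
    points = tibble::as_tibble(points)
  )
}

#' Fit the power (Eston-Parfitt) perceptual model
#'
#' The curvilinear EP response is fitted by linear regression in the log-log
#' domain: log(VO2) on log(RPE), natural logarithms. Back-transforming gives
#' VO2 = a * RPE^b with exponent `b` (the log-domain slope) and constant
#' `a = exp(intercept)` (ml/kg/min). Predictions are provably invariant to
#' the logarithm base.
#'
#' @inheritParams fit_linear_model
#' @return A `perceptual_model` object (`form = "power"`) with elements
#'   `slope_or_b` (exponent b) and `intercept_or_const` (constant a).
#' @export
fit_power_model <- function(points, scale = "EP", ceiling = NA_integer_) {
  if (any(points$rpe <= 0)) {
    abort("power model requires all RPE > 0; filter EP ratings below 1 first")
  }
  nd <- check_fit_points(points)
  fit <- stats::lm(log(vo2) ~ log(rpe), data = points)
  sm <- suppressWarnings(summary(fit))
  cf <- coef(fit)
  new_perceptual_model(
    scale = match_scale(scale), form = "power", ceiling = ceiling,
    slope_or_b = unname(cf["log(rpe)"]),
    intercept_or_const = exp(unname(cf["(Intercept)"])),
    n_points = nrow(points), n_distinct_rpe = nd,
    coef_table = sm$coefficients, r_squared = sm$r.squared, sigma = sm$sigma,
    points = tibble::as_tibble(points)
  )
}

#' Predict VO2peak by extrapolating a fitted perceptual model
#'
#' Evaluates the fitted submaximal RPE-VO2 relation at an extrapolation
#' endpoint: the scale's theoretical maximum (RPE 10) or the terminal rating
#' children typically report at exhaustion (RPE 9).
#'
#' @param model A `perceptual_model`.
#' @param endpoint Extrapolation endpoint on the RPE scale (vectorised;
#'   the study design uses 9 and 10).
#' @return Predicted VO2peak (ml/kg/min), one value per endpoint.
#' @export
predict_vo2peak <- function(model, endpoint) {
  stopifnot(inherits(model, "perceptual_model"))
  if (model$form == "linear") {
    model$intercept_or_const + model$slope_or_b * endpoint
  } else {
    model$intercept_or_const * endpoint^model$slope_or_b
  }
}

#' @export
predict.perceptual_model <- function(object, endpoint = 10, ...) {
  predict_vo2peak(object, endpoint)
}

#' @export
print.perceptual_model <- function(x, ...) {
  lab <- if (x$form == "linear") {
    sprintf("VO2 = %.3f + %.3f * RPE", x$intercept_or_const, x$slope_or_b)
  } else {
    sprintf("VO2 = %.3f * RPE^%.3f", x$intercept_or_const, x$slope_or_b)
  }
  cat(sprintf(
    "<perceptual_model> %s (%s)%s\n  %s\n  %d points, %d distinct RPE, R^2 = %.3f\n",
    x$scale, x$form,
    if (is.na(x$ceiling)) "" else sprintf(", ceiling %s", x$ceiling),
    lab, x$n_points, x$n_distinct_rpe, x$r_squared
  ))
  invisible(x)
}

#' @describeIn fit_linear_model Coefficient table in broom convention
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`); terms are
#'   named `intercept`/`slope` for the linear form and
#'   `log_constant`/`exponent` for the power form.
#' @param x A `perceptual_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.perceptual_model <- function(x, ...) {
  ct <- x$coef_table
  terms <- if (x$form == "linear") {
    c("intercept", "slope")
  } else {
    c("log_constant", "exponent")
  }
  tibble::tibble(
    term = terms,
    estimate = unname(ct[, "Estimate"]),
    std.error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "t value"]),
    p.value = unname(ct[, "Pr(>|t|)"])
  )
}

#' @describeIn fit_linear_model One-row model summary.
#' @exportS3Method generics::glance
glance.perceptual_model <- function(x, ...) {
  tibble::tibble(
    scale = x$scale, form = x$form, ceiling = x$ceiling,
    slope_or_b = x$slope_or_b, intercept_or_const = x$intercept_or_const,
    r.squared = x$r_squared, sigma = x$sigma,
    n_points = x$n_points, n_distinct_rpe = x$n_distinct_rpe
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.perceptual_model <- function(object, endpoints = c(9, 10), ...) {
  grid <- tibble::tibble(
    rpe = seq(min(object$points$rpe), max(endpoints), length.out = 200)
  )
  grid$vo2 <- if (object$form == "linear") {
    object$intercept_or_const + object$slope_or_b * grid$rpe
  } else {
    object$intercept_or_const * grid$rpe^object$slope_or_b
  }
  preds <- tibble::tibble(
    rpe = endpoints, vo2 = predict_vo2peak(object, endpoints)
  )
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$rpe, y = .data$vo2)) +
    ggplot2::geom_line(data = grid, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = preds, shape = 4, size = 3, colour = "red") +
    ggplot2::labs(
      x = sprintf("%s rating", object$scale),
      y = expression(dot(V) * O[2] ~ (ml %.% kg^-1 %.% min^-1)),
      title = sprintf("%s %s fit", object$scale, object$form)
    ) +
    ggplot2::theme_minimal()
}

#' Extrapolated VO2peak predictions for a whole cohort
#'
#' Runs the full per-participant prediction design: for each participant,
#' each scale (CERT linear, EP power), each submaximal ceiling (5, 7) and
#' each extrapolation endpoint (10, 9) -- eight records per participant.
#' A scale-ceiling combination with fewer than two distinct submaximal
#' ratings cannot be regressed and yields `status = "INSUFFICIENT_DATA"`
#' records with no prediction; the per-condition count of `"OK"` records is
#' the n reported by [build_table1()].
#'
#' @param cohort A `gxt_cohort` tibble with populated `stage_vo2`.
#' @return A tibble with 8 rows per participant: `participant_id`, `scale`,
#'   `ceiling`, `endpoint`, `vo2peak_predicted`, `status`, `slope_or_b`,
#'   `intercept_or_const`, `n_points`, `n_distinct_rpe`.
#' @export
predict_all <- function(cohort) {
  combos <- tidyr::crossing(scale = c("CERT", "EP"), ceiling = c(5L, 7L))
  ids <- unique(cohort$participant_id)

  res <- purrr::map2(
    rep(combos$scale, each = 1), combos$ceiling,
    function(sc, cl) {
      pts_all <- submaximal_points(cohort, sc, cl)
      pts_split <- split(pts_all, factor(pts_all$participant_id, levels = ids))
      purrr::map(ids, function(pid) {
        pts <- pts_split[[pid]]
        n_pts <- if (is.null(pts)) 0L else nrow(pts)
        nd <- if (is.null(pts)) 0L else dplyr::n_distinct(pts$rpe)
        base <- tibble::tibble(
          participant_id = pid, scale = sc, ceiling = cl,
          endpoint = c(10L, 9L)
        )
        if (nd < 2) {
          return(dplyr::mutate(
            base,
            vo2peak_predicted = NA_real_, status = "INSUFFICIENT_DATA",
            slope_or_b = NA_real_, intercept_or_const = NA_real_,
            n_points = n_pts, n_distinct_rpe = nd
          ))
        }
        model <- if (sc == "CERT") {
          fit_linear_model(pts, scale = sc, ceiling = cl)
        } else {
          fit_power_model(pts, scale = sc, ceiling = cl)
        }
        dplyr::mutate(
          base,
          vo2peak_predicted = predict_vo2peak(model, .data$endpoint),
          status = "OK",
          slope_or_b = model$slope_or_b,
          intercept_or_const = model$intercept_or_const,
          n_points = n_pts, n_distinct_rpe = nd
        )
      }) |> dplyr::bind_rows()
    }
  ) |> dplyr::bind_rows()

  res |>
    dplyr::arrange(
      .data$participant_id, .data$scale, .data$ceiling,
      dplyr::desc(.data$endpoint)
    )
}
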