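# Measured-versus-predicted agreement battery: summary statistics, paired t
# tests, one-way ANOVA with Bonferroni post hoc contrasts, Pearson
# correlation with agreement categories, the standard error of estimate in
# absolute / standardized / relative form, and the eight-condition report.

#' Summary statistics with a 95% confidence interval
#'
#' Sample mean, sample SD (n - 1 denominator) and the 95% CI of the mean via
#' the Student t distribution with n - 1 degrees of freedom.
#'
#' @param values Numeric vector (ml/kg/min in this package's use); `NA`s are
#'   dropped.
#' @return A one-row tibble: `n`, `mean`, `sd`, `ci95_low`, `ci95_high`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    stop_insufficient("need at least 2 values to summarise")
  }
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  tibble::tibble(
    n = n, mean = m, sd = s, ci95_low = m - half, ci95_high = m + half
  )
}

#' Paired t test on matched values
#'
#' Standard paired t statistic on the differences `a - b` with
#' `df = n - 1` and a two-sided p value. Degenerate cases follow the
#' conventions of a no-difference null: identical vectors give `t = 0`,
#' `p = 1`; zero-variance differences with a nonzero mean give a signed
#' infinite `t` with `p = 0`.
#'
#' @param a,b Equal-length numeric vectors; pairs with an `NA` on either
#'   side are dropped.
#' @return A one-row tibble: `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have equal length")
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  if (n < 2) {
    stop_insufficient("need at least 2 complete pairs")
  }
  d <- a - b
  if (all(d == 0)) {
    return(tibble::tibble(t = 0, df = n - 1, p = 1))
  }
  if (stats::sd(d) == 0) {
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = unname(tt$p.value)
  )
}

#' Pearson correlation with the agreement category
#'
#' Pearson product-moment correlation between measured and predicted values,
#' labelled by the conventional criterion-validity bands: `r > 0.75`
#' excellent, `0.4 <= r <= 0.75` fair-to-good (the sliver above 0.74 is
#' folded into fair-to-good), otherwise poor.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, both with nonzero variance.
#' @return A one-row tibble: `r`, `category`.
#' @export
pearson_with_category <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    stop_insufficient("need at least 3 complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance", class = "peakrpe_degenerate")
  }
  r <- stats::cor(x, y)
  category <- if (r > 0.75) {
    "excellent"
  } else if (r >= 0.4) {
    "fair-to-good"
  } else {
    "poor"
  }
  tibble::tibble(r = r, category = category)
}

#' Standard error of estimate (absolute)
#'
#' Residual scatter of the criterion regressed on the prediction, the usual
#' random-error summary in validity studies: fit OLS of `measured`
#' (response) on `predicted` (predictor) and return
#' `sqrt(SS_residual / (n - 2))`. A perfect linear relation -- even a biased
#' one -- gives SEE 0: the SEE measures scatter, not bias.
#'
#' @param measured,predicted Paired numeric vectors (ml/kg/min), `n >= 3`.
#' @return The SEE in ml/kg/min.
#' @export
see_absolute <- function(measured, predicted) {
  keep <- !is.na(measured) & !is.na(predicted)
  measured <- measured[keep]
  predicted <- predicted[keep]
  n <- length(measured)
  if (n < 3) {
    stop_insufficient("need at least 3 complete pairs")
  }
  if (stats::sd(predicted) == 0) {
    abort("degenerate regression: zero variance in `predicted`",
      class = "peakrpe_degenerate"
    )
  }
  fit <- stats::lm(measured ~ predicted)
  sqrt(sum(stats::resid(fit)^2) / (n - 2))
}

likelihood_label <- function(value) {
  dplyr::case_when(
    value < 0.2 ~ "trivial",
    value < 0.6 ~ "small",
    value < 1.2 ~ "moderate",
    value < 2.0 ~ "large",
    TRUE ~ "very large"
  )
}

#' Standardized SEE with its likelihood label
#'
#' Divides the SEE by the standard deviation of the measured criterion and
#' labels the result with the conventional magnitude bands (half-open):
#' below 0.2 trivial, 0.2-0.6 small, 0.6-1.2 moderate, 1.2-2.0 large, 2.0
#' and above very large.
#'
#' @param see SEE in ml/kg/min (vectorised).
#' @param sd_measured SD of the measured criterion (ml/kg/min), `> 0`.
#' @return A tibble: `value` (dimensionless), `likelihood`.
#' @export
see_standardized <- function(see, sd_measured) {
  if (any(sd_measured <= 0)) {
    abort("`sd_measured` must be positive")
  }
  if (any(see < 0)) {
    abort("`see` must be non-negative")
  }
  value <- see / sd_measured
  tibble::tibble(value = value, likelihood = likelihood_label(value))
}

#' Relative standard error
#'
#' The SEE expressed as a percentage of the mean of the measured criterion.
#'
#' @param see SEE in ml/kg/min (vectorised).
#' @param mean_measured Mean of the measured criterion (ml/kg/min), `> 0`.
#' @return RSE in percent.
#' @export
relative_standard_error <- function(see, mean_measured) {
  if (any(mean_measured <= 0)) {
    abort("`mean_measured` must be positive")
  }
  100 * see / mean_measured
}

#' One-way ANOVA of prediction conditions against the measured criterion
#'
#' Between-groups one-way ANOVA over five groups -- the measured VO2peak
#' values plus four prediction conditions -- followed by Bonferroni-adjusted
#' two-sided pairwise t tests (pooled variance) of each prediction condition
#' against the measured group (four comparisons per family).
#'
#' @param measured Numeric vector of measured VO2peak values.
#' @param predictions Named list of four numeric vectors, one per prediction
#'   condition; groups may have unequal n (insufficient-data exclusions).
#' @return An `anova_vs_measured` object: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, and a `posthoc` tibble (`condition`, `p_adj`,
#'   `significant` at 0.05).
#' @export
oneway_anova_vs_measured <- function(measured, predictions) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  groups <- c(list(measured = measured), predictions)
  groups <- purrr::map(groups, function(v) v[!is.na(v)])
  small <- names(groups)[purrr::map_int(groups, length) < 2]
  if (length(small) > 0) {
    stop_insufficient(paste0(
      "group(s) with fewer than 2 values: ", paste(small, collapse = ", ")
    ))
  }
  long <- tibble::tibble(
    group = factor(
      rep(names(groups), lengths(groups)), levels = names(groups)
    ),
    value = unlist(groups, use.names = FALSE)
  )
  fit <- stats::aov(value ~ group, data = long)
  sm <- summary(fit)[[1]]
  f_stat <- sm[["F value"]][1]
  p_value <- sm[["Pr(>F)"]][1]
  if (!is.finite(f_stat)) { # zero variance everywhere
    f_stat <- 0
    p_value <- 1
  }

  posthoc <- purrr::map_dfr(names(predictions), function(cond) {
    x <- groups[[cond]]
    y <- groups[["measured"]]
    p <- if (stats::sd(c(x, y)) == 0) {
      1
    } else {
      stats::t.test(x, y, var.equal = TRUE)$p.value
    }
    p_adj <- min(1, p * length(predictions))
    tibble::tibble(
      condition = cond, p_adj = p_adj, significant = p_adj < 0.05
    )
  })

  structure(
    list(
      f_stat = f_stat,
      df_between = sm[["Df"]][1],
      df_within = sm[["Df"]][2],
      p_value = p_value,
      posthoc = posthoc,
      group_n = purrr::map_int(groups, length)
    ),
    class = "anova_vs_measured"
  )
}

#' @export
print.anova_vs_measured <- function(x, ...) {
  cat(sprintf(
    "<anova_vs_measured> F(%d, %d) = %.3f, p = %.4g\n",
    x$df_between, x$df_within, x$f_stat, x$p_value
  ))
  print(x$posthoc)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anova_vs_measured <- function(x, ...) {
  x$posthoc
}

#' @exportS3Method generics::glance
glance.anova_vs_measured <- function(x, ...) {
  tibble::tibble(
    f_stat = x$f_stat, df_between = x$df_between, df_within = x$df_within,
    p_value = x$p_value
  )
}

#' Measured-versus-predicted agreement report (eight conditions)
#'
#' Builds the full comparison table for the eight prediction conditions
#' (scale CERT/EP x ceiling 5/7 x endpoint 10/9). Each row is restricted to
#' the participants whose prediction has `status = "OK"` for that condition;
#' the measured summary, the SD standardizing the SEE and the mean
#' normalizing the RSE are all computed over the same subset, so the
#' "measured" column can differ between rows with different n.
#'
#' @param cohort A `gxt_cohort` tibble.
#' @param predictions Output of [predict_all()].
#' @param denominator SD used to standardize the SEE: `"measured"` (the
#'   criterion SD, the convention the printed bands assume) or
#'   `"predicted"`.
#' @return An `agreement_report` tibble with one row per condition, ordered
#'   endpoint 10 before endpoint 9 and CERT 5, CERT 7, EP 5, EP 7 within an
#'   endpoint. Conditions with n < 3 are flagged `reportable = FALSE` and
#'   carry `NA` statistics.
#' @export
build_table1 <- function(cohort, predictions,
                         denominator = c("measured", "predicted")) {
  denominator <- match.arg(denominator)
  meas <- gxt_participants(cohort) |>
    dplyr::select("participant_id", "vo2peak_measured")

  conds <- tibble::tibble(
    endpoint = rep(c(10L, 9L), each = 4),
    scale = rep(c("CERT", "CERT", "EP", "EP"), 2),
    ceiling = rep(c(5L, 7L, 5L, 7L), 2)
  )

  rows <- purrr::pmap_dfr(conds, function(endpoint, scale, ceiling) {
    ep <- endpoint
    sc <- scale
    cl <- ceiling
    ok <- predictions |>
      dplyr::filter(
        .data$scale == sc, .data$ceiling == cl, .data$endpoint == ep,
        .data$status == "OK"
      ) |>
      dplyr::inner_join(meas, by = "participant_id")
    n <- nrow(ok)
    base <- tibble::tibble(endpoint = ep, scale = sc, ceiling = cl, n = n)
    if (n < 3) {
      return(dplyr::mutate(
        base,
        measured_mean = NA_real_, measured_sd = NA_real_,
        predicted_mean = NA_real_, predicted_sd = NA_real_,
        predicted_ci_low = NA_real_, predicted_ci_high = NA_real_,
        mean_diff = NA_real_, r = NA_real_, r_category = NA_character_,
        see_absolute = NA_real_, see_standardized = NA_real_,
        rse_percent = NA_real_, likelihood = NA_character_,
        reportable = FALSE
      ))
    }
    ms <- summary_stats(ok$vo2peak_measured)
    ps <- summary_stats(ok$vo2peak_predicted)
    pc <- pearson_with_category(ok$vo2peak_measured, ok$vo2peak_predicted)
    see <- see_absolute(ok$vo2peak_measured, ok$vo2peak_predicted)
    sd_denom <- if (denominator == "measured") ms$sd else ps$sd
    ss <- see_standardized(see, sd_denom)
    dplyr::mutate(
      base,
      measured_mean = ms$mean, measured_sd = ms$sd,
      predicted_mean = ps$mean, predicted_sd = ps$sd,
      predicted_ci_low = ps$ci95_low, predicted_ci_high = ps$ci95_high,
      mean_diff = ps$mean - ms$mean,
      r = pc$r, r_category = pc$category,
      see_absolute = see, see_standardized = ss$value,
      rse_percent = relative_standard_error(see, ms$mean),
      likelihood = ss$likelihood,
      reportable = TRUE
    )
  })

  class(rows) <- unique(c("agreement_report", class(rows)))
  rows
}

.likelihood_display <- c(
  trivial = "Trivial", small = "Small", moderate = "Mod.",
  large = "Large", `very large` = "V.large"
)

#' Format an agreement report as an aligned text table
#'
#' Display rounding follows the reporting convention: 1 decimal for VO2
#' means/SDs and RSE, 2 decimals for r, mean difference and standardized
#' SEE, 3 significant digits for the absolute SEE.
#'
#' @param report An `agreement_report` tibble from [build_table1()].
#' @return A character vector of lines.
#' @export
format_table1 <- function(report) {
  header <- sprintf(
    "%-12s %3s %14s %14s %9s %5s %9s %9s %6s %-10s",
    "Condition", "N", "Actual(SD)", "Predicted(SD)", "MeanDiff",
    "r", "SEE abs.", "SEE std.", "RSE%", "Likelihood"
  )
  lines <- purrr::pmap_chr(report, function(...) {
    row <- list(...)
    cond <- sprintf("%s %d -> %d", row$scale, row$ceiling, row$endpoint)
    if (!isTRUE(row$reportable)) {
      return(sprintf("%-12s %3d %s", cond, row$n, "(unreportable: n < 3)"))
    }
    sprintf(
      "%-12s %3d %8.1f (%4.1f) %8.1f (%4.1f) %9.2f %5.2f %9.3g %9.2f %6.1f %-10s",
      cond, row$n, row$measured_mean, row$measured_sd,
      row$predicted_mean, row$predicted_sd, row$mean_diff, row$r,
      row$see_absolute, row$see_standardized, row$rse_percent,
      .likelihood_display[[row$likelihood]]
    )
  })
  c(header, lines)
}

#' @export
print.agreement_report <- function(x, ...) {
  needed <- c(
    "scale", "ceiling", "endpoint", "n", "measured_mean", "measured_sd",
    "predicted_mean", "predicted_sd", "mean_diff", "r", "see_absolute",
    "see_standardized", "rse_percent", "likelihood", "reportable"
  )
  if (!all(needed %in% names(x))) {
    return(NextMethod()) # column subsets print as plain tibbles
  }
  cat(format_table1(x), sep = "\n")
  invisible(x)
}

#' Scatter plots of predicted versus measured VO2peak
#'
#' One panel per prediction condition, with the identity line (perfect
#' agreement, dashed) and the least-squares line of best fit (solid).
#'
#' @param cohort A `gxt_cohort` tibble.
#' @param predictions Output of [predict_all()].
#' @return A ggplot object.
#' @export
plot_agreement <- function(cohort, predictions) {
  meas <- gxt_participants(cohort) |>
    dplyr::select("participant_id", "vo2peak_measured")
  ok <- predictions |>
    dplyr::filter(.data$status == "OK") |>
    dplyr::inner_join(meas, by = "participant_id") |>
    dplyr::mutate(
      condition = sprintf("%s %d → %d", .data$scale, .data$ceiling, .data$endpoint)
    )
  ggplot2::ggplot(
    ok,
    ggplot2::aes(x = .data$vo2peak_predicted, y = .data$vo2peak_measured)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "black") +
    ggplot2::facet_wrap(~condition, nrow = 2) +
    ggplot2::labs(
      x = expression(Predicted ~ dot(V) * O[2 * peak] ~ (ml %.% kg^-1 %.% min^-1)),
      y = expression(Measured ~ dot(V) * O[2 * peak] ~ (ml %.% kg^-1 %.% min^-1))
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.agreement_report <- function(object, ...) {
  df <- dplyr::filter(object, .data$reportable) |>
    dplyr::mutate(
      condition = sprintf("%s %d → %d", .data$scale, .data$ceiling, .data$endpoint)
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = stats::reorder(.data$condition, .data$see_absolute),
                 y = .data$see_absolute, fill = .data$likelihood)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "SEE (ml/kg/min)", fill = "Likelihood"
    ) +
    ggplot2::theme_minimal()
}

#' Write an agreement report to disk
#'
#' @param report An `agreement_report` tibble.
#' @param path Output path; `format = "csv"` writes the full-precision
#'   tibble, `format = "text"` writes the aligned display table.
#' @param format `"csv"` or `"text"`.
#' @return The report, invisibly.
#' @export
write_agreement_report <- function(report, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    write_atomic(path, function(p) {
      readr::write_csv(tibble::as_tibble(report), p, progress = FALSE)
    })
  } else {
    write_atomic(path, function(p) writeLines(format_table1(report), p))
  }
  invisible(report)
}
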