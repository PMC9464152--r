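#' Fit a linear or quadratic age trend to one measure
#'
#' Ordinary least squares of a measure on age, solved in closed form from
#' the normal equations. Reports the standard error of the estimate
#' `SEE = sqrt(RSS / (n - p))`, the coefficient of determination R^2, a
#' two-sided p-value (t test on the slope for the linear model, overall F
#' test for the quadratic model), the percent coefficient of variation
#' `%CV = 100 * SEE / mean(y)`, and — for significant linear fits — the
#' annual percent change relative to the reference age (see
#' [annual_percent_change()]).
#'
#' Pairs with a missing age or value are dropped (listwise per measure)
#' and the retained n is reported.
#'
#' @param data Data frame containing the age and measure columns.
#' @param measure Name of the measure column (string).
#' @param age Name of the age column (default `"age"`).
#' @param degree 1 for linear (default), 2 for quadratic.
#' @param alpha Two-sided significance level gating the derived percent
#'   statistics (default 0.05).
#' @param ref_age Reference age for the annual percent change (default 20,
#'   the lower end of the study age range).
#' @return An object of class `trend_fit`: measure name, `n`, `degree`,
#'   `coefficients` (ascending powers of age), `slope`/`intercept`
#'   convenience fields for degree 1, `see`, `r2`, `p_value`, `pct_cv`,
#'   `annual_pct_change` (`NA` unless degree 1 and `p_value < alpha`), and
#'   the data actually fitted (for plotting).
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_subjects = 30,
#'   trends = data.frame(measure = "imat_volume_cm3", slope = 2.1,
#'                       intercept = 67.2, residual_sd = 0),
#'   seed = 1
#' ))
#' fit <- fit_age_trend(cohort, "imat_volume_cm3")
#' glance(fit)
#' @export
fit_age_trend <- function(data, measure, age = "age", degree = 1,
                          alpha = 0.05, ref_age = 20) {
  stopifnot(is.data.frame(data))
  if (!measure %in% names(data)) {
    abort(sprintf("Measure column '%s' not found.", measure))
  }
  if (!age %in% names(data)) {
    abort(sprintf("Age column '%s' not found.", age))
  }
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2.")
  ok <- stats::complete.cases(data[[age]], data[[measure]])
  x <- as.numeric(data[[age]][ok])
  y <- as.numeric(data[[measure]][ok])
  n <- length(x)
  n_dropped <- sum(!ok)
  p <- degree + 1L
  if (n < p + 1L) {
    abort(sprintf("Need at least %d complete observations, got %d.", p + 1L, n))
  }
  if (stats::var(x) == 0) {
    abort("Ages have zero variance: the age trend is not identifiable.")
  }

  X <- stats::poly(x, degree = degree, raw = TRUE)
  X <- cbind(1, matrix(X, nrow = n))
  beta <- drop(solve(crossprod(X), crossprod(X, y)))
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  see <- sqrt(rss / (n - p))
  r2 <- if (tss > 0) 1 - rss / tss else 0
  sigma2 <- rss / (n - p)

  if (degree == 1) {
    sxx <- sum((x - mean(x))^2)
    se_slope <- sqrt(sigma2 / sxx)
    tval <- if (se_slope > 0) beta[2] / se_slope else Inf * sign(beta[2])
    p_value <- if (is.finite(tval)) 2 * pt(-abs(tval), df = n - 2) else {
      if (beta[2] == 0) 1 else 0
    }
    if (beta[2] == 0 && se_slope == 0) p_value <- 1
  } else {
    # overall model F test
    if (sigma2 > 0) {
      fval <- ((tss - rss) / (p - 1)) / sigma2
      p_value <- pf(fval, p - 1, n - p, lower.tail = FALSE)
    } else {
      p_value <- if (tss > rss) 0 else 1
    }
    se_slope <- NA_real_
  }

  mean_y <- mean(y)
  pct_cv <- if (mean_y != 0) 100 * see / mean_y else NA_real_

  apc <- NA_real_
  if (degree == 1 && p_value < alpha) {
    apc <- annual_percent_change(beta[2], beta[1], ref_age = ref_age)
  }

  structure(
    list(
      measure = measure,
      n = n,
      n_dropped = n_dropped,
      degree = degree,
      coefficients = unname(beta),
      slope = if (degree == 1) beta[2] else NA_real_,
      intercept = beta[1],
      se_slope = se_slope,
      see = see,
      r2 = r2,
      p_value = p_value,
      mean_y = mean_y,
      pct_cv = pct_cv,
      alpha = alpha,
      ref_age = ref_age,
      annual_pct_change = apc,
      data = tibble(age = x, value = y)
    ),
    class = "trend_fit"
  )
}

#' Annual percent change of a linear age trend, relative to a reference age
#'
#' For a linear fit `y = intercept + slope * age`, the annual change as a
#' percentage of the fitted value at the reference age:
#' `100 * slope / (intercept + ref_age * slope)`.
#'
#' When the fitted value at the reference age is very small the statistic
#' explodes; it is still returned (such values are genuinely reported for
#' measures that are near zero at the reference age) but with a warning,
#' since it must be interpreted with caution.
#'
#' @param slope Slope in measure units per year.
#' @param intercept Intercept in measure units (value at age 0).
#' @param ref_age Reference age in years (default 20).
#' @param denom_floor Absolute fitted-value magnitude below which the
#'   instability warning fires (default 0.01 measure units).
#' @return Percent change per year.
#' @examples
#' annual_percent_change(2.1, 67.2)    # 1.92...%/y
#' annual_percent_change(0.059, -0.71) # 12.55...%/y
#' @export
annual_percent_change <- function(slope, intercept, ref_age = 20,
                                  denom_floor = 0.01) {
  denom <- intercept + ref_age * slope
  if (denom == 0) {
    abort(sprintf(
      "Fitted value at age %g is exactly zero: annual percent change undefined.",
      ref_age
    ))
  }
  if (abs(denom) < denom_floor) {
    warn(sprintf(
      paste("Fitted value at age %g is near zero (%.4g): annual percent",
            "change is numerically unstable and should be interpreted with",
            "caution."),
      ref_age, denom
    ))
  }
  100 * slope / denom
}

#' Percent coefficient of variation from the standard error of the estimate
#'
#' `%CV = 100 * SEE / mean(y)` — the regression scatter expressed as a
#' percentage of the cohort mean of the measure.
#'
#' @param see Standard error of the estimate, in measure units.
#' @param mean_y Mean of the measure over the cohort; must be nonzero.
#' @return Percent CV.
#' @export
percent_cv <- function(see, mean_y) {
  if (see < 0) abort("`see` must be nonnegative.")
  if (mean_y == 0) abort("`mean_y` is zero: %CV undefined.")
  100 * see / mean_y
}

#' Evaluate a fitted age trend
#'
#' @param object A `trend_fit`.
#' @param age Ages (years) at which to evaluate the fitted polynomial.
#' @param ... Unused.
#' @return Fitted values in measure units.
#' @examples
#' # published thigh muscle-tissue FF trend: 0.044 %/y on top of 2.6 %
#' predict_trend(c(2.6, 0.044), age = c(25, 50, 80))
#' @export
predict.trend_fit <- function(object, age, ...) {
  predict_trend(object$coefficients, age)
}

#' @describeIn predict.trend_fit Evaluate a polynomial given its
#'   coefficients in ascending powers of age.
#' @param coefficients Numeric vector, ascending powers (intercept first).
#' @export
predict_trend <- function(coefficients, age) {
  powers <- seq_along(coefficients) - 1
  vapply(age, function(a) sum(coefficients * a^powers), numeric(1))
}

#' Percent change of a fitted trend between two ages
#'
#' `100 * (y(age_to) - y(age_from)) / y(age_from)` evaluated on the fitted
#' curve; used to summarise quadratic fits over age segments such as 20--40
#' and 40--70.
#'
#' @param model A `trend_fit` (any degree) or a numeric coefficient vector
#'   in ascending powers.
#' @param age_from,age_to Segment endpoints in years.
#' @return Percent change over the segment, relative to `age_from`.
#' @export
segment_percent_change <- function(model, age_from, age_to) {
  coefs <- if (inherits(model, "trend_fit")) model$coefficients else model
  y0 <- predict_trend(coefs, age_from)
  if (y0 == 0) {
    abort(sprintf("Fitted value at age %g is zero: segment change undefined.",
                  age_from))
  }
  y1 <- predict_trend(coefs, age_to)
  100 * (y1 - y0) / y0
}

#' @export
print.trend_fit <- function(x, ...) {
  kind <- if (x$degree == 1) "linear" else "quadratic"
  cat(sprintf("<trend_fit> %s ~ age (%s), n = %d\n", x$measure, kind, x$n))
  cat(sprintf("  coefficients: %s\n",
              paste(signif(x$coefficients, 4), collapse = ", ")))
  cat(sprintf("  SEE %.4g, R2 %.3f, p %.3g\n", x$see, x$r2, x$p_value))
  if (!is.na(x$annual_pct_change)) {
    cat(sprintf("  annual change: %.2f %%/y relative to age %g\n",
                x$annual_pct_change, x$ref_age))
  }
  invisible(x)
}

#' Tidy and glance methods for age-trend fits
#'
#' `tidy()` returns one row per model term; `glance()` one row of model
#' summaries (n, SEE, R^2, p, %CV, annual % change).
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trend_fit <- function(x, ...) {
  terms <- c("(Intercept)", "age", "age^2")[seq_along(x$coefficients)]
  tibble(
    term = terms,
    estimate = x$coefficients,
    std.error = c(NA_real_, x$se_slope, NA_real_)[seq_along(x$coefficients)]
  )
}

#' @rdname tidy.trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(
    measure = x$measure,
    n = x$n,
    degree = x$degree,
    see = x$see,
    r.squared = x$r2,
    p.value = x$p_value,
    pct_cv = x$pct_cv,
    annual_pct_change = x$annual_pct_change
  )
}

#' Plot an age-trend fit
#'
#' Scatter of the fitted data with the model curve: solid for a linear
#' fit, dashed for a quadratic fit.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_fit <- function(object, ...) {
  grid <- tibble(age = seq(min(object$data$age), max(object$data$age),
                           length.out = 100))
  grid$value <- predict(object, grid$age)
  lt <- if (object$degree == 1) "solid" else "dashed"
  ggplot2::ggplot(object$data, ggplot2::aes(.data$age, .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, linetype = lt) +
    ggplot2::labs(x = "Age (years)", y = object$measure) +
    ggplot2::theme_minimal()
}

#' Linear (or quadratic) trend table over many measures
#'
#' Fits each requested measure against age and assembles the regression
#' summary table: slope, intercept, annual percent change relative to the
#' reference age (blank unless the regression is significant at `alpha`),
#' SEE, R^2 and p. With `degree = 2` the quadratic coefficients and the
#' gated segment percent changes (20 to 40 relative to age 20, 40 to 70
#' relative to age 40 by default) are reported instead.
#'
#' @param cohort Data frame with an age column and one column per measure.
#' @param measures Character vector of measure columns; default: every
#'   numeric column except the age and any `subject_id` column.
#' @param age Age column name (default `"age"`).
#' @param alpha Significance level gating the percent statistics.
#' @param ref_age Reference age for annual percent change.
#' @param degree 1 (linear, default) or 2 (quadratic with segment changes).
#' @param segments For `degree = 2`: two-column matrix-like list of age
#'   segments, default `list(c(20, 40), c(40, 70))`.
#' @return A tibble, one row per measure. Measures listed in `measures`
#'   but absent from `cohort` are reported with a warning and skipped.
#' @export
build_trend_table <- function(cohort, measures = NULL, age = "age",
                              alpha = 0.05, ref_age = 20, degree = 1,
                              segments = list(c(20, 40), c(40, 70))) {
  stopifnot(is.data.frame(cohort))
  if (!age %in% names(cohort)) abort(sprintf("Age column '%s' not found.", age))
  if (is.null(measures)) {
    numeric_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    measures <- setdiff(numeric_cols, c(age, "subject_id"))
  }
  missing_cols <- setdiff(measures, names(cohort))
  if (length(missing_cols) > 0) {
    warn(sprintf("Measure column(s) missing, skipped: %s.",
                 paste(missing_cols, collapse = ", ")))
    measures <- setdiff(measures, missing_cols)
  }
  if (length(measures) == 0) abort("No measure columns to fit.")

  purrr::map_dfr(measures, function(m) {
    fit <- fit_age_trend(cohort, m, age = age, degree = degree,
                         alpha = alpha, ref_age = ref_age)
    if (degree == 1) {
      tibble(
        measure = m,
        n = fit$n,
        slope = fit$slope,
        intercept = fit$intercept,
        pct_change_per_year = fit$annual_pct_change,
        see = fit$see,
        r2 = fit$r2,
        p = fit$p_value,
        pct_cv = fit$pct_cv,
        significant = fit$p_value < alpha
      )
    } else {
      sig <- fit$p_value < alpha
      seg_vals <- purrr::map_dbl(segments, function(s) {
        if (sig) segment_percent_change(fit, s[1], s[2]) else NA_real_
      })
      seg_names <- vapply(segments, function(s) {
        sprintf("pct_change_%g_%g", s[1], s[2])
      }, character(1))
      out <- tibble(
        measure = m,
        n = fit$n,
        coef_age2 = fit$coefficients[3],
        coef_age = fit$coefficients[2],
        intercept = fit$coefficients[1],
        see = fit$see,
        r2 = fit$r2,
        p = fit$p_value,
        significant = sig
      )
      for (i in seq_along(seg_vals)) out[[seg_names[i]]] <- seg_vals[i]
      out
    }
  })
}
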