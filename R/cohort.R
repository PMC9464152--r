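#' Specification of a synthetic cross-sectional cohort
#'
#' Describes a cohort whose measures follow known linear age trends with
#' Gaussian residuals: for each measure, `value = intercept + slope * age
#' + N(0, residual_sd)`, with ages drawn uniformly over the study range.
#' This inverts the age-regression model, so refitting a generated cohort
#' recovers the generating parameters (exactly when `residual_sd = 0`).
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param age_min,age_max Age range in years (defaults 20 and 70, the
#'   study design range for healthy adult males).
#' @param trends Data frame with columns `measure`, `slope` (units/year),
#'   `intercept` (units at age 0) and `residual_sd` (units; matches the
#'   regression SEE scale).
#' @param seed Optional integer seed for bit-reproducibility.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, age_min = 20, age_max = 70, trends,
                        seed = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 3L) abort("`n_subjects` must be >= 3.")
  if (!(age_min < age_max)) abort("`age_min` must be below `age_max`.")
  stopifnot(is.data.frame(trends))
  need <- c("measure", "slope", "intercept", "residual_sd")
  missing_cols <- setdiff(need, names(trends))
  if (length(missing_cols) > 0) {
    abort(sprintf("`trends` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(trends$residual_sd < 0)) abort("`residual_sd` must be >= 0.")
  if (anyDuplicated(trends$measure)) abort("Duplicate measure names in `trends`.")
  structure(
    list(
      n_subjects = n_subjects, age_min = age_min, age_max = age_max,
      trends = as_tibble(trends), seed = seed
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort following known age trends
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `subject_id`, `age`, and one column per measure.
#' @examples
#' spec <- cohort_spec(
#'   n_subjects = 10,
#'   trends = data.frame(measure = "imat_volume_cm3", slope = 2.1,
#'                       intercept = 67.2, residual_sd = 57),
#'   seed = 42
#' )
#' generate_cohort(spec)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  run <- function() {
    n <- spec$n_subjects
    out <- tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = runif(n, spec$age_min, spec$age_max)
    )
    for (i in seq_len(nrow(spec$trends))) {
      tr <- spec$trends[i, ]
      out[[tr$measure]] <-
        tr$intercept + tr$slope * out$age + rnorm(n, 0, tr$residual_sd)
    }
    out
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, run()) else run()
}

#' Reference linear age-trend coefficients for healthy adult males
#'
#' Published linear-regression summaries (slope, intercept, annual percent
#' change relative to age 20, SEE, R^2, significance) of myosteatosis
#' measures against age in healthy males aged 20--70: thigh measures from a
#' 3D fascia-lata analysis (n = 48) and paraspinal measures from a
#' single-slice L2 analysis (n = 44), psoas and erector spinae averaged
#' over left and right. Useful as generating parameters for
#' [cohort_spec()] and as worked-example inputs for
#' [annual_percent_change()].
#'
#' `pct_change_per_year` is the printed value (`NA` for non-significant
#' regressions, where it was not reported); `pct_digits` is the precision
#' it was printed at. The psoas MT FF row prints 1.5 while the
#' slope/intercept arithmetic gives 1.4; the printed value is kept
#' verbatim and the row is flagged `pct_anomaly = TRUE`.
#'
#' @return Tibble with columns `site`, `measure`, `slope`, `intercept`,
#'   `pct_change_per_year`, `pct_digits`, `see`, `r2`, `n`, `significant`,
#'   `pct_anomaly`.
#' @export
reference_trends <- function() {
  thigh <- tibble(
    site = "thigh",
    measure = c(
      "fl_volume_cm3", "imat_volume_cm3", "mt_volume_cm3",
      "imat_over_fl", "mt_over_fl", "imat_over_mt",
      "fl_ff_pct", "mt_ff_pct",
      "imat_over_bmi", "imat_over_asmm", "mtff_over_bmi", "mtff_over_asmm"
    ),
    slope = c(-1.9, 2.1, -4.0, 0.001, -0.001, 0.002, 0.13, 0.044,
              0.065, 0.084, 0.001, 0.002),
    intercept = c(1687, 67.2, 1621, 0.03, 0.97, 0.03, 5.7, 2.6,
                  2.9, 2.0, 0.11, 0.082),
    pct_change_per_year = c(NA, 1.9, -0.3, 2.0, -0.1, 2.9, 1.6, 1.3,
                            1.5, 2.3, 0.8, 1.6),
    see = c(228, 57, 201, 0.03, 0.03, 0.04, 2.8, 1.0, 1.8, 1.9, 0.04, 0.04),
    r2 = c(0.02, 0.24, 0.09, 0.39, 0.39, 0.38, 0.37, 0.34,
           0.24, 0.32, 0.23, 0.31),
    n = 48L,
    significant = c(FALSE, rep(TRUE, 11))
  )
  psoas <- tibble(
    site = "psoas",
    measure = c(
      "roi_volume_cm3", "imat_volume_cm3", "mt_volume_cm3",
      "imat_over_roi", "mt_over_roi", "imat_over_mt",
      "roi_ff_pct", "mt_ff_pct"
    ),
    slope = c(-0.01, 0.002, -0.02, 0.001, 0.001, 0.001, 0.07, 0.065),
    intercept = c(8.9, 0.41, 8.5, 0.04, 0.97, 0.04, 7.0, 3.4),
    pct_change_per_year = c(rep(NA_real_, 7), 1.5),
    see = c(1.5, 0.4, 1.5, 0.05, 0.05, 0.06, 4.48, 1.33),
    r2 = c(0.03, 0.03, 0.03, 0.02, 0.02, 0.02, 0.05, 0.36),
    n = 44L,
    significant = c(rep(FALSE, 7), TRUE)
  )
  erector <- tibble(
    site = "erector",
    measure = c(
      "roi_volume_cm3", "imat_volume_cm3", "mt_volume_cm3",
      "imat_over_roi", "mt_over_roi", "imat_over_mt",
      "roi_ff_pct", "mt_ff_pct"
    ),
    slope = c(-0.04, 0.059, -0.098, 0.003, -0.003, 0.004, 0.30, 0.096),
    intercept = c(21, -0.71, 21.6, -0.045, 1.05, -0.079, -1.38, 1.55),
    pct_change_per_year = c(NA, 12.6, -0.5, 20.0, -0.3, 400.0, 6.5, 2.8),
    see = c(2.5, 0.94, 2.62, 0.049, 0.049, 0.07, 4.26, 1.56),
    r2 = c(0.05, 0.48, 0.25, 0.51, 0.53, 0.48, 0.53, 0.48),
    n = 44L,
    significant = c(FALSE, rep(TRUE, 7))
  )
  out <- dplyr::bind_rows(thigh, psoas, erector)
  out$pct_digits <- 1L
  out$pct_anomaly <- out$site == "psoas" & out$measure == "mt_ff_pct"
  out
}
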