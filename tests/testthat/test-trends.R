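test_that("closed-form OLS equals the reference implementation on random data", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      x <- runif(n, 20, 70)
      y <- rnorm(n, 2 + 0.1 * x, 3)
      d <- data.frame(age = x, y = y)
      fit <- fit_age_trend(d, "y")
      lmfit <- stats::lm(y ~ age, data = d)
      expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-9)
      expect_equal(fit$slope, unname(coef(lmfit)[2]), tolerance = 1e-9)
      s <- summary(lmfit)
      expect_equal(fit$see, s$sigma, tolerance = 1e-9)
      expect_equal(fit$r2, s$r.squared, tolerance = 1e-9)
      expect_equal(fit$p_value, unname(s$coefficients[2, 4]), tolerance = 1e-9)

      qfit <- fit_age_trend(d, "y", degree = 2)
      qlm <- stats::lm(y ~ age + I(age^2), data = d)
      expect_equal(qfit$coefficients, unname(coef(qlm)), tolerance = 1e-8)
    }
  })
})

test_that("degenerate regression inputs are handled as specified", {
  d <- data.frame(age = c(30, 30, 30), y = c(1, 2, 3))
  expect_error(fit_age_trend(d, "y"), "variance")
  expect_error(fit_age_trend(data.frame(age = 1:2, y = 1:2), "y"), "at least")
  # constant response: slope 0, R^2 defined as 0
  dc <- data.frame(age = c(20, 40, 60, 70), y = rep(7, 4))
  fit <- fit_age_trend(dc, "y")
  expect_equal(fit$slope, 0)
  expect_equal(fit$r2, 0)
  # missing pairs are dropped and counted
  dm <- data.frame(age = c(20, 30, 40, 50, NA), y = c(1, 2, NA, 4, 5))
  fitm <- fit_age_trend(dm, "y")
  expect_equal(fitm$n, 3)
  expect_equal(fitm$n_dropped, 2)
})

test_that("annual percent change reproduces the published worked examples", {
  expect_equal(round(annual_percent_change(2.1, 67.2), 1), 1.9)
  expect_equal(annual_percent_change(0, 5), 0)
  expect_equal(round(annual_percent_change(0.059, -0.71), 1), 12.6)
  expect_equal(
    round(suppressWarnings(annual_percent_change(0.004, -0.079)), 1),
    400.0
  )
  expect_error(annual_percent_change(1, -20), "zero")
  expect_warning(annual_percent_change(0.004, -0.079), "caution")
})

test_that("percent CV is SEE relative to the mean response", {
  expect_equal(percent_cv(0, 10), 0)
  expect_equal(percent_cv(10, 10), 100)
  expect_error(percent_cv(1, 0), "zero")
  expect_error(percent_cv(-1, 10), "nonnegative")
  # simulation: fitted %CV approaches 100 * sd / mean
  withr::with_seed(77, {
    tr <- data.frame(measure = "m", slope = 0.044, intercept = 2.6,
                     residual_sd = 1.0)
    cvs <- replicate(60, {
      coh <- generate_cohort(cohort_spec(48, trends = tr))
      fit <- fit_age_trend(coh, "m")
      fit$pct_cv
    })
    mean_y <- 2.6 + 0.044 * 45
    expect_equal(mean(cvs), 100 * 1.0 / mean_y, tolerance = 0.08)
  })
})

test_that("quadratic fits recover parabolas and their segment changes", {
  # exact parabola: coefficients and R^2 = 1
  coefs <- c(5, 0.4, -0.01)
  d <- data.frame(age = seq(20, 70, by = 5))
  d$y <- predict_trend(coefs, d$age)
  fit <- fit_age_trend(d, "y", degree = 2)
  expect_equal(fit$coefficients, coefs, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  # linear data: quadratic term vanishes, segment change matches the line
  dl <- data.frame(age = seq(20, 70, by = 5))
  dl$y <- 67.2 + 2.1 * dl$age
  fl <- fit_age_trend(dl, "y", degree = 2)
  expect_equal(fl$coefficients[3], 0, tolerance = 1e-9)
  expect_equal(
    segment_percent_change(fl, 20, 40),
    100 * (predict_trend(c(67.2, 2.1), 40) - predict_trend(c(67.2, 2.1), 20)) /
      predict_trend(c(67.2, 2.1), 20),
    tolerance = 1e-8
  )
  # direct-evaluation oracle on a random parabola
  withr::with_seed(5, {
    cf <- c(runif(1, 50, 100), runif(1, -1, 1), runif(1, -0.02, 0.02))
    got <- segment_percent_change(cf, 25, 60)
    y0 <- cf[1] + cf[2] * 25 + cf[3] * 625
    y1 <- cf[1] + cf[2] * 60 + cf[3] * 3600
    expect_equal(got, 100 * (y1 - y0) / y0, tolerance = 1e-12)
  })
  expect_equal(segment_percent_change(c(7, 0), 20, 40), 0)
  expect_error(segment_percent_change(c(0, 0), 20, 40), "zero")
})

test_that("trend predictions evaluate the fitted polynomial", {
  # muscle-tissue FF trend of the thigh: 2.6% + 0.044%/y
  expect_equal(round(predict_trend(c(2.6, 0.044), 80), 1), 6.1)
  expect_equal(predict_trend(c(2.6, 0.044), 0), 2.6)
  d <- data.frame(age = seq(20, 70, 10))
  d$y <- 2.6 + 0.044 * d$age
  fit <- fit_age_trend(d, "y")
  expect_equal(predict(fit, c(0, 35)), c(2.6, 2.6 + 0.044 * 35),
               tolerance = 1e-10)
})

test_that("trend table reports gated percent changes and skips missing measures", {
  rt <- reference_trends()
  gen <- rt[rt$site == "thigh", ]
  trends <- data.frame(
    measure = gen$measure, slope = gen$slope, intercept = gen$intercept,
    residual_sd = 0
  )
  coh <- generate_cohort(cohort_spec(48, trends = trends, seed = 99))
  tab <- build_trend_table(coh, measures = gen$measure)
  expect_equal(tab$measure, gen$measure)
  expect_equal(tab$slope, gen$slope, tolerance = 1e-9)
  expect_equal(tab$intercept, gen$intercept, tolerance = 1e-9)
  # noise-free fits are all significant, so every percent change is reported
  expect_equal(round(tab$pct_change_per_year, 1)[gen$measure != "fl_volume_cm3"],
               gen$pct_change_per_year[gen$measure != "fl_volume_cm3"])

  # a pure-noise measure must be gated out
  withr::with_seed(4, {
    coh$noise <- rnorm(48, 10, 5)
  })
  tab2 <- build_trend_table(coh, measures = c("imat_volume_cm3", "noise"))
  expect_true(is.na(tab2$pct_change_per_year[tab2$measure == "noise"]))
  expect_false(tab2$significant[tab2$measure == "noise"])

  expect_warning(
    tab3 <- build_trend_table(coh, measures = c("imat_volume_cm3", "absent")),
    "absent"
  )
  expect_equal(nrow(tab3), 1)
})

test_that("type-I rate of percent-change reporting is near alpha for null slopes", {
  withr::with_seed(123, {
    hits <- replicate(300, {
      coh <- generate_cohort(cohort_spec(
        30, trends = data.frame(measure = "m", slope = 0, intercept = 10,
                                residual_sd = 2)
      ))
      fit <- fit_age_trend(coh, "m")
      !is.na(fit$annual_pct_change)
    })
    rate <- mean(hits)
    expect_gt(rate, 0.015)
    expect_lt(rate, 0.10)
  })
})

test_that("tidy, glance and autoplot work on trend fits", {
  d <- data.frame(age = seq(20, 70, 5))
  d$y <- 67.2 + 2.1 * d$age + sin(seq_len(nrow(d)))
  fit <- fit_age_trend(d, "y")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "age"))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(d))
  expect_s3_class(autoplot(fit), "ggplot")
  h <- detect_modes_and_minimum(
    build_ff_histogram(
      ff_volume(array(c(40, 40, 850, 40), dim = c(2, 2, 1))),
      roi_mask(array(TRUE, dim = c(2, 2, 1)))
    )
  )
  expect_s3_class(autoplot(h), "ggplot")
  expect_equal(sum(tidy(h)$raw_count), 4)
})
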