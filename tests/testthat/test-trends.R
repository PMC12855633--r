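test_that("polynomial fit recovers an exact cubic with zero residuals", {
  yrs <- 1985:2020
  vals <- 3 + 0.5 * (yrs - 2000) - 0.02 * (yrs - 2000)^2 +
    0.004 * (yrs - 2000)^3
  fit <- fit_polynomial(tibble::tibble(year = yrs, value = vals), 3)
  expect_lt(max(abs(fit$data$residual)), 1e-8)
  expect_lt(fit$mae, 1e-8)
  expect_equal(fit$data$fitted + fit$data$residual, fit$data$observed)
})

test_that("polynomial fit handles constant series and underdetermined input", {
  fit <- fit_polynomial(tibble::tibble(year = 1:10, value = 7), 3)
  expect_equal(fit$data$fitted, rep(7, 10), tolerance = 1e-10)
  expect_error(fit_polynomial(tibble::tibble(year = 1:3, value = 1:3), 3),
               "underdetermined")
})

test_that("MAE matches a hand computation on a 5-point series", {
  d <- tibble::tibble(year = 1:5, value = c(2, 4, 3, 8, 10))
  fit <- fit_polynomial(d, 1)
  # brute-force simple regression on the same points
  x <- d$year - mean(d$year)
  beta <- sum(x * d$value) / sum(x^2)
  alpha <- mean(d$value)
  resid <- d$value - (alpha + beta * x)
  expect_equal(fit$mae, mean(abs(resid)), tolerance = 1e-12)
})

test_that("fit is invariant to translating the year axis", {
  set.seed(5)
  d <- tibble::tibble(year = 1985:2020, value = rnorm(36, 50, 10))
  f1 <- fit_polynomial(d, 4)
  f2 <- fit_polynomial(dplyr::mutate(d, year = year + 1000), 4)
  expect_equal(f1$data$fitted, f2$data$fitted, tolerance = 1e-9)
  expect_equal(f1$mae, f2$mae, tolerance = 1e-9)
})

test_that("tidiers expose coefficients, fit statistics and per-year data", {
  d <- tibble::tibble(year = 1:10, value = (1:10)^2)
  fit <- fit_polynomial(d, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$degree, 2)
  expect_equal(gl$r.squared, 1, tolerance = 1e-9)
  expect_equal(augment(fit), fit$data)
})

test_that("fluctuation threshold rounds MAE to the nearest 10, ties down", {
  mk <- function(mae) structure(list(mae = mae), class = "trend_fit")
  expect_equal(fluctuation_threshold(mk(52.8)), 50)
  expect_equal(fluctuation_threshold(mk(0)), 0)
  expect_equal(fluctuation_threshold(mk(55)), 50)
  expect_equal(fluctuation_threshold(mk(55.01)), 60)
  expect_equal(fluctuation_threshold(mk(4.9)), 0)
  expect_equal(fluctuation_threshold(mk(52.8), rounding = "none"), 52.8)
})

test_that("remobilization window is recovered from a constructed cubic", {
  # genuine cubic strictly below -50 exactly for 1988..2016, with
  # threshold crossings at 1987.6 and 2016.4
  yrs <- 1985:2020
  f <- function(y) -50 - 0.4 * (y - 1987.6) * (2016.4 - y) * (2100 - y) / 100
  fit <- fit_polynomial(tibble::tibble(year = yrs, value = f(yrs)), 3)
  expect_lt(fit$mae, 1e-8) # exact cubic
  win <- detect_remobilization_window(fit, 50)
  expect_equal(win$start_year, 1988)
  expect_equal(win$end_year, 2016)
  expect_equal(win$duration, 28)
})

test_that("window detection under multiplicative noise stays within a year", {
  yrs <- 1985:2020
  f <- function(y) -50 - 0.4 * (y - 1987.6) * (2016.4 - y) * (2100 - y) / 100
  set.seed(17)
  noisy <- f(yrs) * rlnorm(length(yrs), 0, sqrt(log(1 + 0.2^2)))
  fit <- fit_polynomial(tibble::tibble(year = yrs, value = noisy), 3)
  win <- detect_remobilization_window(fit, 50)
  expect_lte(abs(win$start_year - 1988), 1)
  expect_lte(abs(win$end_year - 2016), 1)
  expect_lte(abs(win$duration - 28), 2)
})

test_that("window detection edge cases", {
  yrs <- 2000:2010
  flat <- fit_polynomial(tibble::tibble(year = yrs, value = -10), 0)
  expect_null(detect_remobilization_window(flat, 50))
  neg <- fit_polynomial(tibble::tibble(year = yrs, value = -10), 0)
  full <- detect_remobilization_window(neg, 0)
  expect_equal(full$start_year, 2000)
  expect_equal(full$end_year, 2010)
  expect_equal(full$duration, 10)
})

test_that("endpoint change interpretability matches brute force on a toy series", {
  d <- tibble::tibble(year = 1:6, value = c(10, 12, 9, 11, 10, 30))
  fit <- fit_polynomial(d, 1)
  res <- endpoint_change_interpretable(fit, percentile = 90)
  change <- abs(fit$data$fitted[6] - fit$data$fitted[1])
  q <- unname(quantile(abs(diff(d$value)), 0.9))
  expect_equal(res$endpoint_change, change)
  expect_equal(res$fluctuation_quantile, q)
  expect_identical(res$interpretable, change >= q)
})

test_that("interpretability: flat noise is not, a strong ramp is", {
  set.seed(31)
  yrs <- 1985:2020
  flat <- tibble::tibble(year = yrs, value = 50 + rnorm(36, 0, 10))
  expect_false(
    endpoint_change_interpretable(fit_polynomial(flat, 3))$interpretable)
  ramp <- tibble::tibble(year = yrs,
                         value = seq(150, 10, length.out = 36) + rnorm(36, 0, 3))
  expect_true(
    endpoint_change_interpretable(fit_polynomial(ramp, 3))$interpretable)
})

test_that("interpretability is scale-equivariant", {
  set.seed(12)
  d <- tibble::tibble(year = 1:20, value = 1:20 + rnorm(20, 0, 4))
  base <- endpoint_change_interpretable(fit_polynomial(d, 2))$interpretable
  for (c_scale in c(0.001, 17, 4000)) {
    scaled <- dplyr::mutate(d, value = value * c_scale)
    expect_identical(
      endpoint_change_interpretable(fit_polynomial(scaled, 2))$interpretable,
      base)
  }
})

test_that("linear trend: exact line, noise, and ramp recovery", {
  exact <- suppressWarnings(
    linear_trend(tibble::tibble(year = 1:20, value = 2 * (1:20))))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_lt(exact$p_value, 1e-12)

  set.seed(8)
  noise <- linear_trend(tibble::tibble(year = 1:50, value = rnorm(50)))
  expect_gt(noise$p_value, 0.05)
  expect_lt(abs(noise$slope), 0.05)

  # a 36-year temperature-like ramp from 8.2 to 9.4 with small noise
  set.seed(9)
  d <- tibble::tibble(year = 1985:2020,
                      value = seq(8.2, 9.4, length.out = 36) + rnorm(36, 0, 0.1))
  lt <- linear_trend(d)
  expect_equal(lt$fitted_start, 8.2, tolerance = 0.02)
  expect_equal(lt$fitted_end, 9.4, tolerance = 0.02)
  expect_lt(lt$p_value, 0.001)

  expect_error(linear_trend(tibble::tibble(year = c(1, 1, 1), value = 1:3)),
               "degenerate")
})

test_that("correlation R2: exact line, independence, brute force", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_r2(x, 3 + 2 * x), 1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3)
  # brute-force Pearson on 4 points
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlation_r2(x, y), (num / den)^2, tolerance = 1e-12)
  set.seed(14)
  expect_lt(correlation_r2(rnorm(500), rnorm(500)), 0.05)
  expect_error(correlation_r2(1:3, rep(1, 3)), "variance")
  expect_error(correlation_r2(1:3, 1:4), "equal length")
})
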