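#' Polynomial trend fit for an annual series
#'
#' Ordinary least squares polynomial fit on a centered, unit-scaled year
#' axis (which makes the fit invariant to shifting all years by a
#' constant). Low-degree polynomials (3-5) are used throughout the package
#' to visualize and interpret long-term monitoring series; the mean
#' absolute residual (MAE) measures the typical fluctuation of the data
#' around the trend line and feeds [fluctuation_threshold()].
#'
#' @param data A data frame of the annual series.
#' @param degree Polynomial degree; must be smaller than the number of
#'   observations.
#' @param year,value Column names (unquoted) of the year axis and the
#'   series values.
#' @return An object of class `trend_fit`: a list with `data` (tibble
#'   `year`, `observed`, `fitted`, `residual`), `degree`, `coefficients`
#'   (on the scaled axis), `mae`, `center`, `scale`.
#' @export
#' @examples
#' d <- tibble::tibble(year = 1985:2020, value = (1985:2020 - 2000)^3 / 500)
#' fit <- fit_polynomial(d, degree = 3)
#' fit$mae
fit_polynomial <- function(data, degree, year = year, value = value) {
  yr <- dplyr::pull(data, {{ year }})
  y <- dplyr::pull(data, {{ value }})
  keep <- !is.na(yr) & !is.na(y)
  yr <- yr[keep]
  y <- y[keep]
  degree <- as.integer(degree)
  if (degree < 0) abort("degree must be >= 0")
  if (length(y) < degree + 1) {
    abort("fit underdetermined: need at least degree + 1 observations")
  }
  center <- mean(yr)
  scale <- if (length(yr) > 1 && stats::sd(yr) > 0) stats::sd(yr) else 1
  x <- (yr - center) / scale
  X <- outer(x, 0:degree, `^`)
  colnames(X) <- paste0("x^", 0:degree)
  fit <- lm.fit(X, y)
  fitted <- as.numeric(X %*% fit$coefficients)
  residual <- y - fitted
  structure(
    list(
      data = tibble::tibble(year = yr, observed = y, fitted = fitted,
                            residual = residual),
      degree = degree,
      coefficients = setNames(fit$coefficients, colnames(X)),
      mae = mean(abs(residual)),
      center = center,
      scale = scale
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> degree ", x$degree, ", n = ", nrow(x$data),
      ", MAE = ", signif(x$mae, 4), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname fit_polynomial
#' @method tidy trend_fit
#' @param x A `trend_fit`.
#' @param ... Unused.
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
#' @rdname fit_polynomial
#' @method glance trend_fit
glance.trend_fit <- function(x, ...) {
  obs <- x$data$observed
  r2 <- if (stats::sd(obs) > 0) cor(obs, x$data$fitted)^2 else NA_real_
  tibble::tibble(degree = x$degree, n = nrow(x$data), mae = x$mae,
                 r.squared = r2)
}

#' @export
#' @rdname fit_polynomial
#' @method augment trend_fit
augment.trend_fit <- function(x, ...) {
  x$data
}

#' Fluctuation threshold from a trend fit
#'
#' Turns the mean absolute residual of a polynomial trend fit into a
#' round-number "natural fluctuation zone" half-width: values of the
#' series within +/- threshold of zero are read as noise, values beyond it
#' as real signal. The default rounds the MAE to the nearest multiple of
#' 10 with ties toward zero (an MAE of 52.8 gives 50).
#'
#' @param fit A `trend_fit`.
#' @param rounding `"nearest10"` (default) or `"none"`.
#' @return Threshold in the units of the series.
#' @export
fluctuation_threshold <- function(fit, rounding = c("nearest10", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(fit, "trend_fit"))
  if (rounding == "none") return(fit$mae)
  m <- fit$mae / 10
  f <- floor(m)
  (f + as.numeric(m - f > 0.5)) * 10
}

#' Detect a remobilization window in a fitted trend
#'
#' Finds the maximal contiguous run of years in which the fitted trend
#' value lies below `-threshold` (a sustained real loss, e.g. sulfur
#' remobilized from the topsoil). The crossing years at the window edges
#' are located by linear interpolation between the adjacent grid years and
#' rounded to the nearest integer year; the duration is reported as
#' `end_year - start_year`.
#'
#' @param fit A `trend_fit` on a yearly grid.
#' @param threshold Non-negative threshold (e.g. from
#'   [fluctuation_threshold()]).
#' @return A one-row tibble `start_year`, `end_year`, `duration`, or
#'   `NULL` if no fitted value falls below `-threshold`.
#' @export
detect_remobilization_window <- function(fit, threshold) {
  stopifnot(inherits(fit, "trend_fit"), threshold >= 0)
  d <- dplyr::arrange(fit$data, .data$year)
  yr <- d$year
  f <- d$fitted
  below <- f < -threshold
  if (!any(below)) return(NULL)
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  pick <- cand[which.max(runs$lengths[cand])]
  i <- starts[pick]
  j <- ends[pick]
  cross <- function(a, b) {
    # linear interpolation of the -threshold crossing between years a < b
    yr[a] + (-threshold - f[a]) / (f[b] - f[a]) * (yr[b] - yr[a])
  }
  start_year <- if (i == 1) yr[1] else round(cross(i - 1, i))
  end_year <- if (j == length(yr)) yr[length(yr)] else round(cross(j, j + 1))
  tibble::tibble(start_year = start_year, end_year = end_year,
                 duration = end_year - start_year)
}

#' Is the endpoint-to-endpoint change of a trend interpretable?
#'
#' Compares the absolute change of the fitted trend between the first and
#' last year with a high percentile of the inter-annual fluctuations of
#' the observed series. If the fitted change does not exceed that
#' percentile, the apparent trend is within the year-to-year noise and is
#' not interpreted. "Inter-annual fluctuation" is operationalized as the
#' absolute year-to-year first differences of the observed series
#' (`method = "first_differences"`, the default) or alternatively as the
#' absolute residuals of the fit (`method = "residuals"`).
#'
#' @param fit A `trend_fit`.
#' @param percentile Percentile of the fluctuation distribution to compare
#'   against (default 90).
#' @param method Fluctuation definition, see above.
#' @return A one-row tibble `interpretable`, `endpoint_change`,
#'   `fluctuation_quantile`, `percentile`.
#' @export
endpoint_change_interpretable <- function(fit, percentile = 90,
                                          method = c("first_differences",
                                                     "residuals")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "trend_fit"))
  d <- dplyr::arrange(fit$data, .data$year)
  if (nrow(d) < 3) abort("need at least 3 years")
  change <- abs(d$fitted[nrow(d)] - d$fitted[1])
  fluct <- switch(method,
    first_differences = abs(diff(d$observed)),
    residuals = abs(d$residual)
  )
  q <- unname(quantile(fluct, percentile / 100))
  tibble::tibble(
    interpretable = change >= q,
    endpoint_change = change,
    fluctuation_quantile = q,
    percentile = percentile
  )
}

#' Linear trend with a t-test on the slope
#'
#' Ordinary least squares regression of an annual series on the year, with
#' the usual two-sided t-test on the slope and the fitted values at the
#' series endpoints (a compact way to report "from a to b over the span").
#'
#' @inheritParams fit_polynomial
#' @return A one-row tibble `slope`, `intercept`, `p_value`, `r_squared`,
#'   `fitted_start`, `fitted_end`.
#' @export
#' @examples
#' d <- tibble::tibble(year = 1:10, value = 2 * (1:10))
#' linear_trend(d)$slope # 2
linear_trend <- function(data, year = year, value = value) {
  yr <- dplyr::pull(data, {{ year }})
  y <- dplyr::pull(data, {{ value }})
  keep <- !is.na(yr) & !is.na(y)
  yr <- yr[keep]
  y <- y[keep]
  if (length(y) < 3) abort("need at least 3 points")
  if (stats::sd(yr) == 0) abort("degenerate year axis")
  fit <- lm(y ~ yr)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = sm$coefficients[2, 4],
    r_squared = sm$r.squared,
    fitted_start = unname(fitted(fit)[which.min(yr)]),
    fitted_end = unname(fitted(fit)[which.max(yr)])
  )
}

#' Squared Pearson correlation of two series
#'
#' @param x,y Numeric vectors of equal length (>= 3), constant-free.
#' @return R-squared, the squared Pearson correlation coefficient.
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance series")
  cor(x, y)^2
}
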