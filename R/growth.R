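# Division-rate inference: exponential-rate fitting from growth curves,
# linear calibration of rate against rRNA-probe fluorescence, and inverse
# prediction of in-gut doubling time.

#' Fit an exponential growth rate from a growth curve
#'
#' OLS slope of `ln(OD)` on time over the sliding window of consecutive
#' points (default width 5) with the highest R^2, restricted to the
#' exponential OD range (default 0.02-0.5). Windowing isolates the
#' exponential phase from lag and saturation.
#'
#' @param curve Data.frame with columns `time_h` and `od`.
#' @param window_width Number of consecutive points per candidate window.
#' @param od_bounds OD range defining the exponential phase.
#' @return The growth rate per hour, with attributes `r_squared` and
#'   `window` (the time range used).
#' @examples
#' tt <- 0:10
#' curve <- data.frame(time_h = tt, od = 0.02 * exp(0.6 * tt))
#' fit_exponential_rate(curve)  # 0.6
#' @export
fit_exponential_rate <- function(curve, window_width = 5,
                                 od_bounds = c(0.02, 0.5)) {
  stopifnot(all(c("time_h", "od") %in% names(curve)))
  d <- curve[order(curve$time_h), , drop = FALSE]
  d <- d[d$od >= od_bounds[1] & d$od <= od_bounds[2], , drop = FALSE]
  if (nrow(d) < 4)
    stop("fewer than 4 points fall inside the exponential OD bounds",
         call. = FALSE)
  w <- min(window_width, nrow(d))
  best <- NULL
  for (i in seq_len(nrow(d) - w + 1)) {
    win <- d[i:(i + w - 1), ]
    fit <- stats::lm(log(od) ~ time_h, data = win)
    r2 <- summary(fit)$r.squared
    if (is.nan(r2)) r2 <- 1  # zero-variance response: perfectly flat fit
    if (is.null(best) || r2 > best$r2)
      best <- list(rate = unname(stats::coef(fit)[2]), r2 = r2,
                   range = range(win$time_h))
  }
  structure(best$rate, r_squared = best$r2, window = best$range)
}

#' Fit the growth-rate vs fluorescence calibration model
#'
#' Linear OLS of growth rate (per hour) on median probe fluorescence across
#' growth conditions. When the table carries a `sample` column, duplicate
#' hybridizations are averaged within sample before fitting.
#'
#' @param pairs Data.frame with columns `rate_per_hour` and
#'   `median_fluorescence`, optionally `sample` for replicate averaging.
#' @return A `calibration_model` list: `slope`, `intercept`, `residual_sd`,
#'   `n`, `f_range`, `f_mean`, `sxx` (the latter two feed the delta-method
#'   prediction error).
#' @export
fit_calibration <- function(pairs) {
  stopifnot(all(c("rate_per_hour", "median_fluorescence") %in% names(pairs)))
  d <- pairs
  if ("sample" %in% names(d)) {
    f <- tapply(d$median_fluorescence, d$sample, mean)
    r <- tapply(d$rate_per_hour, d$sample, mean)
    d <- data.frame(median_fluorescence = as.numeric(f),
                    rate_per_hour = as.numeric(r))
  }
  if (length(unique(d$median_fluorescence)) < 3)
    stop("need at least 3 distinct fluorescence values", call. = FALSE)
  fit <- stats::lm(rate_per_hour ~ median_fluorescence, data = d)
  cf <- stats::coef(fit)
  if (abs(cf[2]) < .Machine$double.eps)
    stop("calibration slope is zero; the model is not invertible", call. = FALSE)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 residual_sd = summary(fit)$sigma, n = nrow(d),
                 f_range = range(d$median_fluorescence),
                 f_mean = mean(d$median_fluorescence),
                 sxx = sum((d$median_fluorescence -
                              mean(d$median_fluorescence))^2)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("rate = %.4g + %.4g * F (per hour; residual sd %.3g, n = %d)\n",
              x$intercept, x$slope, x$residual_sd, x$n))
  cat(sprintf("calibrated fluorescence range: %.4g - %.4g\n",
              x$f_range[1], x$f_range[2]))
  invisible(x)
}

#' Infer doubling time from hybridization fluorescence
#'
#' Inverts the calibration model by prediction: the growth rate at the
#' observed fluorescence is `intercept + slope * F`, and the doubling time
#' is `60 * ln(2) / rate` minutes. The standard error propagates the
#' calibration prediction error by the delta method. Fluorescence outside
#' the calibrated range triggers an extrapolation warning.
#'
#' @param fluorescence Median fluorescence (arbitrary units); vectorized.
#' @param model A [fit_calibration()] model.
#' @return A data.frame with columns `fluorescence`, `rate_per_hour`,
#'   `doubling_min`, `doubling_se_min`.
#' @examples
#' m <- structure(list(slope = 1e-3, intercept = 0.1, residual_sd = 0,
#'                     n = 8, f_range = c(100, 800), f_mean = 450,
#'                     sxx = 4.2e5), class = "calibration_model")
#' infer_doubling_time(593.1, m)  # rate ~0.6931 -> ~60 min
#' @export
infer_doubling_time <- function(fluorescence, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(fluorescence < model$f_range[1] | fluorescence > model$f_range[2]))
    warning("fluorescence outside the calibrated range; extrapolating",
            call. = FALSE)
  rate <- model$intercept + model$slope * fluorescence
  if (any(rate <= 0))
    stop("predicted growth rate is non-positive; cannot invert to a doubling time",
         call. = FALSE)
  # prediction se of the mean response at F, then delta method through
  # t_double = 60 ln2 / rate
  se_rate <- model$residual_sd *
    sqrt(1 / model$n + (fluorescence - model$f_mean)^2 / model$sxx)
  doubling <- 60 * log(2) / rate
  data.frame(fluorescence = fluorescence, rate_per_hour = rate,
             doubling_min = doubling,
             doubling_se_min = doubling / rate * se_rate)
}

#' Cohort doubling-time summary
#'
#' Averages duplicate hybridizations within each mouse-day sample, inverts
#' each sample through the calibration model, and summarizes the cohort.
#'
#' @param hyb Data.frame with columns `mouse_id`, `day`, `replicate`,
#'   `median_fluorescence` (as produced by [simulate_hybridization()]).
#' @param model A [fit_calibration()] model.
#' @return A list with `per_sample` (data.frame of per-mouse-day doubling
#'   times), `mean_doubling_min` and `sem_doubling_min` (2 s.e.m. across
#'   samples is twice this).
#' @export
doubling_time_summary <- function(hyb, model) {
  stopifnot(all(c("mouse_id", "day", "median_fluorescence") %in% names(hyb)))
  key <- interaction(hyb$mouse_id, hyb$day, drop = TRUE)
  f <- tapply(hyb$median_fluorescence, key, mean)
  ids <- do.call(rbind, strsplit(names(f), ".", fixed = TRUE))
  inv <- infer_doubling_time(as.numeric(f), model)
  per_sample <- data.frame(mouse_id = ids[, 1], day = as.numeric(ids[, 2]),
                           inv, stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       mean_doubling_min = mean(per_sample$doubling_min),
       sem_doubling_min = stats::sd(per_sample$doubling_min) /
         sqrt(nrow(per_sample)))
}
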