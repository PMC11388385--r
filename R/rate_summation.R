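#' Thermal regime: a time series of temperatures
#'
#' A measured or constructed temperature record, stored as hours since the
#' start of the winter treatment plus the temperature at each time point.
#' Temperatures are treated as piecewise constant between consecutive
#' samples (left-closed segments), matching the semantics of hourly or
#' 10-minute logger records.
#'
#' @param time_h Strictly increasing numeric vector, hours since day 0.
#' @param temperature Numeric vector of temperatures (degrees C).
#' @param description Free-text label, e.g. `"12:12 h 0:8 degC"`.
#' @return An object of class `thermal_regime`.
#' @export
thermal_regime <- function(time_h, temperature, description = "") {
  if (length(time_h) != length(temperature) || length(time_h) < 1L) {
    stop("time_h and temperature must be equal-length, non-empty",
         call. = FALSE)
  }
  if (anyNA(time_h) || anyNA(temperature) || any(!is.finite(temperature))) {
    stop("regime contains missing or non-finite values", call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("time_h must be strictly increasing", call. = FALSE)
  }
  structure(list(time_h = as.numeric(time_h),
                 temperature = as.numeric(temperature),
                 description = description),
            class = "thermal_regime")
}

#' @export
print.thermal_regime <- function(x, ...) {
  cat(sprintf("Thermal regime%s: %d points over %.1f days, %.1f to %.1f degC\n",
              if (nzchar(x$description)) paste0(" '", x$description, "'") else "",
              length(x$time_h), diff(range(x$time_h)) / 24,
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Build a square-wave daily thermal regime from field notation
#'
#' Parses specifications of the form `"H1:H2 h T1:T2 degC"` — H1 hours at
#' temperature T1 followed by H2 hours at T2 within each 24-hour day (H1 +
#' H2 must equal 24) — and samples the cycle on a regular grid.
#'
#' @param spec Specification string, e.g. `"22:2 h 0:15 degC"` or
#'   `"12:12 h -2:10"`.
#' @param days Number of days the regime should cover.
#' @param step_min Sampling resolution in minutes (default hourly).
#' @return A [thermal_regime] object.
#' @export
square_wave_regime <- function(spec, days, step_min = 60) {
  m <- regmatches(spec, regexec(
    "^\\s*(\\d+(?:\\.\\d+)?):(\\d+(?:\\.\\d+)?)\\s*h\\s+(-?\\d+(?:\\.\\d+)?):(-?\\d+(?:\\.\\d+)?)", spec))[[1]]
  if (length(m) != 5L) {
    stop(sprintf("cannot parse regime spec '%s'; expected 'H1:H2 h T1:T2'",
                 spec), call. = FALSE)
  }
  h1 <- as.numeric(m[2]); h2 <- as.numeric(m[3])
  t1 <- as.numeric(m[4]); t2 <- as.numeric(m[5])
  if (abs(h1 + h2 - 24) > 1e-9) {
    stop("square-wave phases must sum to 24 h", call. = FALSE)
  }
  step_h <- step_min / 60
  time_h <- seq(0, days * 24 - step_h, by = step_h)
  phase <- time_h %% 24
  thermal_regime(time_h, ifelse(phase < h1, t1, t2), description = spec)
}

#' Accumulated expected termination progress under a thermal regime
#'
#' Rate summation: subdivides the regime into piecewise-constant segments
#' between consecutive samples, evaluates the TPC on each segment, and sums
#' segment rate x duration. Reported at integer days: `S(t)` includes every
#' segment whose midpoint falls before day `t`. Gaps up to `max_gap_hours`
#' are bridged by carrying the last temperature forward (the piecewise-
#' constant rule); larger gaps raise an error naming the gap.
#'
#' @param regime A [thermal_regime] object.
#' @param tpc A [tpc_params()] object.
#' @param horizon_days Integer number of days to report.
#' @param max_gap_hours Largest tolerated spacing between samples (default
#'   3 h).
#' @return Numeric vector `S` of length `horizon_days`; `S[t]` is the
#'   accumulated dimensionless progress by day `t`. Nondecreasing, with
#'   implicit `S(0) = 0`.
#' @export
accumulated_progress <- function(regime, tpc, horizon_days,
                                 max_gap_hours = 3) {
  stopifnot(inherits(regime, "thermal_regime"), is_tpc_params(tpc))
  horizon_days <- as.integer(horizon_days)
  if (horizon_days < 1L) stop("horizon_days must be >= 1", call. = FALSE)
  end_h <- horizon_days * 24
  gaps <- diff(regime$time_h)
  if (any(gaps > max_gap_hours)) {
    i <- which.max(gaps)
    stop(sprintf(
      "regime gap of %.2f h between %.2f h and %.2f h exceeds tolerance %.2f h",
      gaps[i], regime$time_h[i], regime$time_h[i + 1], max_gap_hours),
      call. = FALSE)
  }
  if (regime$time_h[1] > max_gap_hours ||
      regime$time_h[length(regime$time_h)] < end_h - max_gap_hours) {
    stop(sprintf("regime does not cover the %d-day horizon", horizon_days),
         call. = FALSE)
  }
  keep <- regime$time_h < end_h
  t0 <- regime$time_h[keep]
  temp <- regime$temperature[keep]
  t1 <- c(t0[-1], end_h)
  dt_days <- (t1 - t0) / 24
  contrib <- lrf_rate(temp, tpc) * dt_days
  day_bin <- pmin(floor(((t0 + t1) / 2) / 24) + 1, horizon_days)
  per_day <- numeric(horizon_days)
  agg <- rowsum(contrib, day_bin)
  per_day[as.integer(rownames(agg))] <- agg[, 1]
  cumsum(per_day)
}

#' Predicted cumulative termination probability under a fluctuating regime
#'
#' Combines rate summation with the lognormal individual-variation model:
#' the probability that an individual has terminated by day `t` is
#' `pnorm(log(S(t)) / sigma_sex)`, where `S(t)` is the accumulated
#' geometric-mean progress (including the batch intercept for batch 2) and
#' `sigma_sex` the sex-specific log-scale SD. Days with zero accumulated
#' progress have probability 0. For a constant regime this reproduces the
#' constant-temperature formula exactly.
#'
#' @param regime A [thermal_regime] object or a single constant temperature.
#' @param params A [termination_params()] object.
#' @param sex `"male"` or `"female"`.
#' @param batch 1 or 2.
#' @param horizon_days Days to predict.
#' @param max_gap_hours Passed to [accumulated_progress()].
#' @return Data frame with columns `day`, `progress` (S(t)) and `prob`.
#' @export
predict_fluctuating <- function(regime, params, sex = "male", batch = 1L,
                                horizon_days = 300, max_gap_hours = 3) {
  sex <- match.arg(sex, c("male", "female"))
  tpc <- term_tpc_for_sex(params, sex)
  if (is.numeric(regime) && length(regime) == 1L) {
    S <- lrf_rate(regime, tpc) * seq_len(horizon_days)
  } else {
    S <- accumulated_progress(regime, tpc, horizon_days, max_gap_hours)
  }
  if (batch == 2L) S <- S * exp(params$batch_effect)
  sigma <- term_sigma_for_sex(params, sex)
  prob <- ifelse(S > 0, stats::pnorm(log(S) / sigma), 0)
  data.frame(day = seq_len(horizon_days), progress = S, prob = prob)
}
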