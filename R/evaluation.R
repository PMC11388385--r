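#' Observed versus predicted cumulative termination counts
#'
#' Day-by-day fit diagnostic: among all trials transferred by day `d`, the
#' observed cumulative number of terminations is compared with the expected
#' cumulative count under the model — the sum of each such trial's predicted
#' termination probability (smooth expected counts, not thresholded
#' simulation).
#'
#' @param trials Trials table for one treatment.
#' @param prediction Data frame with `day` and `prob` columns (e.g. from
#'   [predict_fluctuating()]); must cover every transfer day.
#' @return List with `series` (day, observed, predicted) and
#'   `max_abs_error`. Empty trials yield an empty series.
#' @export
cumulative_count_comparison <- function(trials, prediction) {
  if (nrow(trials) == 0L) {
    return(list(series = data.frame(day = numeric(0), observed = numeric(0),
                                    predicted = numeric(0)),
                max_abs_error = NA_real_))
  }
  if (length(unique(trials$treatment_id)) != 1L) {
    stop("trials must come from a single treatment", call. = FALSE)
  }
  if (max(trials$transfer_day) > max(prediction$day)) {
    stop("prediction horizon does not cover all transfer days",
         call. = FALSE)
  }
  p_at <- prediction$prob[match(trials$transfer_day, prediction$day)]
  if (anyNA(p_at)) stop("prediction missing some transfer days",
                        call. = FALSE)
  days <- sort(unique(trials$transfer_day))
  obs <- vapply(days, function(d) {
    sum(trials$terminated[trials$transfer_day <= d])
  }, numeric(1))
  pred <- vapply(days, function(d) {
    sum(p_at[trials$transfer_day <= d])
  }, numeric(1))
  series <- data.frame(day = days, observed = obs, predicted = pred)
  list(series = series, max_abs_error = max(abs(obs - pred)))
}

#' Observed versus predicted day of termination
#'
#' For each observed increment in the proportion of total terminations
#' (k-th termination out of K), records the transfer day on which it
#' occurred and the day at which the prediction reaches the same proportion
#' of its *own* total, linearly interpolated between prediction days.
#' Proportions the prediction never reaches are recorded as missing.
#'
#' @param trials Trials table for one treatment (>= 1 termination).
#' @param prediction Data frame with `day` and `prob` columns.
#' @return List with `series` (proportion, observed_day, predicted_day,
#'   error_days) and `max_abs_error` over non-missing rows.
#' @export
day_of_termination_comparison <- function(trials, prediction) {
  term <- trials[trials$terminated == 1L, ]
  if (nrow(term) == 0L) stop("no observed terminations", call. = FALSE)
  term <- term[order(term$transfer_day), ]
  K <- nrow(term)
  props <- seq_len(K) / K
  obs_day <- term$transfer_day
  # expected cumulative count under the prediction, on the trial design
  p_at <- prediction$prob[match(trials$transfer_day, prediction$day)]
  if (anyNA(p_at)) stop("prediction missing some transfer days",
                        call. = FALSE)
  days <- sort(unique(trials$transfer_day))
  pred_cum <- vapply(days, function(d) {
    sum(p_at[trials$transfer_day <= d])
  }, numeric(1))
  total <- pred_cum[length(pred_cum)]
  pred_day <- rep(NA_real_, K)
  if (total > 0) {
    frac <- pred_cum / total
    for (k in seq_len(K)) {
      i <- which(frac >= props[k])[1]
      if (is.na(i)) next
      if (i == 1L || frac[i] == props[k]) {
        pred_day[k] <- days[i]
      } else {
        f0 <- frac[i - 1L]; f1 <- frac[i]
        pred_day[k] <- days[i - 1L] +
          (props[k] - f0) / (f1 - f0) * (days[i] - days[i - 1L])
      }
    }
  }
  series <- data.frame(proportion = props, observed_day = obs_day,
                       predicted_day = pred_day,
                       error_days = obs_day - pred_day)
  list(series = series,
       max_abs_error = if (all(is.na(series$error_days))) NA_real_
       else max(abs(series$error_days), na.rm = TRUE))
}

#' Reduced major axis regression
#'
#' Standardised (geometric mean) regression used for observed-vs-predicted
#' agreement: slope is `sign(cor(x, y)) * sd(y) / sd(x)` and the line passes
#' through the centroid.
#'
#' @param x,y Numeric vectors (>= 3 points; x must vary).
#' @return Named vector `c(slope, intercept)`.
#' @export
rma_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need >= 3 paired points", call. = FALSE)
  }
  sdx <- stats::sd(x)
  if (sdx == 0) stop("x has zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- sign(if (is.na(r) || r == 0) 1 else r) * stats::sd(y) / sdx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Headline quantities derived from fitted parameters
#'
#' Translates model parameters into the quantities the field reports:
#' termination time at the thermal optimum (`1 / r_opt`, days, per sex), the
#' typical between-individual percentage difference implied by the lognormal
#' SD (`exp(sigma) - 1`), the percentage by which one sex outpaces the other
#' (`exp(effect) - 1`), and the fraction of postdiapause development
#' completed under a warm winter (`1 - exp(-delta)`, see
#' [completed_fraction_from_log_shift()]). Full-precision values are
#' returned alongside reporting-rounded companions (nearest day / nearest
#' percent).
#'
#' @param r_opt_male,r_opt_female Peak termination rates (per day).
#' @param sigma Lognormal termination-rate SD (sex-averaged or per sex).
#' @param sex_effect Log-scale development sex intercept.
#' @param history_shift Log-scale development-rate elevation after warm
#'   winter.
#' @return Data frame with columns `quantity`, `value`, `rounded`, `unit`.
#' @export
derived_quantities <- function(r_opt_male, r_opt_female, sigma,
                               sex_effect = 0, history_shift = 0) {
  rows <- list(
    c("termination_time_topt_male", 1 / r_opt_male, "days"),
    c("termination_time_topt_female", 1 / r_opt_female, "days"),
    c("percent_individual_difference", 100 * (exp(sigma) - 1), "percent"),
    c("percent_faster_male_development", 100 * (exp(sex_effect) - 1),
      "percent"),
    c("percent_winter_completion",
      100 * completed_fraction_from_log_shift(history_shift), "percent"))
  out <- data.frame(
    quantity = vapply(rows, `[`, "", 1L),
    value = as.numeric(vapply(rows, `[`, "", 2L)),
    unit = vapply(rows, `[`, "", 3L),
    stringsAsFactors = FALSE)
  out$rounded <- round(out$value)
  out[, c("quantity", "value", "rounded", "unit")]
}
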