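#' Parameters of the postdiapause development-rate model
#'
#' Postdiapause development rate (1/days from transfer to eclosion) follows
#' a left-skewed LRF curve of postwinter temperature with lognormal error.
#' The sex effect is an intercept centered on zero (+e/2 for males, -e/2 for
#' females, so the TPC itself is sex-averaged); pupae that overwintered at
#' 4 degrees C — above the development threshold — carry a positive
#' log-scale intercept because part of their development was already
#' completed during winter. The TPC's `r_opt` is anchored to the 2 degree C
#' winter-history group, for which no development could occur before
#' transfer.
#'
#' @param tpc Left-skewed [tpc_params()], sex-averaged.
#' @param sex_effect Male-female log-scale intercept difference (centered).
#' @param history_effect Log-scale rate elevation for 4 degree C winter
#'   history relative to 2 degree C.
#' @param sigma_dev Lognormal observation SD (> 0).
#' @param family_sd SD of family random intercepts, >= 0.
#' @return An object of class `development_params`.
#' @export
development_params <- function(tpc, sex_effect = 0, history_effect = 0,
                               sigma_dev, family_sd = 0) {
  stopifnot(is_tpc_params(tpc))
  if (tpc$skew != "left") stop("development TPC must be left-skewed",
                               call. = FALSE)
  if (sigma_dev <= 0) stop("sigma_dev must be positive", call. = FALSE)
  if (family_sd < 0) stop("family_sd must be >= 0", call. = FALSE)
  structure(list(tpc = tpc, sex_effect = sex_effect,
                 history_effect = history_effect, sigma_dev = sigma_dev,
                 family_sd = family_sd),
            class = "development_params")
}

#' @export
print.development_params <- function(x, ...) {
  cat(sprintf(
    "Postdiapause development model\n  T_min %.3g T_opt %.3g T_max %.3g R_opt %.4g; sigma %.3g\n  sex effect %.3g, 4-degC history effect %.3g (log scale)\n",
    x$tpc$t_min, x$tpc$t_opt, x$tpc$t_max, x$tpc$r_opt, x$sigma_dev,
    x$sex_effect, x$history_effect))
  invisible(x)
}

#' Natural-log geometric mean postdiapause development rate
#'
#' `log(lrf_rate(T)) + sex_effect/2 * (+1 male, -1 female) +
#' history_effect * 1{4 degC winter}`. Returns `-Inf` (the zero-rate signal)
#' where `T` lies outside the TPC support. `sex = "average"` drops the sex
#' term.
#'
#' @param T Postwinter temperature, degrees C (vectorised).
#' @param sex `"male"`, `"female"` or `"average"`.
#' @param winter_history `"2C"`, `"4C"` or `"other"` (treated as `"2C"`).
#' @param params A [development_params()] object.
#' @return Natural-log rate(s), day^-1 on the natural scale.
#' @export
development_rate_mean <- function(T, sex = "average", winter_history = "2C",
                                  params) {
  sex <- match.arg(sex, c("average", "male", "female"))
  winter_history <- match.arg(winter_history, c("2C", "4C", "other"))
  mu <- lrf_rate(T, params$tpc)
  sx <- switch(sex, average = 0, male = params$sex_effect / 2,
               female = -params$sex_effect / 2)
  hx <- if (winter_history == "4C") params$history_effect else 0
  ifelse(mu > 0, log(mu) + sx + hx, -Inf)
}

#' Fraction of postdiapause development completed during winter
#'
#' A log-scale elevation `delta` of the apparent development rate after a
#' warm winter is interpreted as removal of a fraction `f` of the remaining
#' development: with fraction `f` already done, the remaining time shrinks
#' by `(1 - f)` and the apparent rate rises by `-log(1 - f)`, so
#' `f = 1 - exp(-delta)`.
#'
#' @param delta Nonnegative log-scale rate elevation.
#' @return Completed fraction in \[0, 1).
#' @export
completed_fraction_from_log_shift <- function(delta) {
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  1 - exp(-delta)
}

#' Quantiles of postdiapause development time
#'
#' Development time is the reciprocal of a lognormal rate, so the q-th
#' quantile of time corresponds to the (1-q)-th rate quantile:
#' `time_q = 1 / exp(log_mean + qnorm(1 - q) * sigma_dev)`. Quantile `q`
#' is oriented so that larger `q` means a *longer* development time
#' (time quantiles are nondecreasing in `q`); the median (`q = 0.5`) is
#' exactly the reciprocal geometric-mean rate.
#'
#' @param T Postwinter temperature inside the TPC support.
#' @param sex `"male"`, `"female"` or `"average"`.
#' @param params A [development_params()] object.
#' @param quantiles Probabilities in (0, 1).
#' @param winter_history As in [development_rate_mean()].
#' @return Named numeric vector of development times (days).
#' @export
development_time_quantiles <- function(T, sex = "average", params,
                                       quantiles = c(0.1, 0.5, 0.9),
                                       winter_history = "2C") {
  if (any(quantiles <= 0 | quantiles >= 1)) {
    stop("quantiles must lie strictly inside (0, 1)", call. = FALSE)
  }
  lmu <- development_rate_mean(T, sex, winter_history, params)
  if (!is.finite(lmu)) {
    stop("temperature outside the development TPC support", call. = FALSE)
  }
  tq <- 1 / exp(lmu + stats::qnorm(1 - quantiles) * params$sigma_dev)
  stats::setNames(tq, paste0("q", quantiles))
}
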