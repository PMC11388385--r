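#' Parameters of the latent lognormal diapause-termination model
#'
#' The generative model for binary transfer-experiment data: each pupa
#' carries a latent termination-rate multiplier drawn once from a lognormal
#' distribution with median 1, and its daily termination rate is that
#' multiplier times a temperature-dependent geometric mean given by a
#' right-skewed LRF curve. Physiological progress accumulates as rate x time;
#' an individual has terminated once accumulated progress reaches 1.
#' Effects of experimental batch and family enter as intercepts on the
#' natural-log rate scale (multiplicative on rates).
#'
#' @param tpc_male,tpc_female Right-skewed [tpc_params()] per sex.
#' @param sigma_male,sigma_female SD of the natural-log rate (positive).
#' @param batch_effect Additive shift on the natural-log rate for batch 2
#'   relative to batch 1 (batch 1 is the reference).
#' @param family_sd SD of family-by-treatment random intercepts on the
#'   natural-log rate; 0 disables family structure.
#' @return An object of class `termination_params`.
#' @export
termination_params <- function(tpc_male, tpc_female, sigma_male, sigma_female,
                               batch_effect = 0, family_sd = 0) {
  stopifnot(is_tpc_params(tpc_male), is_tpc_params(tpc_female))
  if (tpc_male$skew != "right" || tpc_female$skew != "right") {
    stop("termination TPCs must be right-skewed", call. = FALSE)
  }
  if (sigma_male <= 0 || sigma_female <= 0) {
    stop("sigma_male and sigma_female must be positive", call. = FALSE)
  }
  if (family_sd < 0) stop("family_sd must be >= 0", call. = FALSE)
  structure(
    list(tpc_male = tpc_male, tpc_female = tpc_female,
         sigma_male = sigma_male, sigma_female = sigma_female,
         batch_effect = batch_effect, family_sd = family_sd),
    class = "termination_params"
  )
}

#' @export
print.termination_params <- function(x, ...) {
  cat("Diapause termination model parameters\n")
  cat(sprintf("  males:   T_min %.3g T_opt %.3g T_max %.3g R_opt %.4g  sigma %.3g\n",
              x$tpc_male$t_min, x$tpc_male$t_opt, x$tpc_male$t_max,
              x$tpc_male$r_opt, x$sigma_male))
  cat(sprintf("  females: T_min %.3g T_opt %.3g T_max %.3g R_opt %.4g  sigma %.3g\n",
              x$tpc_female$t_min, x$tpc_female$t_opt, x$tpc_female$t_max,
              x$tpc_female$r_opt, x$sigma_female))
  cat(sprintf("  batch-2 effect %.3g (log scale); family SD %.3g\n",
              x$batch_effect, x$family_sd))
  invisible(x)
}

term_tpc_for_sex <- function(params, sex) {
  if (identical(sex, "male")) params$tpc_male else params$tpc_female
}

term_sigma_for_sex <- function(params, sex) {
  if (identical(sex, "male")) params$sigma_male else params$sigma_female
}

#' Natural-log geometric mean termination rate with design offsets
#'
#' The log of the LRF geometric-mean rate at temperature `T` for the given
#' sex, plus the batch-2 intercept when `batch == 2` and the family-level
#' random intercept for batch 1. Family intercepts are nullified (forced to
#' zero) for batch 2, which has no recorded family structure. Where the TPC
#' is zero (temperature outside the curve's support) the result is `-Inf`,
#' the zero-rate signal consumed downstream as termination probability 0.
#'
#' @param T Temperature, degrees C (scalar or vector).
#' @param sex `"male"` or `"female"`.
#' @param batch 1 or 2.
#' @param family_intercept Log-scale family-by-treatment offset (scalar or
#'   vector matching `T`); ignored for batch 2.
#' @param params A [termination_params()] object.
#' @return Natural-log rate(s); `-Inf` outside the TPC support.
#' @export
log_geometric_mean_rate <- function(T, sex, batch, family_intercept = 0,
                                    params) {
  sex <- match.arg(sex, c("male", "female"))
  if (!batch %in% c(1L, 2L)) stop("batch must be 1 or 2", call. = FALSE)
  mu <- lrf_rate(T, term_tpc_for_sex(params, sex))
  off <- if (batch == 2L) params$batch_effect else family_intercept
  ifelse(mu > 0, log(mu) + off, -Inf)
}

#' Cumulative probability of having terminated diapause
#'
#' Probability that a lognormal(0, sigma^2) individual rate multiplier times
#' the accumulated geometric-mean progress exceeds the completion threshold
#' of 1: `pnorm(log_rate_sum / sigma)`. For a constant temperature held for
#' `t` days, `log_rate_sum = log(t) + log(mu(T))`. A `log_rate_sum` of
#' `-Inf` (zero accumulated progress) maps to probability 0.
#'
#' @param log_rate_sum Natural log of accumulated expected progress
#'   (dimensionless); may be `-Inf`.
#' @param sigma Log-scale SD of individual rates, > 0.
#' @return Probability in \[0, 1\]; nondecreasing in `log_rate_sum`.
#' @export
cumulative_termination_prob <- function(log_rate_sum, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  p <- stats::pnorm(log_rate_sum / sigma)
  p[log_rate_sum == -Inf] <- 0
  p
}

# Probability clamp for Bernoulli log-mass; keeps saturated trials finite.
TERMINATION_PROB_EPS <- 1e-12

#' Bernoulli log likelihood of termination trials
#'
#' Sums the Bernoulli log-mass over trials, with per-trial success
#' probability given by [cumulative_termination_prob()] evaluated at the
#' trial's transfer day under its mean treatment temperature. Probabilities
#' are clamped to `[1e-12, 1 - 1e-12]` for numerical stability; the clamp
#' only matters for saturated trials (accumulated progress effectively 0 or
#' infinite).
#'
#' @param trials A `termination_trials` data frame (see
#'   [termination_trials()]) carrying a numeric `temperature` column with
#'   each trial's mean treatment temperature.
#' @param params A [termination_params()] object.
#' @param family_intercepts Named numeric vector of log-scale intercepts
#'   keyed by `family:treatment_id` (see [family_cell_key()]); missing keys
#'   default to 0. Ignored for batch-2 trials.
#' @return Total log likelihood (0 for an empty trial set).
#' @export
trial_log_likelihood <- function(trials, params, family_intercepts = NULL) {
  if (nrow(trials) == 0L) return(0)
  if (is.null(trials$temperature) || anyNA(trials$temperature)) {
    stop("trials must carry a complete 'temperature' column", call. = FALSE)
  }
  p <- trial_probabilities(trials, params, family_intercepts)
  p <- pmin(pmax(p, TERMINATION_PROB_EPS), 1 - TERMINATION_PROB_EPS)
  sum(ifelse(trials$terminated == 1L, log(p), log1p(-p)))
}

# Per-trial termination probability under constant treatment temperature.
trial_probabilities <- function(trials, params, family_intercepts = NULL) {
  fam_off <- rep(0, nrow(trials))
  if (!is.null(family_intercepts) && length(family_intercepts)) {
    key <- family_cell_key(trials$family, trials$treatment_id)
    hit <- !is.na(key) & key %in% names(family_intercepts) &
      trials$batch == 1L
    fam_off[hit] <- family_intercepts[key[hit]]
  }
  p <- numeric(nrow(trials))
  for (sx in c("male", "female")) {
    i <- trials$sex == sx
    if (!any(i)) next
    lmu <- log_geometric_mean_rate(trials$temperature[i], sx,
                                   batch = 1L, family_intercept = 0,
                                   params = params)
    off <- ifelse(trials$batch[i] == 2L, params$batch_effect, fam_off[i])
    ls <- log(trials$transfer_day[i]) + lmu + off
    p[i] <- cumulative_termination_prob(ls, term_sigma_for_sex(params, sx))
  }
  p
}

#' Key identifying one family-by-treatment random-intercept cell
#'
#' @param family Family identifiers (NA for batch-2 pupae).
#' @param treatment_id Treatment identifiers.
#' @return Character keys `"family:treatment"`; NA where family is NA.
#' @export
family_cell_key <- function(family, treatment_id) {
  ifelse(is.na(family), NA_character_, paste(family, treatment_id, sep = ":"))
}

#' Simulate individual diapause-termination trajectories
#'
#' Draws one lognormal rate multiplier per individual (a single draw shared
#' across all temperatures it experiences, so an individual's rate scales
#' multiplicatively with temperature change), accumulates daily progress
#' `multiplier * mu(T_day)`, and returns the first day on which accumulated
#' progress reaches the completion threshold of 1. Individuals that never
#' reach the threshold within the horizon get `NA`.
#'
#' @param n Number of individuals (>= 1).
#' @param regime Either a single finite temperature (constant conditions) or
#'   a [thermal_regime] object.
#' @param params A [termination_params()] object.
#' @param sex `"male"` or `"female"`.
#' @param batch 1 or 2 (applies the batch intercept).
#' @param horizon_days Number of days to simulate.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `n`: termination day or `NA`.
#' @export
simulate_individual_paths <- function(n, regime, params, sex = "male",
                                      batch = 1L, horizon_days = 365,
                                      seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sex <- match.arg(sex, c("male", "female"))
  S <- daily_progress(regime, params, sex, batch, horizon_days)
  sigma <- term_sigma_for_sex(params, sex)
  m <- exp(stats::rnorm(n, 0, sigma))
  # first day d with m * S[d] >= 1  <=>  S[d] >= 1/m ; S is nondecreasing
  day <- findInterval(1 / m, S, left.open = TRUE) + 1L
  day[day > length(S)] <- NA_integer_
  if (all(S <= 0)) day[] <- NA_integer_
  day
}

# Accumulated geometric-mean progress at integer days 1..horizon, with sex
# and batch offsets applied multiplicatively.
daily_progress <- function(regime, params, sex, batch, horizon_days) {
  tpc <- term_tpc_for_sex(params, sex)
  if (is.numeric(regime) && length(regime) == 1L) {
    if (!is.finite(regime)) stop("constant temperature must be finite",
                                 call. = FALSE)
    S <- lrf_rate(regime, tpc) * seq_len(horizon_days)
  } else if (inherits(regime, "thermal_regime")) {
    S <- accumulated_progress(regime, tpc, horizon_days)
  } else {
    stop("regime must be a single temperature or a thermal_regime",
         call. = FALSE)
  }
  if (batch == 2L) S <- S * exp(params$batch_effect)
  S
}
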