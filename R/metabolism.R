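#' Convert respirometry gas volumes to a mass-specific metabolic rate
#'
#' Applies the standard oxyjoule conversion
#' `vO2 * (16 + 5.164 * (vCO2 / vO2))` (joules per day from gas exchange,
#' with the respiratory-quotient correction) and divides by body mass.
#' Linear in each gas volume and homogeneous of degree -1 in mass.
#'
#' @param v_o2 Oxygen consumption, mL/day (vectorised).
#' @param v_co2 Carbon dioxide production, mL/day.
#' @param mass Body mass, g (> 0).
#' @return Mass-specific metabolic rate, J g^-1 day^-1. A record with both
#'   gas volumes zero returns 0; `v_o2 = 0` with `v_co2 > 0` is an error
#'   (undefined respiratory quotient).
#' @examples
#' metabolic_rate_joules(1, 1, 1)   # 21.164
#' @export
metabolic_rate_joules <- function(v_o2, v_co2, mass) {
  n <- max(length(v_o2), length(v_co2), length(mass))
  v_o2 <- rep_len(v_o2, n); v_co2 <- rep_len(v_co2, n)
  mass <- rep_len(mass, n)
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  if (any(v_o2 < 0) || any(v_co2 < 0)) {
    stop("gas volumes must be nonnegative", call. = FALSE)
  }
  if (any(v_o2 == 0 & v_co2 > 0)) {
    stop("v_o2 = 0 with v_co2 > 0: respiratory quotient undefined",
         call. = FALSE)
  }
  out <- numeric(n)
  pos <- v_o2 > 0
  out[pos] <- v_o2[pos] * (16 + 5.164 * (v_co2[pos] / v_o2[pos])) / mass[pos]
  out
}

#' Fit the exponential metabolic-rate model to respirometry records
#'
#' Models the natural log of the mass-specific metabolic rate as affine in
#' temperature with sex-specific intercepts and slopes, a random intercept
#' per individual (repeated measures at pupal ages 30/90/150 d) and a random
#' intercept per treatment-by-age cell. The linear mixed model is estimated
#' by REML via [lme4::lmer()]; approximate posterior draws for the fixed
#' effects come from the asymptotic Gaussian sampling distribution
#' (conditional on the variance components, which enter the draw matrix as
#' point estimates).
#'
#' @param records Respirometry data frame with columns `pupa_id`, `sex`,
#'   `mass`, `temperature`, `v_o2`, `v_co2`, `age_days`, `treatment_id`.
#' @param n_draws Number of approximate posterior draws.
#' @param seed Optional seed for the draw generation.
#' @return A [posterior_set] with per-sex `intercept_<sex>` and
#'   `slope_<sex>` columns plus `sigma_obs`, `sd_individual`, `sd_cell`.
#' @export
fit_metabolic_model <- function(records, n_draws = 1000, seed = NULL) {
  validate_respirometry_records(records)
  if (length(unique(records$temperature)) < 2L) {
    stop("need >= 2 distinct temperatures to identify a slope", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- records
  d$rate <- metabolic_rate_joules(d$v_o2, d$v_co2, d$mass)
  if (any(d$rate <= 0)) stop("nonpositive metabolic rates cannot be logged",
                             call. = FALSE)
  d$log_rate <- log(d$rate)
  d$sex <- factor(d$sex)
  d$cell <- interaction(d$treatment_id, d$age_days, drop = TRUE)
  single_sex <- nlevels(d$sex) == 1L
  form <- if (single_sex) {
    log_rate ~ temperature + (1 | pupa_id) + (1 | cell)
  } else {
    log_rate ~ 0 + sex + sex:temperature + (1 | pupa_id) + (1 | cell)
  }
  fit <- lme4::lmer(form, data = d,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  draws_fix <- MASS::mvrnorm(n_draws, beta, V)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(grp) {
    v <- vc$sdcor[vc$grp == grp & is.na(vc$var2)]
    if (length(v)) v[1] else 0
  }
  # map lmer coefficient names onto the package's parameter names
  if (single_sex) {
    sx <- as.character(d$sex[1])
    out <- cbind(draws_fix[, "(Intercept)", drop = FALSE],
                 draws_fix[, "temperature", drop = FALSE])
    colnames(out) <- paste0(c("intercept_", "slope_"), sx)
  } else {
    sexes <- levels(d$sex)
    out <- NULL
    for (sx in sexes) {
      ic <- draws_fix[, paste0("sex", sx), drop = FALSE]
      sl <- draws_fix[, paste0("sex", sx, ":temperature"), drop = FALSE]
      blk <- cbind(ic, sl)
      colnames(blk) <- paste0(c("intercept_", "slope_"), sx)
      out <- cbind(out, blk)
    }
  }
  out <- cbind(out,
               sigma_obs = rep(stats::sigma(fit), n_draws),
               sd_individual = rep(sd_of("pupa_id"), n_draws),
               sd_cell = rep(sd_of("cell"), n_draws))
  modes <- c(stats::setNames(as.numeric(out[1, seq_len(ncol(out) - 3)]),
                             colnames(out)[seq_len(ncol(out) - 3)]),
             sigma_obs = stats::sigma(fit),
             sd_individual = sd_of("pupa_id"), sd_cell = sd_of("cell"))
  # replace the arbitrary first-draw fixed-effect "modes" with the REML point
  fix_names <- colnames(out)[seq_len(ncol(out) - 3)]
  point <- if (single_sex) {
    stats::setNames(c(beta["(Intercept)"], beta["temperature"]), fix_names)
  } else {
    v <- numeric(0)
    for (sx in levels(d$sex)) {
      v <- c(v, beta[paste0("sex", sx)], beta[paste0("sex", sx, ":temperature")])
    }
    stats::setNames(as.numeric(v), fix_names)
  }
  modes[fix_names] <- point
  posterior_set(out, modes = modes)
}

validate_respirometry_records <- function(records) {
  req <- c("pupa_id", "sex", "mass", "temperature", "v_o2", "v_co2",
           "age_days", "treatment_id")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("respirometry records missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(records$mass <= 0)) stop("mass must be positive", call. = FALSE)
  invisible(records)
}
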