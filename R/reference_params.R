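#' Reference parameter values for Pieris napi diapause biology
#'
#' Posterior-mode parameter estimates for the green-veined white butterfly
#' (*Pieris napi*), used throughout the package as the default "true" values
#' of the synthetic-study generator and as worked-example inputs. Males
#' terminate diapause fastest just above 0 degrees C at about 0.0075 / day
#' (a ~134-day termination time at the optimum); females peak at ~0.0063 /
#' day (~158 days). The second experimental batch has a lower termination
#' rate (intercept -0.230 on the natural-log scale).
#'
#' @return [pnapi_termination_params()] returns a [termination_params()]
#'   object; [pnapi_development_params()] a [development_params()] object;
#'   [pnapi_metabolic_params()] a list with `male` and `female`
#'   [exp_curve_params()] plus `sigma_obs`, the lognormal observation SD.
#' @name pnapi_reference
NULL

#' @rdname pnapi_reference
#' @export
pnapi_termination_params <- function() {
  termination_params(
    tpc_male   = tpc_params(-6.18, 0.683, 31.3, 0.00746, skew = "right"),
    tpc_female = tpc_params(-4.11, 1.60, 30.9, 0.00634, skew = "right"),
    sigma_male = 0.240,
    sigma_female = 0.208,
    batch_effect = -0.230,
    family_sd = 0
  )
}

#' @rdname pnapi_reference
#' @export
pnapi_development_params <- function() {
  development_params(
    tpc = tpc_params(1.99, 29.6, 36.9, 0.152, skew = "left"),
    sex_effect = 0.0927,
    history_effect = 0.060,
    sigma_dev = 0.0852,
    family_sd = 0
  )
}

#' @rdname pnapi_reference
#' @export
pnapi_metabolic_params <- function() {
  list(
    male = exp_curve_params(intercept = 0.273, slope = 0.0926),
    female = exp_curve_params(intercept = 0.183, slope = 0.0779),
    sigma_obs = 0.177
  )
}

#' The four fluctuating overwintering regimes used for model validation
#'
#' Square-wave daily temperature cycles in the field's "H1:H2 h T1:T2 degC"
#' notation: H1 hours at T1 followed by H2 hours at T2 each day. Two
#' symmetric 12:12 regimes and two asymmetric 22:2 regimes.
#'
#' @return Character vector of four regime specification strings accepted by
#'   [square_wave_regime()].
#' @export
pnapi_fluctuating_regimes <- function() {
  c("12:12 h 0:8 degC", "12:12 h -2:10 degC",
    "22:2 h 0:15 degC", "22:2 h 15:0 degC")
}
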