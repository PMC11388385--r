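#' Cardinal-temperature thermal performance curve parameters
#'
#' Constructs and validates the parameter set of a Lobry-Rosso-Flandrois
#' (LRF) thermal performance curve: the three cardinal temperatures and the
#' peak rate. The `skew` flag selects between the standard left-skewed form
#' (typical of development rates, long cold tail) and its mirror image, the
#' right-skewed form used for diapause termination (peak near the cold end,
#' long warm tail). Both orientations share the same four interpretable
#' parameters: the curve is zero at and beyond `t_min` and `t_max` and equals
#' `r_opt` exactly at `t_opt`.
#'
#' @param t_min Minimum temperature (degrees C) below which the rate is zero.
#' @param t_opt Temperature (degrees C) at which the rate peaks.
#' @param t_max Maximum temperature (degrees C) above which the rate is zero.
#' @param r_opt Peak rate (per day), strictly positive.
#' @param skew Either `"left"` (development-type curve) or `"right"`
#'   (termination-type curve).
#' @return An object of class `tpc_params`.
#' @examples
#' tpc <- tpc_params(t_min = -6.18, t_opt = 0.683, t_max = 31.3,
#'                   r_opt = 0.00746, skew = "right")
#' lrf_rate(c(-10, 0.683, 8, 35), tpc)
#' @export
tpc_params <- function(t_min, t_opt, t_max, r_opt, skew = c("left", "right")) {
  skew <- match.arg(skew)
  for (v in list(t_min, t_opt, t_max, r_opt)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("all TPC parameters must be single finite numbers", call. = FALSE)
    }
  }
  if (!(t_min < t_opt && t_opt < t_max)) {
    stop("cardinal temperatures must satisfy t_min < t_opt < t_max",
         call. = FALSE)
  }
  if (r_opt <= 0) stop("r_opt must be positive", call. = FALSE)
  structure(
    list(t_min = t_min, t_opt = t_opt, t_max = t_max, r_opt = r_opt,
         skew = skew),
    class = "tpc_params"
  )
}

#' @export
print.tpc_params <- function(x, ...) {
  cat(sprintf(
    "LRF thermal performance curve (%s-skewed)\n  T_min %.3g  T_opt %.3g  T_max %.3g degC;  R_opt %.4g / day\n",
    x$skew, x$t_min, x$t_opt, x$t_max, x$r_opt))
  invisible(x)
}

is_tpc_params <- function(x) inherits(x, "tpc_params")

# Left-skewed Rosso cardinal form, vectorised over T; zero outside the
# support and wherever the algebraic value would be negative or non-finite
# (pathological denominators).
lrf_left_core <- function(T, t_min, t_opt, t_max, r_opt) {
  out <- numeric(length(T))
  inside <- T > t_min & T < t_max
  if (any(inside)) {
    Ti <- T[inside]
    num <- r_opt * (Ti - t_max) * (Ti - t_min)^2
    den <- (t_opt - t_min) *
      ((t_opt - t_min) * (Ti - t_opt) -
         (t_opt - t_max) * (t_opt + t_min - 2 * Ti))
    val <- num / den
    val[!is.finite(val) | val < 0] <- 0
    out[inside] <- val
  }
  out
}

#' Evaluate an LRF thermal performance curve
#'
#' Computes the rate at temperature `T` under the cardinal-temperature LRF
#' model. For `skew = "left"` this is the standard Rosso form
#' \deqn{R(T) = R_{opt} \frac{(T - T_{max})(T - T_{min})^2}{(T_{opt} -
#'   T_{min})[(T_{opt} - T_{min})(T - T_{opt}) - (T_{opt} - T_{max})(T_{opt}
#'   + T_{min} - 2T)]}}
#' inside `(t_min, t_max)` and 0 outside. For `skew = "right"` the curve is
#' the mirror image, obtained by evaluating the left-skewed form at `-T` with
#' reflected cardinal temperatures `(-t_max, -t_opt, -t_min)`; this keeps all
#' four parameters' meanings identical between the two orientations.
#'
#' The returned rate is continuous on the whole real line, nonnegative
#' everywhere, and attains its unique interior maximum `r_opt` at `t_opt`.
#'
#' @param T Numeric vector of temperatures (degrees C); must be finite.
#' @param params A [tpc_params()] object.
#' @return Numeric vector of rates (per day), same length as `T`.
#' @export
lrf_rate <- function(T, params) {
  if (!is_tpc_params(params)) stop("params must be a tpc_params object",
                                   call. = FALSE)
  if (!is.numeric(T) || anyNA(T) || any(!is.finite(T))) {
    stop("T must be finite numeric", call. = FALSE)
  }
  if (params$skew == "left") {
    lrf_left_core(T, params$t_min, params$t_opt, params$t_max, params$r_opt)
  } else {
    lrf_left_core(-T, -params$t_max, -params$t_opt, -params$t_min,
                  params$r_opt)
  }
}

#' Exponential (log-linear) rate curve parameters
#'
#' Parameters of the exponential mass-specific metabolic-rate model:
#' the rate at temperature T is `exp(intercept + slope * T)`, i.e. the
#' natural-log rate is affine in temperature. Intercepts and slopes are
#' typically sex-specific.
#'
#' @param intercept Natural-log rate at 0 degrees C.
#' @param slope Change in natural-log rate per degree C.
#' @return An object of class `exp_curve_params`.
#' @export
exp_curve_params <- function(intercept, slope) {
  if (!is.numeric(intercept) || !is.numeric(slope) ||
      length(intercept) != 1L || length(slope) != 1L ||
      !is.finite(intercept) || !is.finite(slope)) {
    stop("intercept and slope must be single finite numbers", call. = FALSE)
  }
  structure(list(intercept = intercept, slope = slope),
            class = "exp_curve_params")
}

#' Evaluate the exponential metabolic-rate curve
#'
#' @param T Numeric vector of temperatures (degrees C); must be finite.
#' @param params An [exp_curve_params()] object.
#' @return Mass-specific metabolic rate, J g^-1 day^-1; strictly positive.
#' @export
exp_rate <- function(T, params) {
  if (!inherits(params, "exp_curve_params")) {
    stop("params must be an exp_curve_params object", call. = FALSE)
  }
  if (!is.numeric(T) || anyNA(T) || any(!is.finite(T))) {
    stop("T must be finite numeric", call. = FALSE)
  }
  exp(params$intercept + params$slope * T)
}
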