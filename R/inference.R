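#' Posterior draw container with modes and HPD intervals
#'
#' Light-weight container shared by all fitting routines: a draws matrix
#' (one column per parameter on the natural scale) plus per-parameter point
#' summaries. When no explicit modes are supplied the marginal mode is
#' located by a Gaussian kernel density estimate (Silverman bandwidth).
#'
#' @param draws Numeric matrix, one named column per parameter.
#' @param modes Optional named numeric vector of point estimates; defaults
#'   to marginal KDE modes.
#' @param hpdi_mass Probability mass for the summary intervals.
#' @return An object of class `posterior_set`.
#' @export
posterior_set <- function(draws, modes = NULL, hpdi_mass = 0.90) {
  draws <- as.matrix(draws)
  if (is.null(colnames(draws))) stop("draws must have column names",
                                     call. = FALSE)
  if (any(!is.finite(draws))) stop("draws must be finite", call. = FALSE)
  if (is.null(modes)) {
    modes <- apply(draws, 2, density_mode)
  }
  structure(list(draws = draws, modes = modes[colnames(draws)],
                 hpdi_mass = hpdi_mass),
            class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  cat(sprintf("posterior_set: %d draws x %d parameters\n",
              nrow(x$draws), ncol(x$draws)))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.posterior_set <- function(object, mass = object$hpdi_mass, ...) {
  out <- do.call(rbind, lapply(colnames(object$draws), function(p) {
    h <- hpdi(object$draws[, p], mass)
    data.frame(parameter = p, mode = unname(object$modes[p]),
               hpdi_low = h[1], hpdi_high = h[2])
  }))
  flags <- attr(object, "flags")
  if (!is.null(flags)) attr(out, "flags") <- flags
  out
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing the requested posterior mass,
#' computed as the minimal-width window over the sorted draws.
#'
#' @param draws Numeric vector of posterior draws (>= 100 recommended for
#'   stable intervals; constant draws yield a zero-width interval).
#' @param mass Probability mass in (0, 1).
#' @return Numeric `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.90) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("mass must lie strictly inside (0, 1)", call. = FALSE)
  }
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n < 2L) return(c(x[1], x[1]))
  m <- max(2L, ceiling(mass * n))   # points inside the window
  if (m >= n) return(c(x[1], x[n]))
  width <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(width)
  c(x[i], x[i + m - 1L])
}

# Marginal mode by kernel density (Silverman's rule); degenerate draws
# return their common value.
density_mode <- function(x) {
  if (length(x) < 2L || stats::var(x) == 0) return(x[1])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

# ---- priors ----------------------------------------------------------------

#' Default weakly informative priors
#'
#' Prior specifications for the termination and development TPC fits: each
#' entry names a parameter and gives a location/scale pair. Cardinal
#' temperatures get wide normals (SD 10 degrees C) centred on the biology of
#' the process (cold optimum for termination, warm for development);
#' `log_r_opt` gets a wide normal on the log scale; SDs get half-normal(0.5);
#' batch/sex/history intercepts get standard normals. All entries can be
#' overridden by passing a modified list to the fitting functions.
#'
#' @return A named list of `c(location, scale)` pairs.
#' @name default_priors
NULL

#' @rdname default_priors
#' @export
default_termination_priors <- function() {
  list(t_min = c(-5, 10), t_opt = c(0, 10), t_max = c(30, 10),
       log_r_opt = c(log(0.01), 3), sigma = c(0, 0.5),
       batch_effect = c(0, 1), family_sd = c(0, 0.5))
}

#' @rdname default_priors
#' @export
default_development_priors <- function() {
  list(t_min = c(0, 10), t_opt = c(30, 10), t_max = c(40, 10),
       log_r_opt = c(log(0.1), 3), sigma = c(0, 0.5),
       sex_effect = c(0, 1), history_effect = c(0, 1), family_sd = c(0, 0.5))
}

prior_entry <- function(priors, name) {
  p <- priors[[name]]
  if (is.null(p) || length(p) != 2L) {
    stop("prior specification missing entry '", name, "'", call. = FALSE)
  }
  p
}

lp_normal <- function(x, spec) stats::dnorm(x, spec[1], spec[2], log = TRUE)
# half-normal on a nonnegative scale parameter
lp_halfnormal <- function(x, spec) {
  stats::dnorm(x, 0, spec[2], log = TRUE) + log(2)
}

# ---- shared TPC block machinery -------------------------------------------

# theta block (t_min, log gap1, log gap2, log r_opt) -> natural parameters
tpc_block_natural <- function(theta4) {
  t_min <- theta4[1]
  t_opt <- t_min + exp(theta4[2])
  t_max <- t_opt + exp(theta4[3])
  c(t_min = t_min, t_opt = t_opt, t_max = t_max, r_opt = exp(theta4[4]))
}

tpc_block_theta <- function(t_min, t_opt, t_max, r_opt) {
  c(t_min, log(t_opt - t_min), log(t_max - t_opt), log(r_opt))
}

tpc_block_logprior <- function(nat, priors) {
  lp_normal(nat["t_min"], prior_entry(priors, "t_min")) +
    lp_normal(nat["t_opt"], prior_entry(priors, "t_opt")) +
    lp_normal(nat["t_max"], prior_entry(priors, "t_max")) +
    lp_normal(log(nat["r_opt"]), prior_entry(priors, "log_r_opt"))
}

# Robust MAP search: multiple jittered restarts of BFGS with a Nelder-Mead
# fallback; returns the best optimum and its Hessian.
map_optimise <- function(negpost, init, restarts = 3L, maxit = 500L,
                         jitter_sd = NULL) {
  if (is.null(jitter_sd)) jitter_sd <- rep(0.3, length(init))
  best <- NULL
  for (r in seq_len(restarts)) {
    par0 <- if (r == 1L) init else init + stats::rnorm(length(init), 0, jitter_sd)
    fit <- tryCatch(
      stats::optim(par0, negpost, method = "BFGS",
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(par0, negpost, method = "Nelder-Mead",
                     control = list(maxit = 5L * maxit)),
        error = function(e) NULL)
    }
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("MAP optimisation failed from all starts",
                          call. = FALSE)
  H <- tryCatch(stats::optimHess(best$par, negpost), error = function(e) NULL)
  list(par = best$par, value = best$value, hessian = H)
}

# Posterior covariance from the MAP Hessian; regularises a non-PD Hessian
# by ridging.
laplace_sigma <- function(map) {
  p <- length(map$par)
  Sigma <- NULL
  if (!is.null(map$hessian)) {
    H <- (map$hessian + t(map$hessian)) / 2
    for (ridge in c(0, 1e-8, 1e-5, 1e-2)) {
      Hr <- H + diag(ridge, p)
      ev <- tryCatch(eigen(Hr, symmetric = TRUE, only.values = TRUE)$values,
                     error = function(e) -1)
      if (all(ev > 0)) { Sigma <- solve(Hr); break }
    }
  }
  if (is.null(Sigma)) Sigma <- diag(1e-6, p)
  Sigma
}

# Laplace-approximation draws around a MAP point.
laplace_draws <- function(map, n_draws) {
  MASS::mvrnorm(n_draws, map$par, laplace_sigma(map))
}

# Adaptive random-walk Metropolis on the unconstrained scale, started at
# the MAP with a Laplace proposal covariance; the global proposal scale is
# tuned toward ~23% acceptance during burn-in, then frozen. Returns a
# thinned draw matrix.
rwm_draws <- function(logpost, map, n_draws = 2000L, burn = 2000L,
                      thin = 3L) {
  p <- length(map$par)
  Sigma <- laplace_sigma(map) + diag(1e-10, p)
  L <- t(chol(Sigma))
  scale <- 2.38 / sqrt(p)
  th <- map$par
  lp0 <- logpost(th)
  n_iter <- burn + n_draws * thin
  keep <- matrix(NA_real_, n_draws, p)
  acc_window <- 0L
  k <- 0L
  for (i in seq_len(n_iter)) {
    prop <- th + scale * as.vector(L %*% stats::rnorm(p))
    lp1 <- logpost(prop)
    if (is.finite(lp1) && log(stats::runif(1)) < lp1 - lp0) {
      th <- prop; lp0 <- lp1; acc_window <- acc_window + 1L
    }
    if (i <= burn && i %% 100L == 0L) {
      scale <- scale * exp((acc_window / 100 - 0.23))
      acc_window <- 0L
    }
    if (i > burn && (i - burn) %% thin == 0L) {
      k <- k + 1L
      keep[k, ] <- th
    }
  }
  keep[seq_len(k), , drop = FALSE]
}

# ---- termination fit -------------------------------------------------------

#' Fit the diapause-termination TPC to binary transfer trials
#'
#' Maximum a posteriori estimation of the full termination model — per-sex
#' right-skewed LRF parameters and log-scale SDs, a batch-2 intercept when
#' both batches are present, and (optionally) family-by-treatment random
#' intercepts estimated jointly with their SD as penalised parameters. The
#' cardinal temperatures are optimised under an ordered transform
#' (`t_min`, log gaps) so `t_min < t_opt < t_max` holds by construction.
#'
#' The reference engine (`method = "mcmc"`) follows the MAP search with a
#' short adaptive random-walk Metropolis chain (Laplace proposal
#' covariance) and reports marginal kernel-density modes of the draws —
#' marginalising over the weakly identified `t_max` ridge, which a profile
#' (MAP) summary cannot. `method = "laplace"` skips the chain and draws
#' from the Gaussian approximation instead (faster; modes are then the MAP
#' projection).
#'
#' @param trials `termination_trials` data frame with a `temperature`
#'   column (mean treatment temperature per trial).
#' @param priors Prior list as from [default_termination_priors()].
#' @param engine List of engine options: `method` (`"mcmc"` or
#'   `"laplace"`), `n_draws`, `burn`, `thin`, `restarts`, `maxit`.
#' @param seed Integer seed (restart jitter and draw generation).
#' @param include_family Estimate family-by-treatment intercepts (requires
#'   batch-1 trials with family labels; forced off for batch-2-only data).
#' @return A [posterior_set] over natural-scale parameters
#'   (`t_min_male`, ..., `sigma_female`, `batch_effect`, `family_sd`), with
#'   an attached builder used by [posterior_predictive_check()].
#' @export
fit_termination_tpc <- function(trials,
                                priors = default_termination_priors(),
                                engine = list(), seed = 1,
                                include_family = FALSE) {
  validate_termination_trials(trials, need_temperature = TRUE)
  eng <- utils::modifyList(list(method = "mcmc", n_draws = 2000L,
                                restarts = 3L, maxit = 2000L, burn = 3000L,
                                thin = 8L),
                           engine)
  if (length(unique(trials$temperature)) < 3L) {
    stop("need >= 3 distinct temperatures to identify cardinal temperatures",
         call. = FALSE)
  }
  y <- trials$terminated
  if (all(y == 1L)) {
    stop("all trials terminated: termination rate unidentifiable (no ",
         "censored outcomes); extend the design to earlier transfer days",
         call. = FALSE)
  }
  if (all(y == 0L)) {
    stop("no trial terminated: rate unidentifiable; extend the design to ",
         "later transfer days or warmer/cooler treatments", call. = FALSE)
  }
  set.seed(seed)
  has_batch2 <- any(trials$batch == 2L)
  has_batch1 <- any(trials$batch == 1L)
  est_batch <- has_batch1 && has_batch2
  if (include_family && !has_batch1) include_family <- FALSE
  fam_keys <- character(0)
  if (include_family) {
    k <- family_cell_key(trials$family, trials$treatment_id)
    fam_keys <- sort(unique(k[!is.na(k) & trials$batch == 1L]))
    if (!length(fam_keys)) include_family <- FALSE
  }

  idx <- term_theta_index(est_batch, fam_keys)
  build <- function(theta) term_build_params(theta, idx, fam_keys)

  negpost <- function(theta) {
    b <- build(theta)
    if (is.null(b)) return(1e10)
    ll <- trial_log_likelihood(trials, b$params, b$family_intercepts)
    lp <- tpc_block_logprior(b$nat_male, priors) +
      tpc_block_logprior(b$nat_female, priors) +
      lp_halfnormal(b$params$sigma_male, prior_entry(priors, "sigma")) +
      lp_halfnormal(b$params$sigma_female, prior_entry(priors, "sigma"))
    if (est_batch) {
      lp <- lp + lp_normal(b$params$batch_effect,
                           prior_entry(priors, "batch_effect"))
    }
    if (length(fam_keys)) {
      fs <- b$params$family_sd
      lp <- lp + lp_halfnormal(fs, prior_entry(priors, "family_sd")) +
        sum(stats::dnorm(b$family_intercepts, 0, max(fs, 1e-6), log = TRUE))
    }
    val <- -(ll + lp)
    if (!is.finite(val)) 1e10 else val
  }

  init <- term_theta_init(trials, idx, fam_keys)
  jit <- rep(0.3, length(init)); jit[idx$male[1]] <- 1; jit[idx$female[1]] <- 1
  map <- map_optimise(negpost, init, restarts = eng$restarts,
                      maxit = eng$maxit, jitter_sd = jit)
  if (eng$method == "mcmc") {
    th_draws <- rwm_draws(function(th) -negpost(th), map,
                          n_draws = eng$n_draws, burn = eng$burn,
                          thin = eng$thin)
    nat <- t(apply(th_draws, 1, function(th) term_natural_row(th, idx)))
    ps <- posterior_set(nat)          # marginal KDE modes
  } else {
    th_draws <- laplace_draws(map, eng$n_draws)
    nat <- t(apply(th_draws, 1, function(th) term_natural_row(th, idx)))
    ps <- posterior_set(nat, modes = term_natural_row(map$par, idx))
  }
  attr(ps, "param_builder") <- function(row) {
    termination_params(
      tpc_male = tpc_params(row["t_min_male"], row["t_opt_male"],
                            row["t_max_male"], row["r_opt_male"], "right"),
      tpc_female = tpc_params(row["t_min_female"], row["t_opt_female"],
                              row["t_max_female"], row["r_opt_female"],
                              "right"),
      sigma_male = row["sigma_male"], sigma_female = row["sigma_female"],
      batch_effect = if ("batch_effect" %in% names(row)) row[["batch_effect"]] else 0,
      family_sd = if ("family_sd" %in% names(row)) max(row[["family_sd"]], 0) else 0)
  }
  attr(ps, "model") <- "termination"
  ps
}

term_theta_index <- function(est_batch, fam_keys) {
  n <- 10L
  idx <- list(male = 1:4, sig_male = 5L, female = 6:9, sig_female = 10L,
              batch = integer(0), fam = integer(0), lfam_sd = integer(0))
  if (est_batch) { n <- n + 1L; idx$batch <- n }
  if (length(fam_keys)) {
    idx$fam <- n + seq_along(fam_keys)
    n <- n + length(fam_keys)
    idx$lfam_sd <- n + 1L
    n <- n + 1L
  }
  idx$n <- n
  idx
}

term_build_params <- function(theta, idx, fam_keys) {
  nm <- tpc_block_natural(theta[idx$male])
  nf <- tpc_block_natural(theta[idx$female])
  if (!all(is.finite(c(nm, nf)))) return(NULL)
  params <- tryCatch(termination_params(
    tpc_male = tpc_params(nm["t_min"], nm["t_opt"], nm["t_max"],
                          nm["r_opt"], "right"),
    tpc_female = tpc_params(nf["t_min"], nf["t_opt"], nf["t_max"],
                            nf["r_opt"], "right"),
    sigma_male = exp(theta[idx$sig_male]),
    sigma_female = exp(theta[idx$sig_female]),
    batch_effect = if (length(idx$batch)) theta[idx$batch] else 0,
    family_sd = if (length(idx$lfam_sd)) exp(theta[idx$lfam_sd]) else 0),
    error = function(e) NULL)
  if (is.null(params)) return(NULL)
  fi <- NULL
  if (length(fam_keys)) fi <- stats::setNames(theta[idx$fam], fam_keys)
  list(params = params, family_intercepts = fi,
       nat_male = nm, nat_female = nf)
}

# Crude data-driven starting point: r_opt from the day by which half of the
# fastest treatment's transfers had terminated.
term_theta_init <- function(trials, idx, fam_keys) {
  theta <- numeric(idx$n)
  for (sx in c("male", "female")) {
    tr <- trials[trials$sex == sx, ]
    lropt <- -log(200)
    if (nrow(tr) && any(tr$terminated == 1L)) {
      frac <- tapply(tr$terminated, tr$treatment_id, mean)
      best <- names(frac)[which.max(frac)]
      trb <- tr[tr$treatment_id == best, ]
      trb <- trb[order(trb$transfer_day), ]
      cum <- cumsum(trb$terminated) / sum(trb$terminated)
      d50 <- trb$transfer_day[which(cum >= 0.5)[1]]
      if (is.finite(d50) && d50 > 0) lropt <- -log(d50)
    }
    block <- c(-5, log(5), log(30), lropt)
    if (sx == "male") {
      theta[idx$male] <- block; theta[idx$sig_male] <- log(0.2)
    } else {
      theta[idx$female] <- block; theta[idx$sig_female] <- log(0.2)
    }
  }
  if (length(idx$batch)) theta[idx$batch] <- 0
  if (length(idx$lfam_sd)) theta[idx$lfam_sd] <- log(0.1)
  theta
}

term_natural_row <- function(theta, idx) {
  nm <- tpc_block_natural(theta[idx$male])
  nf <- tpc_block_natural(theta[idx$female])
  out <- c(t_min_male = unname(nm["t_min"]), t_opt_male = unname(nm["t_opt"]),
           t_max_male = unname(nm["t_max"]), r_opt_male = unname(nm["r_opt"]),
           sigma_male = exp(theta[idx$sig_male]),
           t_min_female = unname(nf["t_min"]),
           t_opt_female = unname(nf["t_opt"]),
           t_max_female = unname(nf["t_max"]),
           r_opt_female = unname(nf["r_opt"]),
           sigma_female = exp(theta[idx$sig_female]))
  if (length(idx$batch)) out <- c(out, batch_effect = theta[idx$batch])
  if (length(idx$lfam_sd)) out <- c(out, family_sd = exp(theta[idx$lfam_sd]))
  out
}

# ---- development fit -------------------------------------------------------

#' Fit the postdiapause development TPC to individual rates
#'
#' MAP estimation (with Laplace draws) of the left-skewed LRF development
#' model from individual development times: sex-averaged cardinal
#' temperatures and peak rate, centred sex intercept, 4-degree-C
#' winter-history intercept (estimated only when both histories occur in the
#' data), and the lognormal observation SD.
#'
#' @param records Development data frame with columns `pupa_id`, `sex`,
#'   `family`, `winter_history`, `postwinter_temperature`,
#'   `development_time`.
#' @param priors Prior list as from [default_development_priors()].
#' @param engine Engine options (`n_draws`, `restarts`, `maxit`).
#' @param seed Integer seed.
#' @return A [posterior_set] over `t_min`, `t_opt`, `t_max`, `r_opt`,
#'   `sex_effect`, `history_effect`, `sigma_dev`. Single-sex inputs leave
#'   the sex effect prior-dominated; a note is attached under
#'   `attr(, "flags")`.
#' @export
fit_development_tpc <- function(records,
                                priors = default_development_priors(),
                                engine = list(), seed = 1) {
  validate_development_records(records)
  eng <- utils::modifyList(list(method = "laplace", n_draws = 1000L,
                                restarts = 3L, maxit = 1000L, burn = 1000L,
                                thin = 2L),
                           engine)
  temps <- unique(records$postwinter_temperature)
  if (length(temps) < 4L) {
    stop("need >= 4 distinct postwinter temperatures", call. = FALSE)
  }
  set.seed(seed)
  y <- log(1 / records$development_time)
  Tv <- records$postwinter_temperature
  sex_sign <- ifelse(records$sex == "male", 0.5,
                     ifelse(records$sex == "female", -0.5, 0))
  both_hist <- all(c("2C", "4C") %in% records$winter_history)
  hist_ind <- as.numeric(records$winter_history == "4C")
  single_sex <- length(unique(records$sex)) == 1L

  # theta: t_min, log gap1, log gap2, log r_opt, sex_effect, [history], log sigma
  n_par <- 6L + as.integer(both_hist)
  i_hist <- if (both_hist) 6L else integer(0)
  i_sig <- n_par

  negpost <- function(theta) {
    nat <- tpc_block_natural(theta[1:4])
    if (!all(is.finite(nat)) || nat["t_min"] >= nat["t_opt"]) return(1e10)
    tpc <- tryCatch(tpc_params(nat["t_min"], nat["t_opt"], nat["t_max"],
                               nat["r_opt"], "left"),
                    error = function(e) NULL)
    if (is.null(tpc)) return(1e10)
    mu <- lrf_rate(Tv, tpc)
    if (any(mu <= 0)) return(1e10)
    sx <- theta[5]
    hx <- if (both_hist) theta[i_hist] else 0
    sigma <- exp(theta[i_sig])
    lmu <- log(mu) + sx * sex_sign + hx * hist_ind
    ll <- sum(stats::dnorm(y, lmu, sigma, log = TRUE))
    lp <- tpc_block_logprior(nat, priors) +
      lp_normal(sx, prior_entry(priors, "sex_effect")) +
      lp_halfnormal(sigma, prior_entry(priors, "sigma"))
    if (both_hist) lp <- lp + lp_normal(hx, prior_entry(priors, "history_effect"))
    val <- -(ll + lp)
    if (!is.finite(val)) 1e10 else val
  }

  r_guess <- max(exp(y))
  init <- c(tpc_block_theta(min(Tv) - 2, temps[which.max(tapply(y, Tv, mean))],
                            max(Tv) + 3, r_guess),
            0, if (both_hist) 0, log(0.2))
  map <- map_optimise(negpost, init, restarts = eng$restarts,
                      maxit = eng$maxit)
  th <- if (eng$method == "mcmc") {
    rwm_draws(function(x) -negpost(x), map, n_draws = eng$n_draws,
              burn = eng$burn, thin = eng$thin)
  } else {
    laplace_draws(map, eng$n_draws)
  }
  to_nat <- function(theta) {
    nat <- tpc_block_natural(theta[1:4])
    c(t_min = unname(nat["t_min"]), t_opt = unname(nat["t_opt"]),
      t_max = unname(nat["t_max"]), r_opt = unname(nat["r_opt"]),
      sex_effect = theta[5],
      history_effect = if (both_hist) theta[i_hist] else 0,
      sigma_dev = exp(theta[i_sig]))
  }
  nat <- t(apply(th, 1, to_nat))
  ps <- if (eng$method == "mcmc") posterior_set(nat) else
    posterior_set(nat, modes = to_nat(map$par))
  attr(ps, "model") <- "development"
  if (single_sex) {
    attr(ps, "flags") <- "single-sex data: sex_effect is prior-dominated"
  }
  if (!both_hist) {
    attr(ps, "flags") <- c(attr(ps, "flags"),
                           "single winter history: history_effect fixed at 0")
  }
  ps
}

# ---- posterior predictive checks ------------------------------------------

#' Default posterior-predictive statistics for termination trials
#'
#' Per-treatment total termination counts plus the mean transfer day among
#' terminated trials (a timing/dispersion summary).
#'
#' @return Named list of functions mapping a trials table to named scalars.
#' @export
default_ppc_statistics <- function() {
  list(
    total_terminations = function(tr) {
      tapply(tr$terminated, tr$treatment_id, sum)
    },
    mean_day_terminated = function(tr) {
      d <- tr$transfer_day[tr$terminated == 1L]
      c(all = if (length(d)) mean(d) else NA_real_)
    }
  )
}

#' Posterior predictive check for the termination model
#'
#' Simulates replicate outcome vectors for the observed trial design from
#' random posterior draws and compares chosen statistics of the replicates
#' with the observed data. The tail probability is the fraction of
#' replicates with statistic value less than or equal to the observed value;
#' values near 0 or 1 flag misfit.
#'
#' @param posterior A [posterior_set] from [fit_termination_tpc()] (draws
#'   required; a MAP-only set is an error).
#' @param trials The observed trials table (with `temperature`).
#' @param statistics Named list of statistic functions; an empty list yields
#'   an empty table.
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed.
#' @return Data frame with columns `statistic`, `observed`, `tail_prob`.
#' @export
posterior_predictive_check <- function(posterior, trials,
                                       statistics = default_ppc_statistics(),
                                       n_rep = 200, seed = 1) {
  if (!inherits(posterior, "posterior_set") || nrow(posterior$draws) < 2L) {
    stop("posterior draws are required for predictive checks", call. = FALSE)
  }
  builder <- attr(posterior, "param_builder")
  if (is.null(builder)) {
    stop("posterior lacks a parameter builder; fit with fit_termination_tpc",
         call. = FALSE)
  }
  if (!length(statistics)) {
    return(data.frame(statistic = character(0), observed = numeric(0),
                      tail_prob = numeric(0)))
  }
  set.seed(seed)
  eval_stats <- function(tr) {
    unlist(lapply(names(statistics), function(nm) {
      v <- statistics[[nm]](tr)
      stats::setNames(as.numeric(v),
                      if (length(v) > 1L || !is.null(names(v)))
                        paste(nm, names(v), sep = ".") else nm)
    }))
  }
  obs <- eval_stats(trials)
  rows <- sample.int(nrow(posterior$draws), n_rep, replace = TRUE)
  rep_mat <- matrix(NA_real_, n_rep, length(obs),
                    dimnames = list(NULL, names(obs)))
  for (r in seq_len(n_rep)) {
    params <- builder(posterior$draws[rows[r], ])
    p <- trial_probabilities(trials, params)
    tr <- trials
    tr$terminated <- stats::rbinom(nrow(trials), 1L, p)
    rep_mat[r, ] <- eval_stats(tr)
  }
  tail_prob <- vapply(seq_along(obs), function(j) {
    mean(rep_mat[, j] <= obs[j], na.rm = TRUE)
  }, numeric(1))
  data.frame(statistic = names(obs), observed = unname(obs),
             tail_prob = tail_prob, row.names = NULL)
}
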