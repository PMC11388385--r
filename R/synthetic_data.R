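#' Configuration of a synthetic overwintering study
#'
#' Bundles the true parameter values and the sampling design used to
#' generate synthetic data with known ground truth. The defaults reproduce
#' the reference *P. napi* study design: a first experimental batch split
#' across four constant winter treatments (2, 4, 8, 15 degrees C) sampled
#' three pupae per sex every 4th day from day 60 to day 240 (slow treatments
#' extended to day 300 with 16-day spacing after day 200), a second batch at
#' -6 and 1 degrees C sampled one pupa per sex daily from day 80 to 185, six
#' families allocated round-robin in batch 1, and four fluctuating
#' square-wave validation regimes.
#'
#' @param term_params True [termination_params()].
#' @param dev_params True [development_params()].
#' @param metab_params True metabolic parameters
#'   (list as [pnapi_metabolic_params()]).
#' @param batch1_treatments Named list of constant winter temperatures for
#'   batch 1.
#' @param batch2_treatments Named list for batch 2.
#' @param slow_treatments Treatment ids (or regime descriptions) whose
#'   sampling is extended to day 300 with 16-day spacing after day 200.
#' @param batch1_schedule,batch2_schedule Lists with `start`, `end`, `step`,
#'   `per_sex` (batch 1 also `slow_switch`, `slow_step`, `slow_end`).
#' @param n_families Number of outbred families in batch 1.
#' @param dev_design List: postwinter `temperatures`, cohort sizes `n_2C`
#'   and `n_4C`.
#' @param resp_design List: `n_per_treatment`, measurement `ages` (days),
#'   individual and treatment-by-age intercept SDs, `mean_mass` (g), `rq`
#'   (respiratory quotient used to split the rate into gas volumes).
#' @param seed Integer seed; mandatory for any stochastic output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(term_params = pnapi_termination_params(),
                             dev_params = pnapi_development_params(),
                             metab_params = pnapi_metabolic_params(),
                             batch1_treatments = list(`2C` = 2, `4C` = 4,
                                                      `8C` = 8, `15C` = 15),
                             batch2_treatments = list(`-6C` = -6, `1C` = 1),
                             slow_treatments = c("15C", "22:2 h 15:0 degC"),
                             batch1_schedule = list(start = 60, end = 240,
                                                    step = 4, per_sex = 3,
                                                    slow_switch = 200,
                                                    slow_step = 16,
                                                    slow_end = 300),
                             batch2_schedule = list(start = 80, end = 185,
                                                    step = 1, per_sex = 1),
                             n_families = 6,
                             dev_design = list(
                               temperatures = c(10, 15, 20, 25, 28, 30, 33),
                               n_2C = 65, n_4C = 99),
                             resp_design = list(n_per_treatment = 20,
                                                ages = c(30, 90, 150),
                                                ind_sd = 0.1, cell_sd = 0.1,
                                                mean_mass = 0.1, rq = 0.8),
                             seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("an explicit integer seed is mandatory", call. = FALSE)
  }
  for (sch in list(batch1_schedule, batch2_schedule)) {
    if (sch$end < sch$start) stop("schedule end before start", call. = FALSE)
    if (sch$step <= 0 || sch$per_sex < 0) {
      stop("schedule step and per_sex must be positive", call. = FALSE)
    }
  }
  structure(list(term_params = term_params, dev_params = dev_params,
                 metab_params = metab_params,
                 batch1_treatments = batch1_treatments,
                 batch2_treatments = batch2_treatments,
                 slow_treatments = slow_treatments,
                 batch1_schedule = batch1_schedule,
                 batch2_schedule = batch2_schedule,
                 n_families = as.integer(n_families),
                 dev_design = dev_design, resp_design = resp_design,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Transfer schedule for one treatment: one row per scheduled pupa, ordered
# by day, then sex, then replicate (the generator's fixed RNG order).
make_schedule <- function(config, batch, slow = FALSE) {
  sch <- if (batch == 1L) config$batch1_schedule else config$batch2_schedule
  days <- seq(sch$start, sch$end, by = sch$step)
  if (batch == 1L && slow) {
    days <- c(seq(sch$start, sch$slow_switch, by = sch$step),
              seq(sch$slow_switch + sch$slow_step, sch$slow_end,
                  by = sch$slow_step))
  }
  data.frame(
    transfer_day = rep(days, each = 2L * sch$per_sex),
    sex = rep(rep(c("male", "female"), each = sch$per_sex), length(days)),
    stringsAsFactors = FALSE)
}

# Core trial generator for one treatment. progress_at(day, sex) must return
# accumulated geometric-mean progress including the batch offset.
gen_treatment_trials <- function(config, treatment_id, batch, progress_at,
                                 family_intercepts = NULL,
                                 id_prefix = treatment_id) {
  slow <- treatment_id %in% config$slow_treatments
  sched <- make_schedule(config, batch, slow)
  n <- nrow(sched)
  if (batch == 1L) {
    fam <- rep_len(paste0("F", seq_len(config$n_families)), n)
  } else {
    fam <- rep(NA_character_, n)
  }
  sig <- ifelse(sched$sex == "male", config$term_params$sigma_male,
                config$term_params$sigma_female)
  m <- exp(stats::rnorm(n, 0, sig))
  fam_off <- rep(0, n)
  if (!is.null(family_intercepts) && batch == 1L) {
    key <- family_cell_key(fam, treatment_id)
    hit <- key %in% names(family_intercepts)
    fam_off[hit] <- family_intercepts[key[hit]]
  }
  S <- vapply(seq_len(n), function(i) {
    progress_at(sched$transfer_day[i], sched$sex[i])
  }, numeric(1))
  terminated <- as.integer(m * exp(fam_off) * S >= 1)
  data.frame(
    pupa_id = sprintf("%s_b%d_%04d", id_prefix, batch, seq_len(n)),
    sex = sched$sex, batch = batch, family = fam,
    treatment_id = treatment_id, transfer_day = sched$transfer_day,
    terminated = terminated, stringsAsFactors = FALSE)
}

draw_family_intercepts <- function(config, treatment_ids) {
  if (config$term_params$family_sd <= 0 || config$n_families < 1L) {
    return(NULL)
  }
  keys <- as.vector(outer(paste0("F", seq_len(config$n_families)),
                          treatment_ids,
                          function(f, tr) paste(f, tr, sep = ":")))
  stats::setNames(stats::rnorm(length(keys), 0,
                               config$term_params$family_sd), keys)
}

#' Generate a complete constant-temperature termination study
#'
#' Simulates one binary termination trial per scheduled transfer in every
#' constant winter treatment of both batches: each pupa draws a single
#' lognormal rate multiplier, accumulates daily progress
#' `multiplier x mu(T)` (times the batch-2 intercept and its family
#' intercept where applicable), and is recorded as terminated when
#' accumulated progress at its transfer day reaches 1. Batch-1 pupae carry
#' family labels allocated round-robin across the configured families.
#'
#' @param config A [synthetic_config()].
#' @param batches Which batches to generate (default both).
#' @return List with `trials` (a `termination_trials` data frame including
#'   the `temperature` column) and `truth` (true parameters, drawn family
#'   intercepts and the config).
#' @export
generate_termination_study <- function(config, batches = c(1L, 2L)) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tp <- config$term_params
  fam_int <- if (1L %in% batches) {
    draw_family_intercepts(config, names(config$batch1_treatments))
  } else NULL
  out <- list()
  if (1L %in% batches) {
    for (id in names(config$batch1_treatments)) {
      Tc <- config$batch1_treatments[[id]]
      prog <- function(day, sex) {
        lrf_rate(Tc, term_tpc_for_sex(tp, sex)) * day
      }
      tr <- gen_treatment_trials(config, id, 1L, prog, fam_int)
      tr$temperature <- Tc
      out[[length(out) + 1L]] <- tr
    }
  }
  if (2L %in% batches) {
    for (id in names(config$batch2_treatments)) {
      Tc <- config$batch2_treatments[[id]]
      prog <- function(day, sex) {
        lrf_rate(Tc, term_tpc_for_sex(tp, sex)) * day *
          exp(tp$batch_effect)
      }
      tr <- gen_treatment_trials(config, id, 2L, prog)
      tr$temperature <- Tc
      out[[length(out) + 1L]] <- tr
    }
  }
  trials <- do.call(rbind, out)
  class(trials) <- c("termination_trials", class(trials))
  list(trials = trials,
       truth = list(params = tp, family_intercepts = fam_int,
                    config = config))
}

#' Generate a fluctuating-regime validation cohort
#'
#' Same observation process as [generate_termination_study()], but
#' accumulated progress follows a fluctuating thermal regime via rate
#' summation. The cohort uses the batch-1 transfer schedule (extended when
#' the regime is flagged slow in the config).
#'
#' @param config A [synthetic_config()].
#' @param regime A [thermal_regime], or a square-wave spec string accepted
#'   by [square_wave_regime()], or a single constant temperature.
#' @param treatment_id Label for the cohort; defaults to the regime
#'   description.
#' @return List with `trials` (temperature column is `NA` for genuinely
#'   fluctuating regimes) and `truth`.
#' @export
generate_fluctuating_cohort <- function(config, regime, treatment_id = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tp <- config$term_params
  const_T <- NA_real_
  if (is.character(regime)) regime_spec <- regime else regime_spec <- NULL
  if (is.numeric(regime) && length(regime) == 1L) {
    const_T <- regime
    if (is.null(treatment_id)) treatment_id <- sprintf("%gC", regime)
  } else {
    if (!is.null(regime_spec)) {
      if (is.null(treatment_id)) treatment_id <- regime_spec
    } else {
      stopifnot(inherits(regime, "thermal_regime"))
      if (is.null(treatment_id)) treatment_id <- regime$description
    }
  }
  fam_int <- draw_family_intercepts(config, treatment_id)
  slow <- treatment_id %in% config$slow_treatments
  sch <- config$batch1_schedule
  horizon <- if (slow) sch$slow_end else sch$end
  if (!is.na(const_T)) {
    S_by_sex <- lapply(c(male = "male", female = "female"), function(sx) {
      lrf_rate(const_T, term_tpc_for_sex(tp, sx)) * seq_len(horizon)
    })
  } else {
    if (!is.null(regime_spec)) {
      regime <- square_wave_regime(regime_spec, days = horizon)
    }
    S_by_sex <- lapply(c(male = "male", female = "female"), function(sx) {
      accumulated_progress(regime, term_tpc_for_sex(tp, sx), horizon)
    })
  }
  prog <- function(day, sex) S_by_sex[[sex]][day]
  tr <- gen_treatment_trials(config, treatment_id, 1L, prog, fam_int)
  tr$temperature <- const_T
  class(tr) <- c("termination_trials", class(tr))
  list(trials = tr,
       truth = list(params = tp, family_intercepts = fam_int,
                    config = config, regime = regime))
}

#' Generate synthetic postdiapause development records
#'
#' Individual development rates drawn lognormally around the left-skewed
#' LRF mean with centred sex effect, 4-degree-C winter-history elevation and
#' optional family intercepts; development time is the reciprocal rate.
#' Pupae are allocated round-robin across postwinter temperatures, sexes and
#' families. Temperatures outside the TPC support are excluded with a
#' warning (no development would ever complete there).
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (a development data frame) and `truth`.
#' @export
generate_development_records <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  dp <- config$dev_params
  temps <- config$dev_design$temperatures
  ok <- lrf_rate(temps, dp$tpc) > 0
  if (any(!ok)) {
    warning("excluding postwinter temperature(s) outside the TPC support: ",
            paste(temps[!ok], collapse = ", "), call. = FALSE)
    temps <- temps[ok]
  }
  blocks <- list()
  fam_pool <- paste0("F", seq_len(max(config$n_families, 1L)))
  fam_int <- if (dp$family_sd > 0) {
    stats::setNames(stats::rnorm(length(fam_pool), 0, dp$family_sd), fam_pool)
  } else NULL
  for (hist in c("2C", "4C")) {
    n <- config$dev_design[[paste0("n_", hist)]]
    if (is.null(n) || n < 1L) next
    Tv <- rep_len(temps, n)
    sex <- rep_len(c("male", "female"), n)
    fam <- rep_len(fam_pool, n)
    lmu <- vapply(seq_len(n), function(i) {
      development_rate_mean(Tv[i], sex[i], hist, dp)
    }, numeric(1))
    if (!is.null(fam_int)) lmu <- lmu + fam_int[fam]
    rate <- exp(lmu + stats::rnorm(n, 0, dp$sigma_dev))
    blocks[[hist]] <- data.frame(
      pupa_id = sprintf("dev_%s_%03d", hist, seq_len(n)),
      sex = sex, family = fam, winter_history = hist,
      postwinter_temperature = Tv, development_time = 1 / rate,
      stringsAsFactors = FALSE)
  }
  if (!length(blocks)) {
    records <- data.frame(pupa_id = character(0), sex = character(0),
                          family = character(0),
                          winter_history = character(0),
                          postwinter_temperature = numeric(0),
                          development_time = numeric(0))
  } else {
    records <- do.call(rbind, blocks)
    rownames(records) <- NULL
  }
  list(records = records,
       truth = list(params = dp, family_intercepts = fam_int,
                    config = config))
}

#' Generate synthetic respirometry records
#'
#' Repeated-measures gas-exchange records: each pupa in each constant
#' batch-1 treatment is measured at the configured pupal ages. Log rates are
#' affine in temperature with sex-specific intercept and slope, an
#' individual random intercept, a treatment-by-age cell intercept and
#' lognormal observation noise. The simulated mass-specific rate is split
#' back into `v_o2`/`v_co2` using the configured respiratory quotient, so
#' [metabolic_rate_joules()] recovers it exactly.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (a respirometry data frame) and `truth`.
#' @export
generate_respirometry_records <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  mp <- config$metab_params
  rd <- config$resp_design
  treatments <- config$batch1_treatments
  rows <- list()
  denom <- 16 + 5.164 * rd$rq
  for (id in names(treatments)) {
    Tc <- treatments[[id]]
    n <- rd$n_per_treatment
    sex <- rep_len(c("male", "female"), n)
    ind_id <- sprintf("resp_%s_%03d", id, seq_len(n))
    u_ind <- stats::rnorm(n, 0, rd$ind_sd)
    mass <- exp(stats::rnorm(n, log(rd$mean_mass), 0.1))
    v_cell <- stats::setNames(stats::rnorm(length(rd$ages), 0, rd$cell_sd),
                              as.character(rd$ages))
    for (a in rd$ages) {
      lmu <- vapply(seq_len(n), function(i) {
        pc <- if (sex[i] == "male") mp$male else mp$female
        pc$intercept + pc$slope * Tc
      }, numeric(1))
      rate <- exp(lmu + u_ind + v_cell[[as.character(a)]] +
                    stats::rnorm(n, 0, mp$sigma_obs))
      v_o2 <- rate * mass / denom
      rows[[length(rows) + 1L]] <- data.frame(
        pupa_id = ind_id, sex = sex, mass = mass, temperature = Tc,
        v_o2 = v_o2, v_co2 = rd$rq * v_o2, age_days = a,
        treatment_id = id, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records,
       truth = list(params = mp, config = config))
}
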