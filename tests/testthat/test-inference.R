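test_that("hpdi finds the shortest mass interval", {
  expect_equal(hpdi(rep(2.5, 500), 0.9), c(2.5, 2.5))
  # endpoint estimates are noisy (~0.02 SD at n = 1e5), so compare their
  # average over seeds against the closed-form normal quantiles
  hs <- vapply(1:10, function(s) {
    set.seed(s)
    hpdi(rnorm(1e5), 0.90)
  }, numeric(2))
  expect_lt(abs(mean(hs[1, ]) + 1.645), 0.03)
  expect_lt(abs(mean(hs[2, ]) - 1.645), 0.03)
  set.seed(11)
  z <- rnorm(1e5)
  h <- hpdi(z, 0.90)
  expect_equal(mean(z >= h[1] & z <= h[2]), 0.9, tolerance = 1e-3)
  # skewed draws: HPDI beats the equal-tailed interval
  x <- exp(rnorm(2e4, 0, 1))
  h <- hpdi(x, 0.9)
  eq <- unname(quantile(x, c(0.05, 0.95)))
  expect_lt(diff(h), eq[2] - eq[1])
  expect_error(hpdi(z, 1.2), "inside")
  expect_error(hpdi(z, 0), "inside")
})

test_that("termination fit rejects unidentifiable designs", {
  cfg <- small_config(seed = 31)
  st <- generate_termination_study(cfg)
  two_t <- st$trials[st$trials$treatment_id %in% c("2C", "4C"), ]
  expect_error(fit_termination_tpc(two_t), "distinct temperatures")
  all1 <- st$trials; all1$terminated <- 1L
  expect_error(fit_termination_tpc(all1), "unidentifiable")
  all0 <- st$trials; all0$terminated <- 0L
  expect_error(fit_termination_tpc(all0), "unidentifiable")
})

test_that("Laplace termination fit recovers parameters and is reproducible", {
  cfg <- small_config(seed = 301)
  st <- generate_termination_study(cfg)
  ps <- fit_termination_tpc(st$trials, seed = 2,
                            engine = list(method = "laplace",
                                          n_draws = 500, restarts = 2))
  expect_s3_class(ps, "posterior_set")
  expect_lt(abs(ps$modes[["r_opt_male"]] / 0.00746 - 1), 0.15)
  expect_lt(abs(ps$modes[["sigma_male"]] - 0.240), 0.08)
  s <- summary(ps)
  expect_true(all(s$hpdi_low <= s$hpdi_high))
  # same data, independent seeds: HPDIs overlap on every parameter
  ps2 <- fit_termination_tpc(st$trials, seed = 77,
                             engine = list(method = "laplace",
                                           n_draws = 500, restarts = 2))
  s2 <- summary(ps2)
  expect_true(all(pmax(s$hpdi_low, s2$hpdi_low) <=
                    pmin(s$hpdi_high, s2$hpdi_high)))
  # exact reproducibility under identical seed and settings
  ps3 <- fit_termination_tpc(st$trials, seed = 2,
                             engine = list(method = "laplace",
                                           n_draws = 500, restarts = 2))
  expect_identical(ps$draws, ps3$draws)
})

test_that("MAP approaches the truth on large samples (flat-ish priors)", {
  cfg <- synthetic_config(
    seed = 311,
    batch1_treatments = list(`2C` = 2, `4C` = 4, `8C` = 8, `15C` = 15),
    batch2_treatments = list(),
    batch1_schedule = list(start = 60, end = 240, step = 4, per_sex = 14,
                           slow_switch = 200, slow_step = 16,
                           slow_end = 300))
  st <- generate_termination_study(cfg)
  expect_gt(nrow(st$trials), 5000)
  ps <- fit_termination_tpc(st$trials, seed = 3,
                            engine = list(method = "laplace",
                                          n_draws = 200, restarts = 2))
  expect_lt(abs(ps$modes[["r_opt_male"]] / 0.00746 - 1), 0.05)
  expect_lt(abs(ps$modes[["r_opt_female"]] / 0.00634 - 1), 0.05)
  expect_lt(abs(ps$modes[["sigma_male"]] / 0.240 - 1), 0.05)
  expect_lt(abs(ps$modes[["sigma_female"]] / 0.208 - 1), 0.05)
})

test_that("batch-2-only data exclude the family variance (dummy nullification)", {
  cfg <- synthetic_config(seed = 32, batch1_treatments = list(),
                          batch2_treatments = list(`-6C` = -6, `1C` = 1,
                                                   `4C` = 4))
  st <- generate_termination_study(cfg, batches = 2L)
  ps <- fit_termination_tpc(st$trials, seed = 1, include_family = TRUE,
                            engine = list(method = "laplace", n_draws = 100,
                                          restarts = 1))
  expect_false("family_sd" %in% colnames(ps$draws))
  expect_false("batch_effect" %in% colnames(ps$draws))
})

test_that("near-deterministic data pin the termination day per treatment", {
  sharp <- ref_term
  sharp$sigma_male <- 0.01
  sharp$sigma_female <- 0.01
  cfg <- synthetic_config(
    seed = 33, term_params = sharp,
    batch1_treatments = list(`2C` = 2, `4C` = 4, `8C` = 8),
    batch2_treatments = list(),
    batch1_schedule = list(start = 60, end = 240, step = 1, per_sex = 2,
                           slow_switch = 200, slow_step = 16,
                           slow_end = 300))
  st <- generate_termination_study(cfg)
  ps <- fit_termination_tpc(st$trials, seed = 1,
                            engine = list(method = "laplace", n_draws = 100,
                                          restarts = 2))
  for (Tc in c(2, 4, 8)) {
    for (sx in c("male", "female")) {
      tpc <- tpc_params(ps$modes[[paste0("t_min_", sx)]],
                        ps$modes[[paste0("t_opt_", sx)]],
                        ps$modes[[paste0("t_max_", sx)]],
                        ps$modes[[paste0("r_opt_", sx)]], "right")
      truth_tpc <- if (sx == "male") ref_term$tpc_male else
        ref_term$tpc_female
      expect_lt(abs(1 / lrf_rate(Tc, tpc) - 1 / lrf_rate(Tc, truth_tpc)),
                1.0)
    }
  }
})

test_that("development fit recovers noiseless data and flags single-sex input", {
  quiet <- development_params(dev_tpc, sex_effect = 0.0927,
                              history_effect = 0.060, sigma_dev = 1e-4)
  cfg <- small_config(seed = 34, dev_params = quiet)
  dv <- generate_development_records(cfg)
  ps <- fit_development_tpc(dv$records, seed = 1,
                            engine = list(n_draws = 100, restarts = 2))
  expect_lt(abs(ps$modes[["t_opt"]] - 29.6), 0.2)
  expect_lt(abs(ps$modes[["t_min"]] - 1.99), 0.5)
  expect_lt(abs(ps$modes[["r_opt"]] / 0.152 - 1), 0.005)
  # single-sex input: flagged, sex effect prior-dominated
  dv2 <- generate_development_records(small_config(seed = 35))
  fem <- dv2$records[dv2$records$sex == "female", ]
  psf <- fit_development_tpc(fem, seed = 1,
                             engine = list(n_draws = 100, restarts = 1))
  expect_match(paste(attr(psf, "flags"), collapse = " "), "single-sex")
  expect_error(
    fit_development_tpc(fem[fem$postwinter_temperature %in% c(10, 20, 30), ]),
    "distinct")
})

test_that("posterior predictive checks separate well- and mis-specified data", {
  cfg <- small_config(seed = 36)
  st <- generate_termination_study(cfg)
  ps <- fit_termination_tpc(st$trials, seed = 1,
                            engine = list(method = "laplace", n_draws = 300,
                                          restarts = 2))
  good <- posterior_predictive_check(ps, st$trials, n_rep = 200, seed = 4)
  expect_true(all(c("statistic", "observed", "tail_prob") %in% names(good)))
  expect_true(all(good$tail_prob >= 0.01 & good$tail_prob <= 0.99))
  # misspecified outcomes: coin-flip terminations regardless of day
  bad <- st$trials
  set.seed(9)
  bad$terminated <- rbinom(nrow(bad), 1L, 0.5)
  flagged <- posterior_predictive_check(ps, bad, n_rep = 200, seed = 4)
  expect_true(any(flagged$tail_prob <= 0.01 | flagged$tail_prob >= 0.99))
  # empty statistic set and MAP-only posteriors
  empty <- posterior_predictive_check(ps, st$trials, statistics = list())
  expect_identical(nrow(empty), 0L)
  map_only <- posterior_set(ps$draws[1, , drop = FALSE])
  expect_error(posterior_predictive_check(map_only, st$trials), "draws")
})
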