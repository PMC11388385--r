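test_that("transfer schedules reproduce the stated design arithmetic", {
  cfg <- small_config(seed = 41)
  st <- generate_termination_study(cfg)
  counts <- table(st$trials$treatment_id)
  # 3 per sex every 4 d, day 60..240: ((240-60)/4 + 1) * 6 = 276
  for (id in c("2C", "4C", "8C")) expect_identical(unname(counts[id]), 276L)
  # slow treatment: 4-day grid to day 200, then 16-day grid to day 300
  expect_identical(unname(counts["15C"]), 252L)
  expect_identical(max(st$trials$transfer_day[st$trials$treatment_id == "15C"]),
                   296)
  # batch 2: one per sex daily, day 80..185
  cfg2 <- synthetic_config(seed = 41)
  st2 <- generate_termination_study(cfg2)
  b2 <- st2$trials[st2$trials$batch == 2L, ]
  expect_identical(unname(table(b2$treatment_id)[["1C"]]), 212L)
  expect_true(all(is.na(b2$family)))
  expect_true(all(!is.na(st2$trials$family[st2$trials$batch == 1L])))
  expect_error(synthetic_config(seed = 1,
                                batch1_schedule = list(start = 100, end = 50,
                                                       step = 4, per_sex = 3,
                                                       slow_switch = 200,
                                                       slow_step = 16,
                                                       slow_end = 300)),
               "end before start")
  expect_error(synthetic_config(), "seed")
})

test_that("same seed and config give byte-identical tables", {
  a <- generate_termination_study(small_config(seed = 42))$trials
  b <- generate_termination_study(small_config(seed = 42))$trials
  expect_identical(a, b)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_termination_trials(a, fa); write_termination_trials(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  c2 <- generate_termination_study(small_config(seed = 43))$trials
  expect_false(identical(a$terminated, c2$terminated))
})

test_that("ground truth round-trips through the config reader", {
  cfg <- small_config(seed = 44)
  st <- generate_termination_study(cfg)
  truth <- list(seed = cfg$seed,
                sigma_male = st$truth$params$sigma_male,
                batch_effect = st$truth$params$batch_effect,
                tpc_male = unclass(st$truth$params$tpc_male))
  f <- tempfile(fileext = ".json")
  write_run_config(truth, f)
  back <- read_run_config(f)
  expect_equal(back$sigma_male, truth$sigma_male)
  expect_equal(back$tpc_male$r_opt, truth$tpc_male$r_opt)
  expect_equal(back$tpc_male$skew, "right")
  expect_equal(back$seed, cfg$seed)
})

test_that("deterministic limits of the termination generator", {
  sharp <- ref_term
  sharp$sigma_male <- 1e-9; sharp$sigma_female <- 1e-9
  cfg <- synthetic_config(seed = 45, term_params = sharp,
                          batch1_treatments = list(`2C` = 2),
                          batch2_treatments = list())
  st <- generate_termination_study(cfg)
  # every transfer far beyond 1/mu terminates
  late <- st$trials[st$trials$transfer_day > 170, ]
  expect_true(all(late$terminated == 1L))
  early <- st$trials[st$trials$transfer_day < 120, ]
  expect_true(all(early$terminated == 0L))
  # a regime entirely above T_max yields no terminations
  hot <- generate_fluctuating_cohort(small_config(seed = 46),
                                     "12:12 h 33:38 degC")
  expect_true(all(hot$trials$terminated == 0L))
})

test_that("generator marginals track the analytic termination probability", {
  cfg <- synthetic_config(
    seed = 47,
    batch1_treatments = list(`2C` = 2),
    batch2_treatments = list(),
    batch1_schedule = list(start = 60, end = 240, step = 4, per_sex = 40,
                           slow_switch = 200, slow_step = 16,
                           slow_end = 300))
  st <- generate_termination_study(cfg)
  tr <- st$trials[st$trials$sex == "male", ]
  mu <- lrf_rate(2, male_tpc)
  for (d in c(100, 140, 180, 220)) {
    sub <- tr[tr$transfer_day == d, ]
    p <- cumulative_termination_prob(log(mu * d), ref_term$sigma_male)
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$terminated) - p), 3 * se + 1e-9)
  }
})

test_that("degenerate constant regime reproduces the constant generator", {
  cfg <- synthetic_config(seed = 48, batch1_treatments = list(`4C` = 4),
                          batch2_treatments = list())
  st <- generate_termination_study(cfg, batches = 1L)
  co <- generate_fluctuating_cohort(cfg, 4, treatment_id = "4C")
  expect_identical(st$trials$terminated, co$trials$terminated)
  expect_identical(st$trials$transfer_day, co$trials$transfer_day)
  expect_identical(st$trials$sex, co$trials$sex)
})

test_that("development generator honours history, noise and empty cohorts", {
  # sigma -> 0 at T_opt: every time is the reciprocal peak rate
  quiet <- development_params(dev_tpc, 0, 0.060, 1e-9)
  cfg <- small_config(seed = 49, dev_params = quiet,
                      dev_design = list(temperatures = 29.6, n_2C = 20,
                                        n_4C = 0))
  dv <- generate_development_records(cfg)
  expect_equal(dv$records$development_time, rep(1 / 0.152, 20),
               tolerance = 1e-6)
  # 4C-history geometric mean faster by exp(0.060), n = 1e4 within 1%
  cfg2 <- small_config(seed = 50,
                       dev_design = list(temperatures = 20, n_2C = 10000,
                                         n_4C = 10000))
  dv2 <- generate_development_records(cfg2)
  gm <- tapply(log(1 / dv2$records$development_time),
               dv2$records$winter_history, mean)
  expect_lt(abs(exp(gm[["4C"]] - gm[["2C"]]) / exp(0.060) - 1), 0.01)
  # zero cohorts: empty table
  empty <- generate_development_records(
    small_config(seed = 51, dev_design = list(temperatures = 20, n_2C = 0,
                                              n_4C = 0)))
  expect_identical(nrow(empty$records), 0L)
  # unusable temperatures are excluded with a warning
  expect_warning(
    generate_development_records(
      small_config(seed = 52,
                   dev_design = list(temperatures = c(0, 20), n_2C = 10,
                                     n_4C = 0))),
    "outside")
})

test_that("respirometry generator matches its stated structure", {
  # zero noise everywhere: records sit exactly on the exponential curve
  cfg <- small_config(
    seed = 53,
    metab_params = list(male = ref_metab$male, female = ref_metab$female,
                        sigma_obs = 1e-12),
    resp_design = list(n_per_treatment = 4, ages = c(30, 90, 150),
                       ind_sd = 0, cell_sd = 0, mean_mass = 0.1, rq = 0.8))
  rp <- generate_respirometry_records(cfg)
  rate <- metabolic_rate_joules(rp$records$v_o2, rp$records$v_co2,
                                rp$records$mass)
  expected <- ifelse(rp$records$sex == "male",
                     exp_rate(rp$records$temperature, ref_metab$male),
                     exp_rate(rp$records$temperature, ref_metab$female))
  expect_equal(rate, expected, tolerance = 1e-9)
  # an individual keeps one intercept across its repeated measures
  cfg2 <- small_config(
    seed = 54,
    metab_params = list(male = ref_metab$male, female = ref_metab$female,
                        sigma_obs = 1e-12),
    resp_design = list(n_per_treatment = 1, ages = c(30, 90, 150),
                       ind_sd = 0.3, cell_sd = 0, mean_mass = 0.1, rq = 0.8))
  rp2 <- generate_respirometry_records(cfg2)
  one <- rp2$records[rp2$records$pupa_id == rp2$records$pupa_id[1], ]
  r1 <- metabolic_rate_joules(one$v_o2, one$v_co2, one$mass)
  expect_equal(r1, rep(r1[1], nrow(one)), tolerance = 1e-9)
  # OLS slope of log rate on temperature within 3 SE of the truth
  rp3 <- generate_respirometry_records(small_config(seed = 55))
  males <- rp3$records[rp3$records$sex == "male", ]
  fit <- lm(log(metabolic_rate_joules(v_o2, v_co2, mass)) ~ temperature,
            data = males)
  est <- coef(summary(fit))["temperature", ]
  expect_lt(abs(est["Estimate"] - 0.0926), 3 * est["Std. Error"])
})
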