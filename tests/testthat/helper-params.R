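# Shared fixtures: reference parameter sets and small study designs.

ref_term <- pnapi_termination_params()
ref_dev <- pnapi_development_params()
ref_metab <- pnapi_metabolic_params()

male_tpc <- ref_term$tpc_male
dev_tpc <- ref_dev$tpc

# A reduced constant-temperature design for fast fitting tests.
small_config <- function(seed, ...) {
  synthetic_config(
    seed = seed,
    batch1_treatments = list(`2C` = 2, `4C` = 4, `8C` = 8, `15C` = 15),
    batch2_treatments = list(),
    ...)
}

# The criterion-level six-treatment batch-1 recovery design.
recovery_config <- function(seed) {
  synthetic_config(
    seed = seed,
    batch1_treatments = list(`-6C` = -6, `1C` = 1, `2C` = 2, `4C` = 4,
                             `8C` = 8, `15C` = 15),
    batch2_treatments = list())
}

# Brute-force rate summation over explicit piecewise-constant segments
# (independent oracle; same midpoint day-binning rule as the package).
brute_progress <- function(time_h, temp, tpc, at_days,
                           horizon_end_h = max(at_days) * 24) {
  ends <- c(time_h[-1], horizon_end_h)
  rates <- lrf_rate(temp, tpc)
  mids <- (time_h + ends) / 2
  contrib <- rates * (ends - time_h) / 24
  vapply(at_days, function(d) sum(contrib[mids < d * 24]), numeric(1))
}
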