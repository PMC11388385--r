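# diapausr

Quantitative models of temperature-dependent diapause progression in
overwintering insects.

## The problem

Many temperate insects overwinter in diapause, a programmed developmental
arrest that must be *terminated* by prolonged cold before development can
resume in spring. Termination is cryptic: an individual pupa looks the same
before and after, and the only practical assay is binary — move it from
winter to post-winter conditions and see whether the adult ecloses within a
cutoff (here, 12 days at 20 °C). Because termination may have happened at
any time before the transfer, rates cannot be read off individual records;
they must be inferred at the population level from the binary outcomes of a
staggered transfer schedule.

`diapausr` implements that inference and everything around it, using the
green-veined white butterfly *Pieris napi* as the reference system:

- **Thermal performance curves.** The Lobry–Rosso–Flandrois (LRF)
  cardinal-temperature model
  `R(T) = R_opt (T−T_max)(T−T_min)² / {(T_opt−T_min)[(T_opt−T_min)(T−T_opt) −
  (T_opt−T_max)(T_opt+T_min−2T)]}`,
  zero outside `(T_min, T_max)`, in its usual left-skewed form for
  postdiapause development and as a mirrored, right-skewed form for diapause
  termination (cold optimum near 1 °C, long warm tail). `lrf_rate()`,
  `tpc_params()`.
- **Latent lognormal termination rates.** Each pupa draws one lognormal
  multiplier around the TPC-valued geometric mean rate; physiological
  progress accumulates as rate × time and termination occurs when it
  reaches 1. The probability of having terminated by day *t* is
  `Φ(ln S(t) / σ)` with `S(t)` the accumulated geometric-mean progress —
  which makes the binary transfer data a Bernoulli likelihood.
  `cumulative_termination_prob()`, `trial_log_likelihood()`,
  `simulate_individual_paths()`.
- **Rate summation.** Predictions under fluctuating regimes integrate the
  constant-temperature TPC over the measured temperature record.
  `square_wave_regime()`, `accumulated_progress()`, `predict_fluctuating()`.
- **Inference.** MAP estimation under an ordered cardinal-temperature
  transform, followed by a short adaptive Metropolis chain; marginal
  kernel-density modes and 90% HPD intervals. `fit_termination_tpc()`,
  `fit_development_tpc()`, `fit_metabolic_model()`, `hpdi()`,
  `posterior_predictive_check()`.
- **Synthetic studies.** A generator reproducing the reference sampling
  design (two batches, constant and square-wave winter treatments, family
  structure) with known ground truth, so the whole pipeline is testable
  offline. `synthetic_config()`, `generate_termination_study()` and
  friends.
- **Evaluation.** Observed-vs-predicted cumulative counts,
  day-of-termination comparisons, reduced-major-axis regression, and the
  headline derived quantities. `cumulative_count_comparison()`,
  `derived_quantities()`.

## Worked example

Simulate a full transfer study under the reference parameters, refit the
termination TPC, and derive the reported quantities:

```r
library(diapausr)

params <- pnapi_termination_params()
params$tpc_male
#> LRF thermal performance curve (right-skewed)
#>   T_min -6.18  T_opt 0.683  T_max 31.3 degC;  R_opt 0.00746 / day

# predicted termination probability under a 12:12 h 0:8 degC square wave
pred <- predict_fluctuating(square_wave_regime("12:12 h 0:8 degC", days = 250),
                            params, sex = "male", horizon_days = 250)
round(pred[c(100, 150, 200), ], 3)
#>     day progress  prob
#> 100 100    0.652 0.038
#> 150 150    0.979 0.464
#> 200 200    1.305 0.866

cfg <- synthetic_config(seed = 1)
study <- generate_termination_study(cfg)   # 1504 binary transfer trials
fit <- fit_termination_tpc(study$trials, seed = 1,
                           engine = list(method = "laplace", n_draws = 1000))
summary(fit)
#>       parameter     mode  hpdi_low hpdi_high
#> 4    r_opt_male  0.00748   0.00623   0.00858
#> 5    sigma_male  0.27495   0.24250   0.31030
#> 9  r_opt_female  0.00609   0.00583   0.00630
#> 11 batch_effect -0.20218  -0.29246  -0.11316   (excerpt)

derived_quantities(fit$modes[["r_opt_male"]], fit$modes[["r_opt_female"]],
                   (fit$modes[["sigma_male"]] + fit$modes[["sigma_female"]]) / 2)
#>                          quantity  value rounded    unit
#> 1      termination_time_topt_male 133.72     134    days
#> 2    termination_time_topt_female 164.14     164    days
#> 3   percent_individual_difference  28.95      29 percent
```

`r_opt` of 0.00748/day means the fastest-terminating temperature still
needs ~134 days of winter; the lognormal σ of ~0.27 implies typical
individuals differ by ~30% in rate. Values recovered from synthetic data
sit near, but not exactly at, the generating modes (0.00746, 0.00634,
σ 0.240/0.208, batch −0.230).

The same pipeline is scriptable:

```sh
Rscript -e 'diapausr::run_cli()' simulate --seed 7 --out-dir out --what termination
Rscript -e 'diapausr::run_cli()' fit-termination --trials out/termination_trials.csv \
    --out out/fit --seed 1
```

## Documentation

The methods vignette (`vignettes/diapause-termination-model.Rmd`) describes
the model, its assumptions, the synthetic-data generator's scope, and the
numerical choices; function documentation lives in the roxygen comments.
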