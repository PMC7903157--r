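# stopvar

Behavioral and BOLD variability in stop-signal response inhibition.

`stopvar` is for researchers who study how *consistently* people inhibit
responses, not just how fast. In the stop-signal task, a go stimulus
occasionally turns into a stop signal after a staircased delay (SSD), and
the latency of the covert stopping process — the stop-signal reaction time
(SSRT) — must be inferred from the race between a go and a stop process.
Children and adults can have indistinguishable mean SSRTs while differing
sharply in the *width* and *tail* of their SSRT distributions; that
behavioral variability can in turn be related to how variable the BOLD
response is from trial to trial in the right-lateralized inhibition
network (IFG, caudate, putamen, thalamus, STN).

The package implements that complete analysis chain on synthetic data with
known ground truth:

- **Task simulator** — staircase-tracked stop-signal sessions (2 x 128
  trials, 25% stops, gaps of 1/2/4/5 go trials, 50-ms up/down SSD
  staircase from 250 ms) played by an independent horse race with
  ex-Gaussian finishing times and optional trigger failures (`p_tf`).
- **Integration SSRT** — rank-ordered correct-go RTs at the failed-
  inhibition quantile, minus mean SSD; plus QC (exclude below 30%
  successful stops).
- **Hierarchical Bayesian race model** (`fit_race()`) — subject- and
  group-level go/stop ex-Gaussian parameters `mu`, `sigma`, `tau` (SSRT
  distribution mean `mu + tau`, variance `sigma^2 + tau^2`) and
  trigger-failure probability, estimated by compiled adaptive
  Metropolis-within-Gibbs sampling with split-Rhat diagnostics and
  posterior-predictive SSRT distributions.
- **BOLD variability (DoR)** — simulate event-related runs whose
  trial-to-trial response-amplitude SD is known per region, then estimate
  it as the difference of residuals between a condition-averaged GLM and a
  trial-wise GLM (canonical double-gamma HRF with temporal and dispersion
  derivatives, pooled error regressor, DCT drift terms; residual sums of
  squares deliberately not divided by degrees of freedom).
- **Group statistics** — ROI/network extraction, one-way ANOVAs with
  eta-squared, Bonferroni-thresholded voxel-wise group t-maps with a
  10-voxel cluster-extent filter, Pearson and partial correlations, Fisher
  r-to-z comparison of independent correlations, and exact noncentral-t
  power analysis.
- **Pipeline** — `run_pipeline()` drives simulate → behavior → race fit →
  DoR → statistics from one seeded configuration, persisting every
  intermediate artifact (TSV, NIfTI) and a markdown report.

## Worked example

```r
library(stopvar)

params  <- race_params(mu_go = 400, sigma_go = 50, tau_go = 100,
                       mu_stop = 200, sigma_stop = 30, tau_stop = 50)
session <- simulate_session(params, task_design(), seed = 1)
summarize_stopping(session)
#>   subject_id group n_go n_stop pct_stop_success mean_ssd mean_go_rt
#> 1        s01 adult  192     64               50 251.5625   500.7161
#>   ssrt_integration
#> 1         232.8108
```

The staircase held this subject at exactly 50% successful stops with a
mean SSD of 252 ms; the integration SSRT of 233 ms is a finite-sample
estimate of the true mean SSRT (`mu_stop + tau_stop` = 250 ms here).

```r
power_sample_size(1.2, alpha = 0.05, power = 0.80)
#> $n_per_group    12
#> $n_total        24
#> $achieved_power 0.802
```

A standardized group difference of d = 1.2 needs 12 subjects per group
(24 in total) for 80% power at alpha = .05.

```r
coh <- simulate_cohort(seed = 1, center_groups = TRUE)  # 19 children + 26 adults
children <- coh$sessions[coh$truth$group == "child"]
fit <- fit_race(children, mcmc_settings(n_chains = 3, n_samples = 9000,
                                        n_burn_in = 3500, thinning = 5,
                                        estimate_trigger_failure = FALSE,
                                        seed = 1))
fit
#> Hierarchical ex-Gaussian race-model fit (child)
#>   19 subjects; 3 chains x 1100 retained draws (thinning 5)
#>   group-level posterior medians:
#>     go:   mu 450, sigma 62, tau 122 ms
#>     stop: mu 216, sigma 48, tau 46 ms; p_tf 0.000
max(rhat_diagnostics(fit)$rhat[1:133])
#> 1.071
```

The child group was generated with stop parameters (218, 48, 46) ms; the
group-level posterior medians recover them as (216, 48, 46) with all
split-Rhat below 1.1. `summary(fit)` adds credible intervals,
`coef(fit)$subjects` gives the per-subject medians used in brain-behavior
correlations, `predict(fit)` draws the posterior-predictive SSRT
distribution, and `plot(fit)` shows it.

For the full chain on one configuration:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "stopvar-output"))
```

which writes sessions, ground truth, behavioral summaries, posterior
draws, per-subject DoR maps (NIfTI), statistics tables, and a report with
behavioral, BOLD-variability and correlation sections.

The methods vignette (`vignettes/stopvar-methods.Rmd`) documents the
models, priors, sampler, numerical choices and known identifiability
limits.

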