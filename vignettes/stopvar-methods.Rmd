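---
title: "Models and methods behind stopvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package studies

Response inhibition is usually summarized by a single number, the
stop-signal reaction time (SSRT). `stopvar` is built around the idea that
the *variability* of stopping, not just its mean, carries developmental
signal: children and adults can stop equally fast on average while children
stop far less consistently, and that behavioral inconsistency can be
related to how variable the BOLD signal is, trial by trial, in the brain's
right-lateralized inhibition network (inferior frontal gyrus, caudate,
putamen, thalamus, subthalamic nucleus).

The package provides, end to end on synthetic data with known ground
truth:

1. a simulator of the staircase-tracked stop-signal task and of
   event-related BOLD runs;
2. the classical horse-race (integration) SSRT estimator and behavioral QC;
3. a hierarchical Bayesian ex-Gaussian race model of the full SSRT
   distribution, with trigger failures;
4. trial-by-trial BOLD variability as a difference of residuals (DoR)
   between a condition-averaged and a trial-wise GLM;
5. the group and brain-behavior statistics linking 2-4.

## The horse-race model and its simulator

Every trial runs an independent race between a *go* process and (on stop
trials) a *stop* process. Finishing times are ex-Gaussian — a
Normal(mu, sigma) plus an independent Exponential with mean tau, so the
distribution has mean `mu + tau`, variance `sigma^2 + tau^2`, and the
right-skewed shape characteristic of response times. The go runner's
finishing time is the response time; a response is withheld iff the stop
runner, launched at the stop-signal delay (SSD), finishes first. With
probability `p_tf` (a *trigger failure*) the stop process never launches
and the trial behaves like a go trial regardless of SSD.

The simulated task follows the standard developmental protocol: two blocks
of 128 trials, 96 go + 32 stop per block, stop trials preceded by go-runs
of 1, 2, 4 or 5 trials (each gap used eight times per block, shuffled), a
50-ms up/down SSD staircase starting at 250 ms (up after successful stops,
floored at 0 ms), a 1500-ms response deadline, and a 2000-4000 ms uniform
inter-trial jitter extended by `1500 - RT` after responses so sessions last
equally long. The staircase provably converges to ~50% successful
stopping, which the tests verify over 5,000+ simulated stop trials.

Simulator choices the task description leaves open: go omissions occur
naturally when the go runner exceeds the deadline; wrong-direction
responses are generated at a configurable 2% so that "correct go trial"
filtering is exercised; any response on a stop trial counts as a failed
stop regardless of its direction.

## Integration SSRT

The canonical estimator: rank the correct-go RTs ascending, look up the RT
at the quantile given by the proportion of failed inhibitions
(index `ceiling(p * N)`, no interpolation), and subtract the mean SSD over
all stop trials. Go omissions are assigned the deadline RT before ranking
(limiting omission bias; this can be switched off); wrong-direction
responses are excluded. On long simulated sessions with `p_tf = 0` the
estimate converges to the true mean SSRT, `mu_stop + tau_stop`.

## Hierarchical Bayesian estimation of the SSRT distribution

`fit_race()` estimates each subject's go and stop ex-Gaussian parameters
and trigger-failure probability simultaneously with group-level locations
and scales. The likelihood is the standard race factorization:

* correct go RT `t`: `f_go(t)`;
* go omission: right-censored at the deadline, `1 - F_go(max_rt)`;
* failed stop at SSD `d` with RT `t`:
  `f_go(t) * (p_tf + (1 - p_tf) * (1 - F_stop(t - d)))`;
* successful stop at SSD `d`:
  `(1 - p_tf) * integral f_stop(s) * (1 - F_go(d + s)) ds`.

The inhibition integral is evaluated by Gauss-Legendre quadrature on two
panels — one resolving the Gaussian core of the stop density, one its
exponential tail — over a window holding all but less than 1e-8 of the
stop-latency mass (24 nodes per panel; measured absolute error below 1e-7
across narrow- and wide-parameter regimes). All computation is in the log
domain with an erfc-based log-Phi.

**Priors.** Subject parameters follow truncated-Normal population
distributions: the mu's on (0, 2000) ms, the sigma's and tau's on
(1, 500) ms; `p_tf` is modelled on the probit scale with a Normal
population distribution on (-6, 2). Group locations have uniform priors
over the same supports, group scales uniform on (0.01, 500) ms (probit
scale: (0.01, 3)).

**Sampler.** Adaptive Metropolis-within-Gibbs, compiled. A component-wise
phase early in burn-in seeds per-subject empirical covariances; afterwards
subjects are updated by multivariate normal block proposals (go block and
stop block) scaled Haario-style toward a 20-50% acceptance rate, with
adaptation frozen at the end of burn-in. Because the group location and
scale are strongly coupled to all subjects through shrinkage, two joint
moves are interleaved for the stop-side parameters: a *shift* move
translating a group location together with every subject's value, and a
*stretch* move rescaling a group scale together with every subject's
deviation (a deterministic expansion with Jacobian `c^(S+1)`). Without
them, group-level chains do not mix at realistic session lengths. Chains
start from short per-subject maximum-likelihood refinements of
moment-based values, jittered per chain. Convergence is checked with
split-Rhat (flagged above 1.1); non-convergence is reported, never silent.

**Defaults.** The default `mcmc_settings()` mirror the conventional
analysis: 3 chains, 30,000 samples, 10,000 burn-in, thinning 10 (2,000
retained draws per chain), 1,000 posterior predictions, trigger-failure
estimation on. The worked examples and tests use shorter chains; the
problem sizes used there (e.g. 3 x 20,000 for the 20-subject recovery
study, 1 x 3,500 per group for the cohort replication) were chosen as the
smallest at which split-Rhat stays below 1.1 on those problems.

**Point estimates** are posterior medians with central 95% credible
intervals; the subject-level stop-parameter medians are the behavioral
variability measures used in brain-behavior correlations. Posterior
predictions draw a new subject from the population distribution per
retained draw and simulate SSRTs, pooling them into the estimated group
SSRT distribution.

### What is, and is not, identifiable at session scale

A 256-trial session contains 64 stop trials. Profile-likelihood analysis
shows `sigma_stop` is then close to unidentified at the subject level
(even 12,800 stop trials yield only ~10 nats of curvature across
sigma in [5, 60] ms), and the posterior lives on a ridge trading
`sigma_stop`, `tau_stop`, `mu_stop` and `p_tf` against each other. Two
consequences shape the package's study designs:

* group-level estimates inherit ridge ambiguity: on some cohort
  realizations the posterior median of the group `sigma_stop` sits far
  from truth even with perfectly converged chains;
* adding the trigger-failure dimension when the data cannot inform it
  (tens of stop trials, no TF trials) destabilizes the whole stop block.

The default synthetic cohort therefore simulates fully attentive
triggering (`p_tf = 0`) and the scaled-down analyses fit with
`estimate_trigger_failure = FALSE`, keeping estimation exactly matched to
the generator; trigger failures remain a first-class model component
(nonzero `p_tf`, likelihood terms, estimation toggle) for real data, where
the full-length default settings apply.

## The default synthetic cohort

19 children and 26 adults. Subject-level truth is drawn from
truncated-Normal group distributions with locations (child / adult):

| parameter | child | adult | scale |
|---|---|---|---|
| mu_go / sigma_go / tau_go (ms) | 450 / 60 / 120 | 400 / 50 / 100 | 40 / 10 / 20 |
| mu_stop (ms) | 218 | 226 | 60 |
| sigma_stop (ms) | 48 | 24 | 6 |
| tau_stop (ms) | 46 | 34 | 12 |

The structure emulates the qualitative developmental pattern: children's
SSRT distributions are much wider (sigma roughly doubled — the dominant
effect) and longer-tailed (tau moderately larger), their go responses are
slower, and mean SSRT (`mu_stop + tau_stop`: 264 vs 260 ms) is matched to
a few ms, far inside the 60-ms between-subject spread, so average stopping
speed does not differ detectably. The 12-ms between-subject scale of
`tau_stop` reflects the substantial individual differences in attentional
lapsing this literature emphasizes. `center_groups = TRUE` re-centers each
group's drawn values so realized group means equal these locations
exactly; the replication analyses use it because their contrasts are
statements about matched truth, which finite-cohort sampling noise (up to
~2 SEM, 35 ms for mu_stop) would otherwise confound.

## Synthetic BOLD runs and the difference of residuals

The synthetic "brain" is a 10x10x10 voxel grid with six disjoint 3x3x3
labeled regions named for the inhibition-network ROIs plus a right
calcarine control; there is no anatomical realism — labels exist so
region-level signal structure and ROI extraction can be exercised against
ground truth. Each voxel's signal is baseline + per-trial responses +
AR(1) noise (coefficient 0.3, stationary SD 1) + a linear-plus-sine drift.
The response amplitude of trial *i* in region *r* is drawn once per
(trial, region) from `Normal(mean, sd)` given the region and the trial's
outcome condition and is shared by the region's voxels — the configured
`sd` *is* the ground-truth trial-by-trial variability that the DoR
analysis estimates. Inhibition regions respond strongly to successful
stops (mean 3, group-dependent SD), weakly to go trials; the calcarine
control responds to every visual event with group-independent SD. The
default stop-locked amplitude SDs are 0.9 (children) and 2.1 (adults),
optionally coupled within group to stopping consistency as
`sd_i = sd_group * exp(-0.5 * z(tau_stop,i))`, which realizes an
adult-group DoR-tau correlation of about -0.6. Six-parameter random-walk
motion is emitted alongside, calibrated (with a lognormal between-subject
factor) to mean framewise displacements of ~0.19 mm in adults and
~0.22 mm in children.

The canonical HRF is the usual double-gamma (peak 6 s, undershoot 16 s,
unit dispersions, ratio 6, 32-s support) sampled at TR/16, with
finite-difference temporal and dispersion derivatives. The standard GLM
has one regressor per condition (canonical + both derivatives), a single
canonical regressor pooling error trials (failed stops, wrong-direction
responses, omissions), optional nuisance series, discrete-cosine drift
terms (128-s cutoff) and an intercept. The trial-wise GLM is identical
except the condition of interest's canonical regressor is replaced by one
canonical regressor per trial; the condition-level derivatives are kept so
the standard design's column space is nested in the trial-wise one — that
nesting is what makes

DoR = SSR_standard - SSR_trialwise >= 0

voxel-wise, a nonnegative estimate of the variance uniquely absorbed by
the per-trial regressors, i.e. of trial-by-trial response variability in
that condition. (The method is sometimes verbally described with the
subtraction reversed; the nonnegative orientation is the one consistent
with its intent, and the package defines it this way.) Residual maps are
deliberately *not* divided by residual degrees of freedom: the trial-wise
model's df depends on each subject's number of successful stops, and
dividing would bias between-subject comparisons. Estimation is plain OLS
without prewhitening. Denoising is confound regression (white-matter/CSF
means where available, realignment parameters, one indicator per flagged
outlier volume); preprocessing proper (realignment, normalization,
smoothing) is out of scope.

A known small artifact of the raw-SSR convention: with k per-trial
regressors the trial-wise model also absorbs ~k noise dimensions, so DoR
has a noise floor that grows with the number of trials of the condition of
interest. Between-group comparisons are unaffected when trial counts are
matched in expectation (the staircase guarantees ~50% successful stops for
everyone), but DoR values should not be read as pure signal variance.

## Group statistics

ROI values are arithmetic means over mask voxels; the network value pools
the five inhibition masks. Group differences use one-way ANOVA with
`eta^2 = SS_between / SS_total`. Voxel-wise group maps use two-sample
pooled-variance t tests thresholded at a Bonferroni-corrected voxel alpha
over in-mask voxels — a deliberate, simple substitute for random-field FWE
correction, which is out of scope — followed by a 10-voxel cluster-extent
filter with 6-connectivity (faces only). Brain-behavior analyses use
Pearson correlations; partial correlations control the go parameters via
residual-on-residual correlation with `n - 2 - k` degrees of freedom;
independent correlations are compared with the Fisher r-to-z statistic
`z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`. The power
calculation inverts the exact noncentral-t power function of the
two-sided two-sample t test for the smallest equal per-group n.

## What passing the synthetic tests does and does not show

The generator emulates the *statistical structure* the analyses assume:
ex-Gaussian races with staircased SSDs, region-coherent trial amplitudes,
AR(1) noise and slow drift. It does not emulate real fMRI physics (no
spatial correlation or smoothing, no physiological noise, no anatomy), nor
real populations (no IQ or demographic structure). Passing tests therefore
demonstrates that the estimators recover what they claim from data obeying
their own assumptions at realistic sizes — a necessary condition — and
quantify the identifiability limits above; they say nothing about
violations a real scanner or a real child can produce.

## Numerical choices and degenerate inputs

* Successful-stop integral: two 24-node Gauss-Legendre panels per unique
  staircase SSD; log-domain throughout; erfc-based log-Phi with an
  asymptotic lower-tail series (relative error < 1e-6 at the switch).
* Sessions with no stop trials, no failed stops, or all-flagged volumes
  raise explicit errors rather than returning NaN.
* Negative DoR values within numerical tolerance of zero are clipped at
  reporting; larger violations (impossible under nesting) warn.
* Degenerate-variance voxels in group maps are flagged and zeroed, never
  propagated as infinities.
* SSD is floored at 0 ms; the ex-Gaussian's left tail is truncated at
  1 ms when simulating finishing times.
* Ties in the integration method are impossible for continuous RTs; the
  `ceiling(p * N)` index is clamped to `[1, N]`.

## Known limitations

* Subject-level `sigma_stop` (and `p_tf`) are weakly identified at
  conventional session lengths; their posteriors are prior- and
  ridge-shaped, and group medians can be far from truth on unlucky
  cohorts. Group contrasts are much more robust than absolute values.
* The Bonferroni voxel threshold is conservative relative to random-field
  FWE; cluster tables are comparable only in structure, not in exact
  extent, to toolbox output.
* The DoR noise floor grows with trial count (above).
* No serial-correlation modelling in the GLM beyond high-pass filtering;
  the AR(1) generator noise mildly inflates SSR in both models and largely
  cancels in the difference.
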