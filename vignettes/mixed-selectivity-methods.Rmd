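---
title: "Models and methods for nonlinear mixed selectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for nonlinear mixed selectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mixedsel)
```

## The scientific problem

In a virtual-navigation delayed match-to-sample task, an animal sees a
binary sample cue (black or white, S = -1/+1), holds it in memory across a
variable-length delay, and then meets a binary test cue configuration
(BW or WB, T = +1/-1). The rewarded turn is the XOR combination S*T, which
equals the choice C on correct trials. A neuron can carry information about
the sample cue only, the test cue only, or a nonlinear conjunction of both —
*nonlinear mixed selectivity*, typified by cells active on exactly one of
the four trial types. This package quantifies these codes in single cells
and populations, and asks whether mixed-selectivity populations encode the
reward direction more accurately and more efficiently than pure-selectivity
populations.

All analyses run on synthetic sessions from the package's own generator, so
every stage is testable without animal data.

## The synthetic session generator

`generate_trials()` draws independent uniform cues, sets C = S*T with
probability `1 - error_rate`, and draws segment lengths on the 400 cm
T-stem: the test segment is fixed at 160 cm, the delay is uniform on
[20, 100] cm, the sample segment takes the remainder. `generate_trajectory()`
produces 30 Hz frames: forward speed is Gaussian per frame (default mean
50 cm/s, s.d. 10, truncated at 1 cm/s so position never decreases),
and three treadmill velocity components are emitted and z-scored over the
session. Position is a single scalar — cumulative path length through the
stem and 60 cm of arm — because the spatial basis set must tile the maze
with one coordinate. Inter-trial intervals are emitted but excluded from
every analysis.

`make_cells()` builds a ground-truth roster across five classes: pure
sample-cue cells, pure test-cue cells, mixed (single-trial-type) cells,
choice cells, and movement-only cells. Task cells are position-tuned with a
raised-cosine envelope (default width 80 cm); their centers default to
240–300 cm, around test-cue onset, because that is where memory and visual
information mix and where the early-test analysis window sits — a cell whose
field misses the analyzed window cannot express its class there, and real
cells in these analyses are selected the same way (by being active in the
analyzed segment). Movement cells are tuned to z-scored forward velocity
instead of position, so a movement-only encoding model explains them fully.
Event trains are Bernoulli per frame (the analyzed signal is a binarized,
deconvolved calcium train, not a count), with peak preferred-trial
probability 0.5 and unpreferred 0.05 per frame by default.

The `error_degradation` parameter (0–1) shrinks the preferred/unpreferred
rate contrast of mixed cells on error trials about its midpoint; 1 makes
their error-trial activity exchangeable across trial types. This is the
generative hypothesis for the observed loss of XOR information on error
trials, and the pipeline's correct-versus-error comparisons test whether
the analysis recovers it.

What the generator does *not* emulate: calcium indicator dynamics and
imaging noise (trains are clean Bernoulli draws), slow drift, position-
dependent movement selectivity, and stimulus-dependent noise correlations.
Passing tests therefore certify the analysis chain under Poisson-like,
conditionally independent noise — not robustness to those real-data
features.

## The encoding model

Each cell's response \(r_i\) — its event count summed over the ten frames
\([i-5, i+4]\), about 350 ms — is modelled as Poisson with mean
\(\mu_i = \exp(\beta_0 + \mathbf{x}_i \cdot \boldsymbol\beta)\). Task
predictors are 31 positional raised-cosine bases (40 cm width, centers
every 20 cm from 0 to 600 cm, half-width overlap) signed by the identity of
each task-variable subset: offset, S, T, C, and optionally the S\*T, T\*C,
S\*C, S\*T\*C interactions (163 or 287 columns). Movement predictors are 13
raised-cosine bases of width 1 on each z-scored velocity component, clipped
to [-3, 3]. Exact center placement is not dictated by the task; 0–600 cm
covers the stem plus arm path with a uniform partition (the unsigned bases
sum to 1 everywhere on the maze).

Fitting is elastic-net Poisson regression (`glmnet`) with mixing
\(\alpha = 0.95\), intercept unpenalized, columns unstandardized (bases are
already bounded in [-1, 1]). The penalty is chosen by 10-fold
cross-validation stratified so each fold holds an equal number of trials
per (S, T, C) condition; the reported coefficients are taken at
\(\lambda_{1se}\), the most regularized model within one standard error of
the minimum CV deviance. Per-trial loss weights inversely proportional to
the (trial type x outcome) count are available (`balance_trials`) but off
by default; results are reported unweighted. A solver failure or an
all-zero response marks the cell `converged = FALSE`, and such cells are
excluded downstream rather than raising.

Numerical choices: `fit_encoding_glm()` defaults to a 50-value
log-spaced \(\lambda\) path down to \(10^{-4}\) of the smallest
all-zeroing penalty; `run_pipeline()` uses 30 values with floor
\(0.05\,\lambda_{max}\) — \(\lambda_{1se}\) sits near the top of the path,
and the deep tail only costs coordinate-descent iterations. The pipeline
also fits on every 5th frame: adjacent 10-frame windowed responses overlap
90%, so consecutive frames are highly redundant for estimation.

Goodness of fit is the fraction of deviance explained on held-out trials,
\(FDE = (L_{GLM} - L_{null}) / (L_{sat} - L_{null})\), with the null model
predicting the training-mean rate and the saturated model the observed
counts; five condition-stratified train/test splits are cycled so every
trial is evaluated held-out exactly once. Comparing the full model with a
movement-only model (39 velocity columns) isolates task-dependence per
cell.

## Single-trial information

Information about a task variable at one frame is the log-likelihood ratio
of the observed count under its two identities, conditioned on observed
movement and marginalized over the unobserved task variables: each retained
(S, T, C) condition is weighted \(P_c/2\) when the choice matches the
reward direction and \(P_e/2\) otherwise, where \(P_c, P_e\) are the
session's outcome proportions. For XOR, the numerator and denominator pool
the (S, T) pairs sharing a reward direction. Mixtures are evaluated in log
space with log-sum-exp; logLR is in natural-log units and clamped to ±50
so zero-rate hypotheses cannot produce infinities. The sign is adjusted by
the identity observed on the trial, so positive logLR always means correct
encoding; a fitted model with no task-group coefficients yields exactly 0.

Window summaries average logLR over the last 1 s of the sample segment,
the last 0.35 s of the delay (10 frames at 30 Hz — the same span as the
response window), and the first 1 s of the test segment, then over trials.

## Selectivity classification

Per cell, correct-trial sample and test information in the early test
window define polar coordinates \(r, \theta\). Cells with \(r\) below the
noise level \(\epsilon = 0.01\) are `noise`: unbinned, but kept in
denominators of bin fractions. Cells within \(\epsilon\) of an axis are
snapped onto it; seven angle bins cover \(\theta < 0\) to
\(\theta > 90^\circ\). Mixed selectivity is \(15^\circ \le \theta <
75^\circ\); pure classes additionally require XOR information magnitude
below a chance level (default \(\epsilon\); `estimate_chance_level()`
offers the empirical alternative — the s.d. of apparent test cue
information *before* the test cue exists, measured in the late sample
window). \(\epsilon\) is exposed as a parameter because chance information
differs across recorded areas in practice.

Normalized activity divides the four trial-type means (correct trials,
early test window) by their sum; the nonlinearity index
\(NI = |(kr_{B/BW} - kr_{B/WB}) - (kr_{W/BW} - kr_{W/WB})|\) is 0 for
additive tuning and 1 for single-trial-type (or single-choice-direction)
activity. Because NI is an absolute value, finite trials give a positive
chance level even for untuned cells; `shuffle_chance_ni()` estimates it by
permuting trial-type labels, and it shrinks as \(1/\sqrt{n}\) with trials
per type (folded-Gaussian scaling, which the tests verify against the
closed form).

## Population decoding

Under conditionally independent noise, the population likelihood of a
condition is the product of single-cell Poisson likelihoods; the population
logLR marginalizes exactly as in the single-cell case (for up to four cells
the tests check it against brute-force enumeration over all eight
conditions at \(10^{-10}\) relative tolerance). A trial's decoded identity
is the sign of its mean frame-wise population logLR over the early test
window — averaging rather than summing is immaterial for the sign — with
exact zeros broken by a seeded fair coin. Accuracy is summarized as the
plug-in mutual information of the 2x2 confusion matrix (base 2, so a
perfect balanced decode is 1 bit). No small-sample bias correction is
applied; with hundreds of trials and a binary variable the plug-in bias is
negligible, a documented limitation for very small sessions. Partitions
(mixed / pure / combined) come from the correct-trial selectivity classes,
and correct/error splits of the same decoder quantify how much reward-
direction information each partition loses on error trials; session-level
averages can be trial-count weighted (`bootstrap_stat(weights = )`).

## The population simulation

`simulate_correlated_poisson()` generates spike counts for 4-cell units —
mixed: one cell per trial type; pure: one cell per cue identity — with
Poisson marginals \(\lambda_{pref}\) on preferred and \(\lambda_{unpref}\)
on unpreferred trials. Noise correlation uses a Gaussian copula: latent
normals with correlation \(\rho_{noise}\) between same-selectivity cells
(block equicorrelation; the structure beyond "same selectivity" is a
modelling choice exposed as configuration), mapped through the Poisson
inverse CDF. The copula preserves the marginals exactly but attenuates the
count-level correlation below the latent \(\rho\); both are reported since
they differ. Decoding uses the true generative rates — the point is the
coding geometry, not model fitting. The pure population's XOR accuracy
follows \(p^2 + (1-p)^2\) in the cue accuracy \(p\) (both cues right or
both wrong), while a mixed population decodes XOR as a single variable;
energy efficiency is XOR mutual information per expected spike.

Default sweep sizes are 200 repetitions of 2000 trials per configuration —
enough for Monte-Carlo standard errors in the fourth decimal — with larger
settings available through the arguments.

## Study conditions and problem sizes

The packaged study conditions, used by `run_pipeline()` defaults, the
acceptance checks and `scripts/acceptance.R`: 250 trials, 20% behavioral
errors, 60 cells (16 mixed, 12 pure-sample, 12 pure-test, 8 choice, 12
movement-only), `error_degradation = 0.9`, five train/test splits, 10 CV
folds. A full run takes a few minutes on one core. The headline simulation
condition is \(\lambda_{pref} = 2\), \(\lambda_{unpref} = 1\), 8 cells,
\(\rho_{noise} = 0.1\).

## Design choices that were genuinely open

- **Where information is classified.** Sample/test information mix in the
  test segment, so classification uses the early test window; the late
  delay window serves the memory-conditioned comparisons.
- **logLR units and clamp.** Natural log, clamp ±50; recorded in output
  metadata.
- **Velocity z-scoring** is per session (the trajectory generator emits
  session-scaled velocities); per-trial scaling would erase slow
  cue-dependent running differences the behavioral decoders look for.
- **Class imbalance** in behavioral decoding is handled by seeded
  subsampling of the majority class, matching the equal-sampling rule used
  for choice attribution.
- **Ties at zero logit/logLR** are decoded by a seeded fair coin wherever
  they occur.
- **Persistence** uses a versioned plain-text session directory (CSV
  tables + JSON manifest) so sessions are diffable and dependency-free.

## Limitations

The pipeline inherits the encoding model's assumptions: Poisson noise,
conditional independence across cells given task and movement, and
position/velocity tuning expressible in the raised-cosine bases. The
generator satisfies these by construction; real data violate them in
degree. Decoded MI on small error-trial counts is noisy — the bootstrap on
the mixed-minus-pure gap difference is the guard, not the point estimate.
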