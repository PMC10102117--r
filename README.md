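# mixedsel

Analysis of **nonlinear mixed selectivity** in neural populations recorded
during a virtual-navigation delayed match-to-sample task — and a synthetic
session generator so the whole chain runs without animal data.

In the task, a mouse sees a binary sample cue (black/white, `S = ±1`),
holds it across a variable delay, meets a binary test cue configuration
(`T = ±1`), and is rewarded for the turn given by the XOR combination
`S*T` (equal to the choice `C` on correct trials). The package asks how
single cells and populations encode `S`, `T`, and `S*T`:

- **Encoding models.** Per-cell Poisson GLMs of 10-frame event counts with
  signed raised-cosine position bases per task-variable subset (offset, S,
  T, C, and their interactions; 163 or 287 predictors) plus raised-cosine
  velocity tuning, fitted by elastic net (α = 0.95) with condition-
  stratified 10-fold cross-validation and the λ<sub>1se</sub> rule;
  goodness of fit as the fraction of deviance explained (FDE) on held-out
  trials.
- **Single-trial information.** Sign-adjusted log-likelihood ratios
  log P(r | V = +1, movement) / P(r | V = −1, movement), marginalized over
  the unobserved task variables with outcome-proportion weights
  P<sub>c</sub>/2 and P<sub>e</sub>/2, for V ∈ {sample, test, XOR}.
- **Selectivity classes.** Polar decomposition of cue information
  (r, θ), noise floor ε = 0.01, seven angle bins; mixed selectivity is
  15° ≤ θ < 75°; the nonlinearity index
  NI = |(kr<sub>B/BW</sub> − kr<sub>B/WB</sub>) − (kr<sub>W/BW</sub> −
  kr<sub>W/WB</sub>)| separates conjunctive from additive tuning.
- **Population decoding.** Conditionally independent population
  likelihoods, decoded identity = sign of the population logLR,
  accuracy as confusion-matrix mutual information (bits), partitioned into
  mixed / pure / combined sub-populations and correct/error trials.
- **Population simulation.** Correlated Poisson populations via a Gaussian
  copula (4-cell mixed or pure units), comparing XOR and cue decoding
  accuracy and XOR bits per spike, including the pure-population
  prediction p² + (1−p)².
- **Behavior.** Choice-bias indices, cross-validated logistic decoding of
  cues/choices from running velocities, choice-attribution regression,
  trial-count-weighted performance averages, bootstrap tests with
  Bonferroni helpers.

## Worked example

```r
library(mixedsel)

cells <- make_cells(error_degradation = 0.9, seed = 142)  # 60 cells, 5 classes
report <- run_pipeline(pipeline_config(seed = 42, cells = cells))
print(report)
```

```
Pipeline report: 250 trials, 60 cells (60 converged), 247.1 s
Class fractions:

      mixed       noise pure_sample   pure_test
      0.267       0.333       0.200       0.200
Ground-truth recovery:
      mixed pure_sample   pure_test
          1           1           1
Population XOR MI (bits):
 partition    mi mi_correct mi_error
     mixed 0.674      0.999    0.031
      pure 1.000      0.999    0.998
  combined 1.000      0.999    0.998
MI gap difference (mixed - pure): 0.967 (p = 0.0005)
```

Reading this: all 60 encoding models converged; every ground-truth
pure-sample, pure-test and mixed cell was assigned its own class from the
fitted models (choice and movement cells fall into `noise` on the cue-
information axes, as they should). On correct trials both the mixed and
pure sub-populations decode the reward direction almost perfectly
(≈1 bit). On error trials the mixed population — whose selectivity the
generator degrades by 0.9 when the animal errs — collapses to 0.03 bits
while the pure population keeps 0.998 bits, so the correct-minus-error MI
gap is specific to the mixed population (difference 0.97 bits, bootstrap
p = 5×10⁻⁴).

The simulation counterpart:

```r
popsim_sweep(data.frame(lambda_pref = 2, lambda_unpref = 1,
                        n_sets = 2, rho_noise = 0.1),
             n_trials = 2000, n_reps = 200, seed = 11)
```

gives XOR accuracy 0.736 (mixed) vs 0.658 (pure), cue accuracy 0.783
(pure) vs 0.736 (mixed), and XOR bits/spike 0.0167 (mixed) vs 0.0061
(pure): a mixed population reads out the nonlinear variable better and
cheaper, a pure population the linear ones.

## Package layout

- `R/trials.R`, `R/trajectory.R`, `R/cells.R` — synthetic task, maze and
  activity generator
- `R/design.R`, `R/glm_fit.R` — basis expansion and encoding models
- `R/information.R`, `R/selectivity.R` — logLR information, classification,
  nonlinearity index
- `R/population.R`, `R/stats.R` — population decoding, correlations,
  bootstrap
- `R/popsim.R` — copula population simulation
- `R/behavior.R` — behavioral statistics
- `R/io.R`, `R/pipeline.R` — session persistence and the end-to-end driver
- `vignettes/mixed-selectivity-methods.Rmd` — models, assumptions, design
  choices, limitations
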