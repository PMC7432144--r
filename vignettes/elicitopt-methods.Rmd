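---
title: "Surrogate modeling and evolutionary optimization of elicited paclitaxel yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modeling and evolutionary optimization of elicited paclitaxel yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitopt)
```

## The problem

Hazel (*Corylus avellana*) cell suspension cultures produce paclitaxel, and
fungal elicitors sharply increase that production. An elicitation experiment
varies four culture inputs — the dose of fungal cell extract (CE, % v/v), the
dose of culture filtrate (CF, % v/v), the culture day on which the elicitor is
added, and the day the culture is harvested — and measures five responses: dry
weight (g l⁻¹), intracellular paclitaxel (µg g⁻¹ DW), extracellular paclitaxel
(µg l⁻¹), total paclitaxel yield (µg l⁻¹), and the extracellular (secreted)
portion (%). The modeling question is twofold: which inputs matter, and what
input settings maximize each response?

`elicitopt` implements the workflow used in this literature: a first-order
multiple linear regression with backward elimination as the interpretable
baseline, and a small multilayer perceptron (MLP) as the accurate surrogate,
with a genetic algorithm (GA) doing double duty — choosing the MLP's
hidden-layer size and then maximizing the fitted surrogate over the culture
inputs. Input importance is ranked by variable sensitivity ratios (VSR).
Because raw flask-level data of this kind are typically unpublished, the
package ships a synthetic experiment generator with known ground-truth
surfaces, so the whole pipeline is testable end to end and optimization
accuracy can be judged against a known optimum.

## The synthetic experiment

`design_config()` reproduces a randomized complete block factorial: 10 blend
levels (CE:CF ratios 100:0, 75:25, 50:50, 25:75, 0:100, plus the same five
ratios of inert water:PDB controls), total concentrations 2.5, 5 and 10 % v/v,
elicitor addition on day 13 or 17, harvests every 2 days after elicitation up
to day 23, and 3 replicate blocks — 720 flask observations. Control blends are
coded `ce_conc = cf_conc = 0` whatever their nominal volume: water and spent
medium carry no microbe-associated molecular patterns, so they cannot elicit.
Harvest day is an absolute culture day, not time since elicitation; elapsed
time is derived afterwards by `elapsed_time()`.

`surface_params()` defines the ground truth the generator samples from:

* **dry weight** — logistic growth in harvest day (baseline 2, plateau
  12.5 g l⁻¹, midpoint day 14, scale 2.2 d), mildly inhibited in proportion to
  total elicitor dose, with a small adding-day offset;
* **intracellular paclitaxel** — a correlated bivariate Gaussian dose hump
  (optimum near CE 3.4, CF 5.3 % v/v, widths 3.2, interaction ρ = −0.25),
  amplified by later elicitation and modulated by a transient harvest-day peak
  around day 20;
* **extracellular paclitaxel** — a second dose hump (optimum near CE 5.2,
  CF 5.7) with a saturating, monotone secretion rise in harvest day;
* **total yield** and **portion** — derived by mass balance,
  `total = intra × dw + extra` and `portion = 100 × extra / total`, before any
  noise.

The hump-shaped dose responses put the dose optimum in the interior of the
design region — the case in which surrogate-based optimization is actually
informative — while growth and secretion kinetics give boundary optima in the
timing inputs, matching the qualitative structure reported for real
elicitation data. Measurement noise is additive Gaussian, independent per
response and row, with standard deviation 10 % of each noiseless response's
spread over the design (`noise_frac = 0.1`), clipped at zero; a per-replicate
block offset is available (`block_sd`) but defaults to 0. What the generator
does **not** emulate: heteroscedastic assay error, correlated errors within a
flask's five responses, batch drift between blocks, and biological
outliers. Green tests on this generator therefore certify the algorithms and
their implementation, not the fit of any particular real data set.

## Regression baseline

`fit_mlr()` is ordinary least squares with intercept (delegated to
`stats::lm`); `backward_eliminate()` iteratively refits after dropping the
single non-intercept term with the largest p-value above α = 0.05 until all
retained terms are significant. The intercept is never a removal candidate,
matching standard practice in this literature, and removal is one term per
iteration — the conventional reading of "backward regression". p-values use
n − k degrees of freedom. Component importance is the absolute t statistic
(`rank_terms_by_t()`), with ties keeping the original column order. The
unit tests verify the whole path against a brute-force normal-equations
solve, so the `lm` delegation is checked, not trusted.

## The perceptron surrogate

`mlp_fit()` trains a three-layer network — four inputs, one hidden layer of
hyperbolic-tangent (tansig) units, one linear (purelin) output — by
full-batch back-propagation on the mean squared error of scaled targets.
Numerical choices, all stored in the model object:

* inputs and target are min–max scaled to [−1, 1] on the training ranges
  (tansig saturates otherwise); `predict()` applies the stored scalers, so
  scaling is part of the model's contract;
* weights start uniform in [−0.5, 0.5] from a recorded seed; training is
  bit-reproducible given data and seed;
* the update is gradient descent with momentum 0.9 plus an adaptive learning
  rate: a step that would raise the batch error by more than 4 % is rejected
  (learning rate × 0.7, momentum reset), otherwise accepted with the rate
  growing 5 % on improvement. The documented consequence is that the accepted
  training-error trace is non-increasing up to that 4 % factor — a property
  the tests assert;
* early stopping monitors a 15 % validation split of the training rows with
  patience 1200 epochs (cap 12 000); the best-validation weights are
  returned. The generous budget matters: optimizing over an undertrained
  surrogate recovers a biased optimum even when test R² looks respectable.

Defaults were chosen for the 500-row training sets of the default design; a
fit takes seconds. Divergence (non-finite error) raises an error suggesting a
smaller learning rate rather than returning garbage.

## The genetic algorithm

`ga_optimize()` is a real-coded GA with the configuration conventional in
this application: population 50, 500 generations, crossover 0.85, mutation
0.01, roulette-wheel selection, one elite. Encoding choices: arithmetic
(per-gene convex blend) crossover; Gaussian mutation with sd 10 % of each
gene's range, clipped to bounds; selection weights are min-shifted fitness
(predictions can be negative). Constraints enter as an additive penalty
proportional to the violation, with the penalty scale frozen after the first
generation so a chromosome's penalized fitness never depends on when it is
evaluated — that is what makes the elitist best-fitness trace provably
monotone, an invariant asserted on every run. The returned optimum is the
best *strictly feasible* chromosome seen during the whole run, so reported
optima satisfy constraints exactly rather than up to the penalty trade-off.

`select_architecture()` searches hidden-layer sizes with an integer-rounded
gene. A candidate's fitness is its RMSE on an inner validation split carved
from the training rows only — the test subset is never touched during
architecture search — with a fixed training seed per candidate and cached
evaluations (there are at most a dozen distinct sizes, so the GA mostly
re-reads its cache).

## Optimizing culture inputs

`optimize_inputs()` maximizes the surrogate over the four inputs subject to
`harvest_day ≥ adding_day`. Two further restrictions, both motivated by the
same principle — *only search where the data constrain the surrogate* — are
applied by the pipeline and exposed as arguments:

* **total-dose cap** (`max_total_conc`): factorial blend designs sample doses
  on the simplices `ce + cf = concentration`, so the high-CE **and** high-CF
  corner of the bounding box is never observed. An unconstrained search
  reliably wanders there and returns extrapolation artifacts. The pipeline
  caps `ce + cf` at the largest total concentration in the data;
* **snap-to-level** (`snap_levels`): an input observed at only a few discrete
  settings (the adding day: 13 or 17) gives the surrogate no information
  between those settings, and a flexible network can place a spurious
  interior optimum there that test-set accuracy cannot detect (the test set
  contains the same two levels). The pipeline therefore optimizes any input
  with ≤ 3 distinct observed values over exactly those values. Continuous
  search over the full box remains the function's default for users who want
  it.

## Sensitivity analysis

`vse()` is the model's RMSE when one input is made unavailable —
implemented deterministically as mean-substitution of that column —
evaluated, by convention, on all data rows (training and testing together).
`vsr_report()` divides each VSE by the base RMSE to give the raw VSR and
rescales to [0, 1] as `(VSR − 1)⁺ / max(VSR − 1)⁺`, anchoring "no effect" at
0 and the dominant input at 1. The raw and scaled rankings are identical
because the rescaling is monotone; published VSR tables in this area do not
state their exact rescaling arithmetic, and only the ranking is used
downstream, so the anchored form was chosen for interpretability. A
permutation mode (shuffle the column instead of substituting its mean) is
provided as an independent perturbation scheme; the test suite requires the
two modes to agree on constructed examples with known importance order.

## Worked reporting arithmetic

Optima are reported the way practitioners state them: `blend_summary()`
converts a (CE, CF) dose pair into a total concentration and an integer blend
label (CE share rounded half-up from the unrounded dose ratio, CF share its
complement, so labels always total 100); `elapsed_time()` converts the
adding-to-harvest interval into hours and a rounded "H h and M min" string.
For example:

```{r arithmetic}
blend_summary(3.33, 5.25)   # 8.58 % v/v of 39CE:61CF
elapsed_time(17, 20.27)$text
```

## End-to-end run

`run_full_pipeline()` wires the stages together for all five responses and
returns the regression-vs-perceptron comparison, sensitivity reports and
optima; `export_estimator()` writes any fitted perceptron to a self-contained
JSON file (weights, scalers, metadata) that reproduces predictions exactly,
and `render_formula()` emits the same network as one closed-form arithmetic
expression for spreadsheet users.

```{r pipeline, eval = FALSE}
report <- run_full_pipeline(seed = 1, hidden_range = c(4, 6, 8, 10))
report$comparison
report$responses$total$optimum
```

On the default synthetic conditions the perceptron's test-subset R² exceeds
the backward regression's for every response — the qualitative contrast that
motivates the surrogate — and the GA optimum of the total-yield surrogate
lands within a few percent of each input's range from the true optimum of the
noiseless surface (verified against a dense-grid oracle, `true_optimum()`).
The test suite and `scripts/acceptance.R` recompute these statements; this
vignette makes no empirical claim beyond what they compute. Problem sizes
used there: the default 720-row design, 20-seed replications for the
stochastic properties, and dense grids at step 0.25 for the oracle.

## Known limitations

* The regression is first-order: no interaction or quadratic terms, by
  design, to match the baseline it reproduces.
* Full-batch gradient descent with momentum is slower per unit of accuracy
  than second-order trainers (Levenberg–Marquardt); it was chosen for
  determinism and zero dependencies. The architecture search assumes a
  modest candidate range (1–15 hidden units).
* VSE's mean-substitution convention understates the importance of inputs
  whose effect is strong only away from their mean; the permutation mode is
  the cross-check.
* With only two sampled adding days, nothing in the data identifies the
  response between day 13 and day 17; the snap-to-level policy makes that
  limitation explicit rather than hiding it behind a continuous optimum.
* Five single-output networks are fitted independently; the mass-balance
  identity linking `total` to `intra`, `dw` and `extra` is used by the
  generator but deliberately not imposed on the fits, mirroring how the five
  responses are modeled separately in practice.
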