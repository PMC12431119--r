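---
title: "Methods: hybrid e-nose breath classification with optimized fuzzy logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid e-nose breath classification with optimized fuzzy logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, defaults and design choices behind
`enosefl`, in the spirit of a statistical-methods appendix: what is
computed, under which assumptions, and what the synthetic experiments can
and cannot tell you about real breath data.

## 1. The measurement model

A breath experiment is a 340 s multichannel recording from a hybrid
electronic-nose array: 8 metal-oxide-semiconductor (MOS) gas sensors read
as voltages across series load resistors, and 14 quartz crystal
microbalance (QCM) sensors read as resonance-frequency shifts. The
experiment has four phases — clean dry air `[0, 130)` s, breath-sample
delivery `[130, 170)` s, reaction with valves closed `[170, 200)` s, and a
cleaning cycle `[200, 340]` s. VOCs reacting on a heated MOS oxide surface
raise its conductance (voltage across the load resistor rises); molecules
adsorbing on a coated QCM crystal add mass and lower its resonance
frequency.

### QCM physics utilities

Under the small-load approximation the Sauerbrey relation links areal mass
to frequency shift, `Δf = -C_f Δm`, with sensitivity factor

```
C_f = 2 n f0^2 / sqrt(mu_q * rho_q)
```

(`mu_q = 2.947e11` g cm⁻¹ s⁻², `rho_q = 2.648` g cm⁻³ for AT-cut quartz).
The computation runs in CGS units and is reported in Hz·cm²/µg; the
fundamental-mode 5 MHz value is 56.6. The dissipation factor is
`D = w/f0` from bandwidth or `D = 1/(π Δf τ)` from the resonator decay
constant. The energy-ratio definition `D = E_dissipated / (2π E_stored)` is
a definition only and plays no computational role in the pipeline, so it is
documented here rather than implemented.

## 2. The synthetic generator

Real clinical recordings of this kind are not distributable, so the
generator (`breath_config()`, `simulate_breath()`) is a first-class,
tested module that emulates the statistical structure the analysis
assumes. Each channel of an experiment with class label `g` is

```
x_s(t) = baseline_s + m * A[g, s] * k(t) + eps(t)
```

* `k(t)` is the first-order response kernel: 0 before 130 s,
  `1 - exp(-(t-130)/tau_rise)` while the sample is present (130–200 s), and
  exponential decay `k(200⁻) exp(-(t-200)/tau_decay)` afterwards. Defaults
  `tau_rise = 15` s, `tau_decay = 25` s — rise times that saturate within
  the 70 s exposure window and decay that does not fully return to
  baseline by 340 s, the qualitative shape of MOS/QCM breath responses.
* `A` is the class × sensor amplitude table (volts for MOS, ≥ 0; hertz for
  QCM, ≤ 0). The default table is a fixed synthetic stand-in pinned in
  `inst/extdata/class_amplitudes.csv` (drawn once from moderate
  between-class perturbations around per-sensor base responses) so that
  tests and examples are reproducible. `effect_size` moves the class rows
  linearly away from their across-class mean: 0 collapses the classes,
  1 is the table as shipped, larger values increase separation. Signs are
  clipped to the physical constraint after scaling.
* `m ~ lognormal(0, subject_sd)` is one per-experiment subject multiplier
  shared by all channels, a multiplicative model of between-subject
  response scaling that keeps responses positive. Default
  `subject_sd = 0.15`.
* `eps` is iid Gaussian noise per sample, `sd = 0.01` V (MOS) and `0.5` Hz
  (QCM) by default.
* Cohort structure: 338 experiments — 219 LC and 119 healthy. The healthy
  split is not dictated by the cohort description, so the default is 60
  HnS / 59 HS, configurable.
* Sampling rate: 1 Hz default (341 samples); all feature windows are in
  seconds, so other rates are transparent.
* QCM channels are stored as shifts from each sensor's resonance
  frequency, so their clean-phase baseline is ≈ 0 Hz — the same quantity
  the reference correction produces.

**What the generator does not emulate:** per-VOC adsorption chemistry,
humidity/temperature drift (the measurement protocol holds these
constant), sensor aging, correlated noise, or day effects. Synthetic
results therefore validate the *pipeline* — its contracts, invariances and
optimization behaviour — not clinical performance. Reported cohort-level
accuracies from real studies are not reproducible here and are not
claimed.

## 3. Preprocessing

Reference correction subtracts the value at `t_ref = 130` s (nearest grid
sample if off-grid) so every channel is zero at the moment the sample
reaches the sensors. MOS voltage is converted to conductance
`G = v / ((V_C - v) R_L)` with the array's wiring defaults (TGS8xx:
`V_C = 24` V; TGS2xxx: `V_C = 5` V; per-sensor load resistors from 1 to
6 kΩ).

The order of the two MOS steps is genuinely ambiguous: the conductance
formula applied to a reference-corrected voltage can see `v ≤ 0`, where
conductance is undefined or negative. The default therefore converts the
*raw* voltage to conductance and then reference-corrects the conductance,
which is always well defined; `order = "literal"` applies the formula to
the corrected voltage (unchecked) for comparison.

## 4. Features

The MOS matrix has exactly 91 columns: 5 summary statistics × 8 sensors,
5 interval slopes × 8 sensors, 3 pairwise signed areas, and 8 areas under
the curve. This enumeration is the only reading of the published feature
list that reproduces the 91-column count, so the "gradient" features are
the five interval slopes (130–145, 145–170, 170–200, 200–215, 200–230 s).
Conventions chosen where none were stated:

* Moments are population (biased) variance, Fisher skewness and excess
  kurtosis, computed over a default response window of 130–230 s
  (delivery + reaction + early decay). A zero-variance window yields
  skewness = kurtosis = 0 by convention.
* Slopes are ordinary least-squares fits of value against time over the
  closed interval.
* Areas use the trapezoid rule on the native grid and are *signed* —
  "area between" two crossing curves is otherwise ill-defined, and the
  sign carries ordering information.
* One published area pair names a sensor ("TGS880") that is not part of
  the 8-sensor array; the default maps it to TGS816 (configurable via
  `mos_feature_config()`), and this substitution is deliberately visible
  rather than silently resolved.

The QCM matrix has exactly 7 columns: signed areas between (QCM6, QCM14),
(QCM2, QCM11), (QCM9, QCM11), (QCM14, QCM7); slopes of QCM11 and QCM6;
and the maximum of QCM5. The published QCM windows reference 100–140 s
even though delivery starts at 130 s; the window is therefore exposed as
configuration (default 100–140 s for all seven features) instead of
asserting one timeline. Concatenation of the two matrices gives the
98-column hybrid matrix; column counts are structural contracts that hold
for any dataset size.

## 5. Dimension reduction

`fit_pca()` retains the smallest number of leading components whose
cumulative explained-variance fraction reaches the threshold (default
0.90). `fit_lda()` implements classical Fisher LDA: eigenvectors of
`Sw⁻¹ Sb`, at most `classes - 1` components — exactly 2 for the three
breath classes, which is the (LD1, LD2) plane the fuzzy classifier uses.
Published tables sometimes report more LDA columns than `classes - 1`;
classical LDA cannot produce them, so this package documents the
discrepancy rather than inventing a variant. Numerical choices:

* `Sw` is regularized by `lambda I`, `lambda = 1e-6 * trace(Sw)/d`, when
  singular or ill-conditioned (`rcond < 1e-12`), which happens whenever
  features outnumber samples.
* Each component's largest-magnitude loading is made positive, a
  deterministic sign convention; components are unit-norm.
* When the within-class scatter is heavily regularized the *order* of the
  two discriminants can differ from other implementations; the spanned
  plane is the same (the test suite checks subspace agreement against
  MASS::lda rather than axis pairing).

Inside cross-validation the projection is refit on each training fold by
default; `transductive = TRUE` reproduces the alternative
reduce-then-split order, which leaks test information and is provided
only for comparison.

## 6. The fuzzy classifier

Each axis of the LD plane carries seven fuzzy sets — `O1, O2` (HS
region), `+1, +2` (HnS region), `D1, D2, D3` (LC region) — in one of five
families (Gaussian, generalized bell, triangular, trapezoidal, pi-shaped)
with standard closed forms. The 7 × 7 rule base maps each (LD1 set, LD2
set) cell to a class; the bundled expert table is shipped as a CSV (rows =
LD2 sets, columns = LD1 sets) and a data-driven constructor assigns each
cell the majority class of the training points whose maximal memberships
select it, with empty cells inheriting the nearest occupied cell's
consequent.

Inference choices (the originating system leaves these unstated, so they
are documented defaults, not claims):

* **t-norm min, aggregation max** — classical Mamdani max–min, the most
  common default for rule-table classifiers.
* **Crisp argmax** of the aggregated class scores; consequents are class
  labels, so no defuzzification surface exists.
* **Tie-break order** LC > HnS > HS, configurable and deterministic.
* **Zero coverage:** finite-support families can leave a point with all
  49 rule strengths zero; such a point inherits the consequent of the
  cell whose pair of MF centres is nearest in the LD plane, so every
  sample receives a label.
* The pi-shaped family is the standard S × Z spline product with
  shoulders `(a, b)` and `(c, d)` and plateau `[b, c]`.

Initialization divides each class's span on each axis (min–max of its
training points) into as many equal parts as the class has sets, centring
one MF per part: Gaussian `sigma = w/2`, gbell `(a, b) = (w/2, 2)`,
triangular/trapezoidal/pi supports extending one sub-interval either side
so neighbouring sets overlap. A zero-width class region is an error.

## 7. Membership-function optimization

The 14 MFs' parameters are flattened into one vector (length 28–56
depending on family) and tuned to maximize training accuracy with the rule
base held fixed. Bounds: positions and breakpoints may roam half an axis
range beyond the observed span; widths live in `(1e-6 × range, range]`;
the gbell exponent in `[0.5, 10]`. Every candidate is repaired before
evaluation — clipped, breakpoints sorted within each MF, widths floored —
so the objective only sees feasible vectors. The initial
(equal-partition) system is seeded into every optimizer's starting
population, which with elitist best-so-far tracking guarantees the tuned
model never scores below the initial one.

Optimizer defaults (250 iterations each):

* **GA**: population 60, tournament size 3, single-point crossover at
  rate 0.8 (two-point available), per-gene Gaussian mutation at rate 0.05
  with `sigma = 0.1 × range`, elitism 2.
* **PSO**: 50 particles, inertia decaying linearly 0.9 → 0.4 (constant
  0.7 available via `w_const`), `c1 = c2 = 1.5`, velocities clamped to
  ±range/2.
* **SA**: single solution, geometric cooling `alpha = 0.995` from a `T0`
  calibrated so the first observed worsening would be accepted with
  probability ≈ 0.8, Gaussian neighbourhood decaying geometrically from
  0.1 × range to 1e-4 × range. With a 250-evaluation budget a free-running
  chain at this cooling rate cannot converge (it accepts nearly all late
  uphill moves), so by default the chain is re-anchored to the incumbent
  after every step — an elitist annealed local search. Longer Metropolis
  excursions are available via `reanchor_every`.
* **IWO**: 50 weeds (also the population cap), 2–6 seeds per weed linear
  in fitness rank, dispersal spread decaying from 3.0 to 0.01 by the
  standard power law with modulation index 3.
* **AEO**: population 50. Each generation the worst individual performs
  production (a move between the best individual and a random point,
  weighted by an environment factor 0.5 and the remaining budget); every
  other individual performs, with probability 0.2, a decomposition move
  (Gaussian-scaled resampling around the best) and otherwise a consumption
  move — herbivore (eats the producer, p = 0.5/0.8), carnivore (eats a
  random better-ranked consumer) or omnivore (a mix). With probability
  0.1 per generation a fresh immigrant replaces the worst individual.
  This assigns one move and one evaluation per individual per generation
  — the published hyperparameter ratios mapped onto the canonical
  production/consumption/decomposition operators — followed by greedy
  selection.

All five methods are reproducible under a fixed seed, respect bounds at
every evaluation, and report the non-decreasing best-so-far history. On a
5-D sphere benchmark over `[-5, 5]` all five reach below 1e-2 within 250
iterations.

## 8. Evaluation protocol

`run_fl_protocol()` runs stratified `k = 5`-fold cross-validation repeated
`repeats = 10` times. Fold assignment depends only on labels and seed;
per-fold class counts deviate from proportionality by at most one. For
each repeat × fold, the LDA projection and the fuzzy system (rule base and
tuned MFs) are fitted on the training folds only and evaluated once on the
held-out fold — a narrative in which tuning iterates "until the test
results converge" would leak test data, so it is not the default; the
transductive projection order is available behind a flag for comparison.

Per-repeat accuracy is the mean over its folds; the reported mean, max,
min and standard deviation are taken over the 10 repeat means
(`aggregate = "fold"` switches to the 50 fold-level accuracies; which of
the two the published tables use is not stated). The pooled 3 × 3
confusion matrix yields one-vs-rest sensitivity and specificity for LC.
Baseline classifiers (rpart decision tree, e1071 SVMs with linear and
polynomial degree-2/3 kernels, class::knn with k = 5 on standardized
features, randomForest with 200 trees) run under the identical protocol;
their hyperparameters are unstated upstream, so these documented defaults
are fixed for reproducibility.

Every run is deterministic given its seed manifest: the fold seed is
`seed + 7919 r` and each fold's tuning seed `seed + 1000 r + f`, so a
report can be reproduced byte for byte.

## 9. Problem sizes in the test suite

The bundled checks run on reduced problem sizes chosen to exercise every
code path at desk scale: synthetic datasets of 4–90 experiments, optimizer
budgets of 10–60 iterations with populations 10–30 for protocol tests, and
the full 250-iteration defaults only on the cheap sphere objective. The
well-separated end-to-end fixture uses 90 experiments (50/20/20) at
`effect_size = 1.5`, low noise and `subject_sd = 0.03`, seed 42. These are
the package's own choices of demonstration scale; the defaults users get
(`breath_config()`, `opt_spec()`) remain the full study conditions.

## 10. Known limitations

* The fuzzy classifier operates only on a 2-D plane; feeding it more
  dimensions requires reducing first.
* The synthetic generator's class structure is linear-Gaussian-like after
  feature extraction; real breath data exhibit heavier tails, drift and
  batch structure the generator does not produce.
* Fitness is raw training accuracy — a step function of the parameters —
  so optimizers see plateaus; ties are resolved by elitism and the
  first-found-best rule, which keeps runs deterministic but means several
  parameter sets can be equally "best".
* The rule-base constructor needs at least one training point in the
  vicinity of the cells it labels; with very small training sets many
  cells inherit a neighbour's consequent.
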