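---
title: "Memory capacity of connectome reservoirs: model, synthetic cohorts, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory capacity of connectome reservoirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`reservoirMC` treats a subject's anatomical connectome — a symmetric,
nonnegative, zero-diagonal matrix $W$ over $N_r$ regions — as the coupling
matrix of an echo-state reservoir with $\tanh$ units:

$$\mathbf r(t+1) = \tanh\!\big(\mathbf W_{\mathrm{in}}\,u(t) + W\,\mathbf r(t)\big),
\qquad \mathbf r(1) = \mathbf 0 .$$

The drive $u(t)$ is i.i.d. uniform on $(0,1)$ for $T$ steps (default
20{,}000) and is fed identically to all regions through an input vector
$\mathbf W_{\mathrm{in}}$ with standard-normal components. $W$ is divided by
its largest singular value before simulation, which for a symmetric matrix
equals its spectral radius; with $\tanh$ units this keeps every state in
$(-1,1)$ and the dynamics at the edge of stability, where linear memory is
maximal. The first 5% of steps are discarded: the invariant
$\lfloor 0.05\,T\rfloor \ge \tau_{\max}$ guarantees every delayed target is
defined on the retained series.

For each delay $\tau$ a linear readout is trained by ridge-free
least squares, $\;W_{\mathrm{out}} = \mathbf y_\tau R^{\mathsf T}
(R R^{\mathsf T})^{+}$, with the pseudoinverse truncating singular values
below $10^{-12}\sigma_{\max}$ (the minimum-norm solution; rank-deficient
state matrices are handled, never an error). The forgetting curve is the
Pearson correlation $\rho(\tau)$ between the reconstruction and
$y_\tau(t) = u(t-\tau)$, and memory capacity is

$$\mathrm{MC} \;=\; \sum_{\tau=6}^{35} \rho(\tau),$$

summed **unsquared and unclipped**. The classic definition of linear memory
capacity uses $\rho^2$; both are available (`squared`, `clip_negative`), but
the plain-$\rho$ sum is the default because it is the quantity the rest of
the pipeline consumes. Delays 1–5 are excluded from MC because any
reasonably connected normalized network reconstructs them almost perfectly
(the acceptance suite checks $\rho(\tau) > 0.9$ for $\tau \le 5$ at 30%
density), so they carry no individual differences; beyond $\tau = 35$
reconstruction fails for all networks. MC is averaged over `n_trials`
(default 10) independent drives.

Evaluation is **in-sample**: $\rho$ is computed on the same post-washout
series the readout was trained on. With $n_{\mathrm{signal}} = 19{,}000$
points and at most 94 regressors the optimism is small at the full
protocol; at the reduced protocols used in tests it inflates all MC values
by a common additive amount, which cancels from every between-subject and
between-group contrast (the statistical layer only ever uses such
contrasts).

### Drives are shared, not per-subject

All drive substreams are keyed on `(master_seed, trial)` only. Every
subject, every density, and every lesioned network in a run therefore sees
the *same* input realizations, so group differences, density profiles and
lesional deltas are never confounded by drive sampling noise. For lesional
capacities the input-weight vector of the full network is subsetted rather
than redrawn (`drive_dim` / `drive_subset`), so deleting a region changes
only the structure, not the drive.

### Regional and lesional capacity

Regional MC restricts the readout to a single region's activation row (a
scalar least-squares problem). Lesional MC is
$\Delta\mathrm{MC}_i = \mathrm{MC}(W) - \mathrm{MC}(W_{-i})$ with the
lesioned network re-normalized to unit spectral norm before simulation —
the lesioned matrix would otherwise have spectral radius below 1 and the
contrast would mostly measure the lost norm rather than the lost structure.
This re-normalization is a package choice and can be bypassed by calling
`global_memory_capacity()` on an un-renormalized lesioned matrix directly.
Note that lesioning removes the region from the *readout* as well as from
the coupling: even an isolated region contributes a (memoryless) regressor,
so its lesional delta is the in-sample value of that regressor, not exactly
zero.

## Network preparation

* `consistency_filter()` implements cohort-level edge selection by
  coefficient of variation: for each edge present in at least one subject,
  $\mathrm{CoV} = \mathrm{sd}/\mathrm{mean}$ across subjects (absent edges
  count as weight 0), and edges at or below the stated CoV percentile
  (default the 10th) are retained. Ties at the cut are kept. The percentile
  is computed over edges present in at least one subject, not over all
  possible pairs. Note that an aggressive percentile leaves fewer edges
  than high target densities require; the pipeline records unreachable
  densities as missing rather than extrapolating.
* `threshold_by_density()` keeps the $k = \lfloor d\,N_r(N_r-1)/2\rfloor$
  strongest undirected edges *at their original weights* (never
  binarized). Ties break deterministically by (weight descending, row,
  column), which makes retained sets nested across densities.
* `spectral_normalize()` is applied after thresholding, so every analyzed
  network has unit spectral norm at every density.
* On input, asymmetry up to $10^{-9}$ is repaired by averaging; anything
  larger is an error, as are negative weights and NaNs.

## The synthetic cohort generator

Real lifespan cohorts with diffusion tractography are access-restricted, so
the generator produces cohorts with the statistical structure the analysis
assumes. Its design is the scientifically load-bearing part of the package
and was chosen as follows.

**Shared template.** All subjects of a cohort share an anatomical template:
94 regions placed uniformly in a unit cube, grouped into spatial modules
(k-means on the coordinates, 13 modules by default), with
$\mathrm{round}(\text{base\_density}\cdot\binom{N_r}{2})$ edges drawn with
probability decaying with distance and down-weighted across module
boundaries. A subject is the template with per-edge multiplicative
log-normal variation (`subject_sd`, default 0.35). Without shared anatomy,
per-region statistics across subjects would be meaningless — as they would
be in a real cohort without a common atlas.

**Heavy-tailed weights.** Template weights are log-normal
(`weight_sigma = 2` by default) damped by distance, scaled to a maximum
of 1 — the heavy-tailed, rich-club-like weight distribution of
streamline-count connectomes. This choice matters dynamically: after
spectral normalization, the reservoir's long-delay memory lives in the
ratio between sub-dominant and dominant spectral structure. During design
we found that with light-tailed (Beta-like) weights, preferentially
attenuating weak edges leaves MC unchanged or even *raises* it: the
least-squares readout is scale-invariant per regressor, and deleting weak
edges moves the network toward its sparse strong skeleton, which in this
model class has *higher* MC. With heavy-tailed weights, the noisy
multiplicative degradation (below) disperses the spectral ratios and
robustly *lowers* MC with age — the empirically observed direction. The
base weight law is configurable, but the default is the regime in which
the aging phenomenon exists.

**Aging law.** Each edge weight $w \in [0,1]$ ages as

$$w \mapsto w\,\exp\!\big(-r\,a\,(1-w)^{b}\,\varepsilon\big),
\qquad \varepsilon = e^{\mathcal N(0,\sigma_\varepsilon^2)},$$

with rate $r$ (default 0.025/year), age $a$, weak-edge bias $b$ (default 3:
the strongest edges are spared, degradation concentrates on weak,
peripheral connections) and per-edge log-normal noise $\sigma_\varepsilon$
(default 1). The factor is in $(0,1]$, exactly 1 at age 0, monotone in age
for a fixed noise draw, and preserves symmetry and the zero pattern. The
*heterogeneity* of degradation ($\sigma_\varepsilon$), not its mean, is
what drives the memory-capacity decline; with $\sigma_\varepsilon$ near 0
and $b = 0$ the law is pure scaling and spectral normalization cancels it —
a useful null.

**What the generator does and does not emulate.** It reproduces: symmetric
nonnegative 94-region matrices with realistic density (0.35), heavy-tailed
weights, spatial modularity, shared anatomy with individual variation,
age-graded weak-edge degradation, group (young/old) and continuous-age
cohorts, and cognitive scores coupled to mean network integrity with
additive noise. It does **not** emulate: real atlas geometry or tract
anatomy, hemispheric symmetry, measurement artifacts of tractography
(distance bias, false positives), head motion, or any true biology of
aging. Passing tests on these cohorts show the *pipeline* behaves correctly
under the stated statistical structure; they are not evidence about real
brains.

**Localized degeneration scenario.** For planted-signal validation of the
regional inference, `planted_module()` selects a complete spatial module of
5 regions whose strength is mostly internal, excluding modules that touch
the 20 strongest edges (degrading those would change the normalization of
the whole network and leak the effect everywhere) and penalizing modules on
which any outside region depends for a large share of its own strength
(degrading the module's incident edges would otherwise carry a genuine
effect into that region). Setting
`affected_regions` restricts the aging law to edges incident to the module.
In this scenario a moderately modular, lighter-tailed configuration
(`weight_sigma = 0.75`, `module_mixing = 0.12`, `between_scale = 0.25`) is
used so that every region has a meaningful regional capacity baseline, and
`isolate_affected = TRUE` severs the template's edges between the module
and the rest of the network. Isolation is what makes the scenario's premise
literally true: with any residual coupling, regions outside the module
genuinely degrade too (they lose their edges into the module, and their
states read degraded module states), and at $n = 200$ with shared drives
the regional test is powerful enough to flag those real secondary effects
— they are not false positives of the statistics, but they falsify the
premise that only five regions carry the effect. Planted regions respond with either sign — attenuating a
saturated region's input can *raise* its regional capacity by moving its
unit into the linear range — which mirrors the empirically observed mix of
negative and positive regional age associations.

## Statistical layer

* **Permutation test** (`permutation_group_test`): statistic
  $\bar a - \bar b$; labels shuffled without replacement; two-tailed p with
  the add-one convention $p = (1 + \#\{|s^\ast| \ge |s|\})/(n_{\mathrm{perm}}+1)$,
  so $p > 0$ always (10,000 permutations by default gives
  $p_{\min} = 1/10001$). `exact = TRUE` enumerates all assignments. Cohen's
  d uses the pooled standard deviation; the 95% CI of the difference is a
  percentile bootstrap (2,000 resamples) — a package choice, since only the
  existence of a CI, not its construction, is standard here.
* **Band AUC** (`band_auc`): trapezoidal integration of MC over the density
  bands low 2–10%, medium 11–20%, high 21–30% (percent units, closed
  ranges as printed; the 10→11 and 20→21 gap trapezoids belong to no band).
* **Regional age association**: partial Pearson correlation between
  regional MC and age, both residualized on sex, then Benjamini–Hochberg
  across regions at $q = 0.05$. Constant regions get $p = 1$ rather than
  NaN. Pearson (not Spearman) is the default.
* **PLS-VIP** (`pls_vip`): PLS1 by NIPALS with deflation on standardized
  predictors and response; the latent-variable count is caller-supplied
  (4–5 is typical for cognition models). VIP
  $= \sqrt{P\,\sum_a \mathrm{SS}_a w_{ja}^2 / \sum_a \mathrm{SS}_a}$;
  mean squared VIP is identically 1, so VIP > 1 marks above-average
  contributors.
* **MLP age prediction** (`cross_validate_predictor`): four ReLU hidden
  layers (256, 512, 512, 256), 10% inverted dropout between hidden layers,
  Adam at $5\times10^{-4}$, batch 64, 100 epochs, epoch checkpoint with the
  lowest validation loss, MAE loss with linear output for regression and
  binary cross-entropy with sigmoid output for classification. Each of the
  10 folds draws an age-stratified 80/10/10 split (order subjects by the
  stratification variable, partition into as many contiguous strata as
  test subjects, draw one per stratum; at $n = 636$ this yields
  508/64/64). Min–max scaling is fit on the training set only; regression
  targets are scaled to $[0,1]$ with the training range and predictions
  mapped back. Hidden activation (ReLU), the per-fold rotation, and the
  0.5 classification threshold are package choices where the recipe is
  otherwise underdetermined. The implementation is plain R matrix algebra —
  the model is small enough that a deep-learning framework would add
  nothing but a dependency.

## Numerical choices and degenerate inputs

* Degenerate correlations (constant prediction or target) are defined as 0,
  never NaN.
* Pseudoinverse cutoff $10^{-12}\sigma_{\max}$; no ridge.
* `threshold_by_density` warns and returns the input unchanged if the
  target exceeds the available density; a target yielding zero edges is an
  error.
* All randomness flows through explicit integer substreams
  (`substream_seed`) derived from user-visible seeds; no global RNG state
  leaks between calls (`with_seed` restores the caller's state). Identical
  seeds give bit-identical results on one platform.
* The spec-level arithmetic anchors hold exactly: 19,000 retained steps at
  $T = 20{,}000$ with 5% washout; 1,311 edges at 30% density for 94
  regions; 508/64/64 splits at $n = 636$.

## Problem sizes used in the test suite

The full protocol ($T = 20{,}000$, 10 trials, 30 densities) is used where a
single network is measured. Cohort-level checks run a reduced protocol —
$T = 2{,}000$, 2 trials, and only the density bands under test — with
cohorts of 60/60 (group contrast), 200 (regional inference; three replicate
cohorts in the test suite, six in the acceptance script) and 60/60 (classification). These sizes give the statistical
properties under test comfortable margins while keeping a full run of the
suite to a few minutes; they are stated here so results can be reproduced
at exactly these conditions.

## Known limitations

* In-sample evaluation inflates absolute MC at short $T$; use the full
  protocol (or the optional held-out evaluation of contrasts) when absolute
  values matter.
* The homogeneous $\tanh$ activation treats all regions identically;
  region-specific gains or time constants are out of scope.
* The generator's aging effect is roughly constant across densities
  (slightly larger at high density); empirically the age gap grows more
  steeply with density than the synthetic model reproduces. Band-AUC
  contrasts remain ordered (high > low) but the synthetic density gradient
  is weaker than the real one.
* Nothing in the package should be read as evidence about real aging; it is
  a measurement instrument plus a simulation harness.
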