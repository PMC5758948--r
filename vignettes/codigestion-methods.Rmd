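---
title: "Methods: Taguchi optimization and neural modeling of anaerobic co-digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Taguchi optimization and neural modeling of anaerobic co-digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codigest)
```

## The problem

Anaerobic co-digestion (AcoD) ferments two complementary substrates — here
oil-refinery wastewater (ORWW), which is carbon-rich but nutrient-poor, and
chicken manure, a rich nitrogen source — to produce methane-bearing biogas.
Process performance depends on several interacting conditions: the ORWW
portion in the digester, temperature, ultrasonic pretreatment time, and
total-solids (TS) loading. A full three-level factorial over four factors
needs 81 runs; a Taguchi L9(3^4) orthogonal array covers the four main
effects in nine runs, each measured in triplicate for three responses:
biogas production yield (BGP, mL/gVS), biomethane yield (BMP, mL/gVS), and
the soluble-COD stabilization rate (CODS, %).

This package implements the complete analysis chain for such experiments —
S/N-ratio factor analysis, multiresponse desirability optimization, the
supporting process chemistry, a neural predictor of biogas yield and
methane content, and a synthetic-experiment generator used to validate the
chain end to end.

## The orthogonal array

`build_l9()` returns the nine-run design in a fixed canonical row order
with the packaged factor assignment (A = ORWW %, B = temperature, C =
sonication time, D = TS level). Two points deserve emphasis:

* **Level order is assignment order, not numeric order.** Sonication levels
  are 15, 30, 0 min, so designation "C3" means the *untreated* control.
  Sorting levels would silently scramble every downstream conclusion about
  pretreatment.
* **Validity is checked by exhaustive counting**, not by construction:
  `validate_design()` verifies that each level appears exactly three times
  per column and that all nine ordered level pairs occur exactly once for
  each of the six column pairs.

## Signal-to-noise analysis

For maximize-type responses the Taguchi larger-the-better statistic is

$$ S/N = -10 \log_{10}\left(\frac{1}{n}\sum_{i=1}^n \frac{1}{y_i^2}\right) \quad [\mathrm{dB}]. $$

Because $y_i$ enters squared, a negative response (an inhibited digester
accumulating hydrolysed COD, e.g. CODS = −263.42%) produces the same S/N
as its absolute value — a run that *failed* scores as if it had succeeded
spectacularly. `snr_ltb()` reproduces this literal behaviour by default
because the tabulated analysis it mirrors did so, but it warns loudly, and
`negative_policy = "exclude"` or `"floor"` are available for new analyses.
The signed CODS values always feed the analysis; `clip_for_display()`
(flooring negatives at zero) exists solely for plots.

### Reconstructing per-run S/N from mean ± SD

Replicate-level measurements are often published only as mean ± SD.
`snr_ltb_from_moments()` reconstructs the triplicate S/N through a
second-moment expansion:

$$ S/N \approx 20\log_{10} m - 10 \log_{10}\!\big(1 + 3\,(s/m)^2\big), $$

where $s$ is the **n-denominator (population) SD** of the replicates.
Under that convention the approximation is accurate to about ±0.02 dB for
CV ≤ 12% (verified by simulation in the test suite), and it reproduces
all nine tabulated biogas S/N cells of the packaged study within
0.009 dB. Had the printed SD been the n−1 (sample) convention, the correct
leading coefficient would be 2 rather than 3 and the tabulated cells would
be missed by up to 0.07 dB — which is how the convention was identified.

### Factor effects, ranking, optima

`effects_table()` averages each factor level's three runs (the balanced
design makes these unconfounded main-effect estimates), takes each
factor's range of level means, and ranks factors by range. Ties — which
the packaged data never produce — break deterministically: factor order
A < B < C < D for ranks, lowest level index for best levels.
`optimal_formulation()` is the per-factor argmax of level means; on the
packaged study it yields A2B1C2D1 for both gas yields and A1B3C3D3 for
CODS removal.

Report-facing dB values are conventionally rounded half-up to two
decimals; all internal computation keeps full precision. Two cells of the
reference factor-effects table were evidently computed from unrounded
intermediates (they differ by 0.01 dB from the printed per-run S/N), so
cell-level comparisons in the tests use a ±0.02 dB band with exact 2-dp
checks on unaffected cells.

## Multiresponse optimization

The published optimum came from numerical multiresponse optimization whose
internal model is unpublished. The surrogate here is deliberately the
simplest one consistent with an orthogonal main-effects design: per
response, prediction at any of the 81 formulations is

$$ \hat y(\ell_1..\ell_4) = \bar y + \sum_j \big(\bar y_{j,\ell_j} - \bar y\big), $$

the grand mean plus additive level-mean deviations, fitted on the raw run
means (not dB). This reproduces the published predicted yields at
A2B1C2D1 to within 0.1 mL/gVS (306.27 vs 306.21 for BGP; 155.24 vs 155.25
for BMP). It does **not** reproduce the published CODS prediction
(additive value 122.6 vs printed 68.35); the divergence presumably
reflects a transformation or exclusion of the negative-CODS runs inside
the original software, which cannot be recovered from the published
tables. The
package documents the divergence and makes no claim about CODS point
predictions.

Each response is scored by a one-sided Derringer–Suich ramp
$d = \mathrm{clip}((y-L)/(U-L), 0, 1)^w$ and combined as a weighted
geometric mean over responses. Default choices, made once:

* **Bounds** $L, U$ default to the observed min/max of the nine run means
  per response. This makes $d = 1$ attainable exactly when a formulation
  is predicted to beat every observed response, consistent with the
  reported desirability of 1.000 at the optimum. Bounds are configurable.
* **Weights and importances** default to 1 (the study reports none).
  Overall D is invariant to rescaling all importances.
* **Degenerate responses** (observed at a single value, possible in
  synthetic planted configurations) contribute neutrally ($d = 1$) since
  they cannot discriminate between formulations.
* Ranking ties break lexicographically by designation, so results are
  byte-reproducible.

`optimize_desirability()` evaluates all 81 formulations exhaustively —
with four three-level factors there is no reason to search approximately.

## Process chemistry

**COD solubilization.** `cods_stabilization()` is the signed percent
reduction $(\mathrm{COD}_{si}-\mathrm{COD}_{sf})/\mathrm{COD}_{si}\times100$;
negative values mean net accumulation and are preserved.

**Free ammonia.** The inhibitory, unionized fraction of total ammonia
nitrogen follows the NH$_3$/NH$_4^+$ equilibrium

$$ \mathrm{FAN} = \mathrm{TAN}\left(1 + 10^{-\mathrm{pH}}\cdot 10^{\,0.09018 + 2729.92/T}\right)^{-1}, $$

with $T$ in Kelvin (the exponent is the van't Hoff temperature dependence
of the ammonium pKa). The published typesetting of this relation is
ambiguous; this reading is the standard equilibrium form, keeps
FAN ∈ [0, TAN], is strictly increasing in pH and temperature, and
reproduces the literature observation that a pH shift from 7 to 8 raises
FAN roughly eight- to nine-fold at mesophilic temperature (the package
computes 9.04× at 36 °C). No worked FAN number is published, so the
equation is anchored by these properties rather than a point value. Ionic
strength and activity corrections are out of scope.

**Inhibition diagnostics.** `diagnose_series()` screens a kinetics time
series against configurable literature thresholds (`ad_thresholds()`):
FAN > 250 mg/L for mesophilic digestion at ≥10% TS, FAN > 700 mg/L
thermophilic, acetate > 800 mg/L together with propionate:acetate > 1.4
(digester-failure signal), TVFA > 5000 mg/L (rapid accumulation) and
> 12000 mg/L (pH suppression), and TAN inside the 1700–14000 mg/L band
reported as undesirable. Thresholds are configuration, not constants,
because they are regime- and substrate-dependent. Each raised flag cites
the first triggering record and the threshold that fired.

## The neural predictor

`train_lm()` fits a fully-connected 9-*h*-2 network — nine digester
kinetic inputs (TAN, FAN, TVFA, the four individual VFAs, temperature,
pH), tanh hidden units, linear outputs, both targets (BGP yield and BMP
content) trained jointly — by Levenberg–Marquardt:

$$ \Delta\theta = (J^\top J + \lambda I)^{-1} J^\top e, $$

with $J$ the residual Jacobian over the training split (computed
analytically). Defaults, chosen to follow the common toolbox conventions
for this training setup and stated here because they matter:

* per-variable affine normalization of inputs and targets to [−1, 1]
  (inverted transparently at prediction time);
* $\lambda_0 = 10^{-3}$, ×10 after a rejected step, ×0.1 after an
  accepted one; damping exhaustion beyond $10^{10}$ at a non-minimum is a
  convergence-failure error;
* random 70/15/15 train/validation/test split (sizes floored, remainder
  assigned train-first), early stopping after 6 epochs without validation
  improvement with reversion to the best-validation weights, at most 1000
  epochs;
* weight initialization uniform in [−0.5, 0.5]; every random choice is
  governed by one integer seed, making training bit-reproducible.

Reported metrics (`ann_metrics()`) are MSE per split, pooled Pearson R per
split and overall, and per-output R² — all on the original measurement
scale.

### Hidden-layer size selection

`architecture_search()` trains a candidate list (default: 5–50 by 5, then
the 16–19 refinement) on a shared split and `select_architecture()` picks
the winner: candidates whose validation or test MSE exceeds κ = 10 times
their training MSE are flagged as overfit (the memorization signature),
and the highest overall R among the remainder wins. Applied to the
packaged reference metrics table (`load_hidden_search()`), the rule
selects 19 hidden neurons and flags the 30- and 50-neuron candidates —
and also the 25-neuron one, whose test MSE is 16× its training MSE; the
κ = 10 rule is applied uniformly rather than tuned to flag exactly the
historically rejected pair.

The original study's training data (time-resolved measurements from its
eleven digesters) are not published, so its printed accuracy values are
not reproducible; the network here is exercised on synthetic data with
known ground truth instead, where noise-free generation must reach test
R² ≥ 0.99 for biogas yield.

## The synthetic-experiment generator

`generate_experiment()` emulates a nine-run, three-replicate batch
co-digestion campaign with known ground truth:

* **True responses** come from additive per-factor effect profiles. The
  default profiles are the additive decomposition of the packaged study's
  run means, so synthetic and packaged paths share shape — including
  negative CODS in the hot, solids-rich (inhibited) corner. All
  calibration constants live in the `synthetic_config()` object, never in
  generator code.
* **Replicate noise** is mean-preserving multiplicative lognormal at a
  configured CV (positive scale responses; defaults 6%/8% sit in the CV
  range of the packaged triplicates), except CODS, which gets additive
  noise because inhibited runs legitimately cross zero.
* **Biogas kinetics** follow the modified Gompertz curve
  $B(t) = P\exp(-\exp(e\,R_m/P(\lambda-t)+1))$ with the plateau tied to
  the true yield, rate tied to temperature level, lag to sonication
  level; each run stops when the daily yield falls below 1% of the
  cumulative total (capped at `max_days` = 60 d).
* **Digester chemistry** is phenomenological: TAN rises with solids load
  and temperature toward a plateau, pH drifts upward faster in inhibited
  runs, FAN is always derived through the ammonia equilibrium (so
  FAN ≤ TAN holds by construction), and TVFA either peaks and is consumed
  (healthy) or accumulates (inhibited), with the propionate:acetate ratio
  crossing the 1.4 failure threshold only under inhibition.
* `planted_config()` builds profiles whose best levels are known, with
  effect sizes expressed in units of the replicate noise SD, for
  Monte-Carlo recovery experiments: at effect/noise ≥ 3 the S/N pipeline
  must recover the planted optimum in ≥95 of 100 seeded repetitions (the
  suite observes 100/100).

What the generator does **not** emulate: mechanistic digestion
(no ADM1, no stoichiometry, no gas-liquid transfer), measurement drift,
missing data, or correlated replicate errors. Passing tests on synthetic
data therefore demonstrate that the *analysis chain* is correct and
recovers planted structure under realistic noise — not that the generator
is a digestion model.

## Problem sizes and runtime choices

The validation suite uses sizes chosen to exercise every code path while
staying comfortably interactive: 100-seed Monte-Carlo recovery runs,
150–350-row ANN datasets with 3–8 hidden units and ≤200 epochs, 500-case
brute-force oracle comparisons, and 200-triplicate approximation sweeps.
The full suite runs in well under a minute; the architecture-search
default candidate list (up to 50 hidden units) is intended for real use
and is exercised in tests with a reduced list.

## Known limitations

* The additive surrogate ignores factor interactions by construction;
  with an L9 that is a design property, not a modeling choice, and
  predicted optima outside the nine tested corners inherit it.
* The literal larger-the-better treatment of negative CODS values is
  reproduced for fidelity but is statistically indefensible; new analyses
  should prefer an explicit `negative_policy`.
* LM training builds the full Jacobian; it is intended for the
  hundreds-of-rows regime of digester campaigns, not for large datasets.
* Diagnostics thresholds are step functions of heterogeneous literature
  origin; they flag, they do not grade severity.
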