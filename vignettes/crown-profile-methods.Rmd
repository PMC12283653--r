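---
title: "Methods: layered crown competition and sequence models for crown profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered crown competition and sequence models for crown profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A crown profile is the curve of crown radius against depth below the tree
top. For *Pinus yunnanensis* and similar light-demanding conifers the crown
is measured at four relative crown heights (RCH = 0.25, 0.5, 0.75, 1.0 —
depth below the top divided by the largest crown length, LCL) in the four
cardinal directions. Crowns are vertically structured and directionally
asymmetric (typically largest toward the south, the sunny side in the
northern hemisphere), and both structure and asymmetry are shaped by
competition with neighbouring trees. `crownprof` predicts the crown radius
at every height layer of every tree from stand measurements, a layered
competition index, and sequence neural networks.

## Profile regularization

Measured radii sit at four (not always equidistant) relative heights. They
are interpolated onto the uniform grid RCH = 0, 0.1, ..., 1.0 with
shape-preserving piecewise cubic Hermite interpolation (PCHIP,
Fritsch–Carlson derivatives, via `pracma::pchip`), after prepending the
known zero-radius anchor at the tree top. PCHIP was chosen over Lagrange,
Newton and ordinary cubic splines because it cannot overshoot local data
extrema and preserves monotone segments — crown radii are nonnegative and
usually increase toward the crown base, and an oscillating interpolant
would create spurious bulges. The interpolated radii are denoted
CR\_0 ... CR\_10; CR\_0 = 0 always. A trailing numerical guard clips
negative values at zero and warns; PCHIP cannot undershoot, so the guard
is not expected to trigger.

Data-quality filters mirror the measurement protocol: trees are excluded
when any radius was recorded above RCH 1.0 or when any direction carries
fewer than four valid radii; guards also reject DBH below the 5 cm
calipering threshold and crown bases at or above the tree top. Filtering
is idempotent.

## The layered, directional competition index

Competitors are the trees whose Voronoi cells share an edge with the
subject's cell. Because no Voronoi library is part of the package's
dependency set, cells are constructed directly by half-plane clipping: the
plot disc (polygonized at 128 segments) is cut by the perpendicular
bisector of the subject and each candidate neighbour, visiting candidates
by increasing distance and stopping when the bisector lies farther than
the cell's farthest vertex. Each surviving edge remembers which bisector
created it, which yields adjacency without any point-location data
structure; this matches the defining property of the Voronoi diagram
exactly and is cross-checked in the tests against a brute-force
"is some point of the plane closer to both stems than to all others"
oracle. Cells are clipped to the plot circle so boundary trees keep
finite cells; the clipping choice only affects trees whose unbounded
cells would otherwise have ill-defined adjacency. Degenerate inputs
(fewer than three stems, collinear stems) fall back to "all other trees
are neighbours" with a classed warning.

At each of the M = 10 layers (k = 1..10, heights from the treetop
CH\_k = 0.1·k·LCL) crowns are idealized as horizontal discs. Two layers
compete only if their heights-from-top differ by at most 2 m (the layer
gate). The pairwise overlap area AO\_ij(k,t) of subject layer k and
competitor layer t is the circle-intersection area in its three regimes:
zero when the discs are disjoint, the circular-lens formula (two
arc-cosine sector terms minus twice the Heron triangle area) for partial
overlap, and the smaller disc's area under containment. The total overlap
AO\_i(k) sums gated pairs over all competitors and layers.

The layer competition index weights each gated pair by the
competitor-to-subject size ratio and scales by the subject's projection
area:

CPCI\_k = (1 / (π·CR\_ik²)) · Σ\_j Σ\_t AO\_ij(k,t) · (CH\_jt·CR\_jt) / (CH\_ik·CR\_ik)

Two reading choices deserve note. First, the size-ratio factor is applied
inside the double sum (per-pair weighting), the construction used by
overlap-based competition indices in the Bella tradition; an alternative
single-competitor reading does not generalize to several competitors.
Second, the subject's layer projection area Z\_ik is taken as π·CR\_ik²,
consistent with the circular-disc idealization. Layers with zero subject
radius have no disc and get index 0. CH here is depth below the treetop
(the convention the field variables use), not height above ground.

The directional allocation splits a layer's index across the four
cardinal directions, giving the *smaller* radius the *larger* share:

CPCI\_dir(k) = CPCI\_k · (1 − CR\_dir,k / Σ\_dir CR\_dir,k)

so the four shares always sum to 3·CPCI\_k (an identity the tests check
to 1e-12). The geometry is computed once on direction-averaged (MEAN)
profiles and then allocated; the directional radii only enter the
allocation weights.

Numerical choices: regime classification uses a 1e-12 tolerance — at an
exact regime boundary the adjacent formulas agree, so ties are harmless;
arc-cosine arguments are clamped to [−1, 1]; the Heron radicand is clamped
at 0. A competitor layer may be gated into several subject layers; each
subject layer is computed independently.

## Feature sequences and normalization

Each tree (per direction, or for the MEAN profile) becomes a 10-step
sequence ordered from the tree top to the crown base. The 14 per-step
inputs are AGE, DBH, TH, CW, HCW, HCB, CH\_k, LCL, TSC (height/diameter
slenderness, m/cm), CLR (LCL/TH), BA (basal area, m²/ha), SDI (Reineke,
reference diameter 25 cm, exponent 1.605), the previous layer's radius
CR\_(k−1), and CPCI\_k (dropped in the 13-feature "no CPCI" condition);
the target is CR\_k. TSC, BA and SDI are not given closed definitions in
the field protocol; the conventional forestry definitions used here
reproduce the published summary statistics (mean TSC 0.6, range 0.3–1.7)
and enter only as model features.

Top-down ordering was chosen because the lag feature is then anchored by
the known CR\_0 = 0 at the first step; a bottom-up sequence has no
observed anchor. The ordering is exposed as a `step_order` switch.

All inputs and the target are min-max scaled to [0, 1] on statistics
learned from the training partition only; validation/test values falling
outside the training range are transformed outside [0, 1] and deliberately
not clipped. The 8:1:1 train/validation/test split is done at the tree
level so the lag feature cannot leak the same tree's radii across
partitions (a per-record split would).

At prediction time the lag feature uses teacher forcing (the observed
previous radius) by default; an autoregressive mode that feeds back the
model's own re-normalized prediction is available, since protocols differ
on this point. Reported metrics state the mode used.

## Architectures and training

Three architectures are compared, all ending in a per-step linear head so
that each height layer gets its own radius prediction:

* **Vanilla LSTM** — one LSTM layer over the 10 steps, full hidden
  sequence out.
* **CNN-LSTM** — two same-padded 1-D convolutions along the step axis
  (kernel 3, ReLU; the second with twice the filters), plus a linear
  projection of the raw input added elementwise (a residual connection
  preserving low-level information), feeding the LSTM.
* **CNN-LSTM-Attention** — additionally, a learned scoring vector produces
  a softmax distribution over the 10 steps, and the hidden sequence is
  reweighted elementwise by those attention weights before the head.
  A pooled weighted *sum* would collapse the sequence and could not feed a
  per-step head, so the sequence-preserving multiplicative reweighting is
  used; the attention weights still form a distribution over layers. The
  product is scaled by the number of steps (h'\_t = T·a\_t·h\_t) so that
  uniform attention is the identity map — without the scaling, softmax
  weights averaging 1/T would shrink the head's inputs tenfold and slow
  optimization for no modelling reason.

No deep-learning framework is among the package's dependencies, so the
forward and backward passes (backpropagation through time) are written
directly in R and verified against central finite differences to ~1e-10
relative error in the test suite. Training minimizes MSE on the
normalized targets with Adam at the configured learning rate, minibatch
shuffling, early stopping on validation loss (default patience 20 within
a 200-epoch budget) and restoration of the best-validation weights. All
randomness is seeded; training is bit-reproducible.

Hyperparameters (filters 32–256, LSTM units 32–128, learning rate
1e-5–1e-2 searched on a log scale, batch size 16–64) can be tuned by a
canonical particle swarm (inertia 0.7, cognitive = social = 1.5, default
swarm 10 × 20 iterations, integer dimensions rounded per evaluation)
whose objective is the validation MSE of a shortened (50-epoch) training
run. Training details that protocols usually leave unstated — optimizer,
epoch budget, kernel width, activations — are exposed in
`model_config()` with the defaults above.

## Evaluation

Five statistics over pooled (tree × layer) records in metres after
reverse normalization: MSE, RMSE, MAE, ME (mean of observed minus
predicted) and R² (1 − SSE/SST with the evaluation set's own mean).
Reports cover the factorial design: three architectures × direction
(MEAN, E, W, S, N) × with/without the competition index.

Feature attribution uses permutation importance: the increase in
held-out MSE when one feature is shuffled across sequences (static
attributes share one permutation across steps; step-varying features are
shuffled per step slot), averaged over repeats. It replaces
model-specific explainers with an assertable, model-agnostic measure.

## The synthetic stand generator

Field crown measurements of this kind are rarely deposited, so the
generator produces stands with the statistical structure the pipeline
assumes, and it is itself tested code:

* stem positions by sequential inhibition (hard-core spacing, default
  1.5 m) in a circular plot (default radius 30 m);
* DBH lognormal calibrated to mean 19.5 cm, sd 6.8 cm; height
  TH = 1.984·DBH^0.6·exp(ε) (≈11.8 m at the mean DBH); crown length
  ratio Beta with mean 0.42 (HCB = TH·(1−CLR) ≈ 6.8 m); open-grown crown
  width 0.46·DBH^0.55 (≈2.1 m diameter at the mean DBH); age
  27.3·(DBH/19.5)^0.4·exp(ε);
* directional radius curves r\_dir(u) = mult\_dir·(CW/2)·u^β·(1−γ·crowd\_dir)
  with β ≈ 0.6 (a power profile, the family that fits measured directional
  crown scatter well), south-favoured multipliers (S 1.14 vs N 0.90), and
  a crowding covariate per compass sector — neighbours weighted by a
  half-cosine angular window around the sector bearing and an exponential
  distance kernel (scale 4 m), saturated into [0, 1];
* measured radii emitted at RCH 0.25/0.5/0.75/1.0 with 5% multiplicative
  lognormal noise; the noise-free curves and crowding covariates are
  returned as ground truth.

What the generator emulates: realistic marginals, competition-dependent
crown reduction, directional asymmetry, measurement noise. What it does
not: crown collisions and plasticity (real crowns interlock and displace),
terrain and light geometry, multi-species mixtures, spatially correlated
site effects, and measurement error structure beyond i.i.d. multiplicative
noise. Passing the synthetic experiments therefore shows that the pipeline
recovers structure *of the kind it assumes*, not that it matches any
particular field stand.

## Synthetic model comparison (problem sizes used)

The package's standing experiment (`recovery_suite()`, also recomputed by
`scripts/acceptance.R`) uses 500-tree stands of radius 35 m with
competition sensitivity γ = 0.5, three replicate seeds, the three
architectures with and without the competition index, training at
filters 32 / units 32 / learning rate 3e-3 / batch 32. These sizes keep a
full 18-model comparison on a single CPU inside a coffee break.

An honest caveat about what this experiment can and cannot show: with the
generator's smooth power-law profiles and the teacher-forced lag feature,
each layer's radius is nearly determined by the previous layer's radius
and CH\_k, so *every* architecture fits held-out trees to R² ≈ 0.996–0.999.
At that ceiling the convolutional models beat the vanilla LSTM
consistently (a median gap of ~1e-3 in R²), but the attention-vs-CNN-LSTM
difference and the effect of adding the competition index are of the same
order as seed-to-seed noise and do not order stably. The index is also
sparse at this stand density (≈0.13 stems/m²): crowns of ~1 m radius at
~2.8 m spacings rarely interlock, so most layers carry CPCI = 0 — the
index measures realized crown interlock, not general proximity, and the
lag feature already transmits the realized competition effect under
teacher forcing. Discriminating the architectures and the index's
predictive value more sharply would need data where the profile is not
quasi-autoregressive — i.e. real crowns, with shape variation the
generator does not emulate.

## Known limitations

* The Voronoi construction is O(n²) per plot in the worst case; fine for
  survey plots (hundreds of stems), not for wall-to-wall inventories.
* The competition geometry idealizes crowns as circles per layer;
  directional asymmetry enters only through the allocation weights, not
  the geometry itself.
* The networks are CPU-bound R implementations: suitable for
  plot-scale studies and experimentation, not for very large training
  corpora.
* The 2 m layer gate is fixed, following the protocol; it does not scale
  with tree size.
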