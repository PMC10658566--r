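---
title: "Modelling drug permeation through microneedle-treated skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug permeation through microneedle-treated skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnperm)
```

`mnperm` predicts cumulative drug permeation through microneedle (MN)
treated skin two ways: mechanistically, by solving the diffusion
equation over a needle–skin–receptor unit cell, and statistically, by
regressing measured permeation on seven device/drug descriptors. This
vignette is the package's own account of the models, the numerical and
design choices behind them, and their limitations.

## The mechanistic model

### Geometry and discretization

An MN patch is an array of identical needles at fixed spacing. Each
needle plus its surrounding skin column is treated as a repeating unit
cell, independent of its neighbours; by the needle's mirror symmetry
only half the cell is simulated. The half cell is a rectangle: the
needle's symmetry axis on the left, the midline to the adjacent needle
on the right (`unit_cell_width`, default 300 µm, i.e. a 600 µm pitch —
needle spacing is rarely reported, so it is a config knob), the skin
surface on top and the skin–receptor interface at depth
`skin_thickness` (default 1000 µm, a typical full-thickness skin
sample; the needle may not be longer than this).

The rectangle is meshed into `dx × dy` cells (default 2 × 2 µm). Mesh
elements fall into five classes by which neighbours they have —
internal (4), edge (top row and side columns, 3), bottom edge (3 plus
the receptor), and the corner/bottom-corner variants
(`classify_elements()`). Rather than special-casing each class, the
solver uses the equivalent conservative formulation: mass moves across
every *existing* face with coefficient `D·dt/dx²` (or `dy²`), and
faces on the domain boundary simply do not exist (no-flux). This makes
conservation exact by construction; the finite-mode mass-balance error
is tracked and is at rounding level (`attr(curve,
"mass_balance_error")`).

The needle's half cross-section is rasterized onto the grid
(`rasterize_half_needle()`): a cell is inside the needle when its
x-centre lies within the analytic half-width evaluated at the cell's
top edge — the widest point of the profile across the cell's depth
span. Evaluating at the top edge (rather than the cell centre) keeps
tip cells from vanishing and reproduces the intended discrete profile
for coarse grids; either convention converges first-order to the
analytic cross-section area under refinement, which the tests check at
two refinement levels.

### Time stepping and stability

The explicit FTCS update is stable for
`dt ≤ dx²dy² / (2D(dx² + dy²))` (`stability_limit()`; `dx²/4D` on a
square grid — 0.001 min at D = 1000 µm²/min and dx = 2 µm, matching
the upper end of the usual step-size range). `run_simulation()` uses
`min(dt_user, 0.9 × limit)` and linearly interpolates the receptor
trajectory onto the requested output times. If instability is somehow
provoked (e.g. through the low-level `diffusion_step()`), negative
concentrations beyond −1e−12 raise an error advising a smaller step.
`D = 0` is allowed as a degenerate case and yields a zero curve.

### Initial condition and needle types

Hydrogel needles carry the drug in the polymer: the load is spread
uniformly over the needle mask. Plastic (solid) needles only pre-treat
the skin; the drug is a solution filling the needle-shaped cavity plus
a donor layer of height `donor_layer_height` (default 1000 µm) above
the skin. Both run through the same solver — the only difference is
which cells start loaded.

Because the diffusion equation and the receptor coupling are linear in
concentration, the solver normalizes the initial mass to 1 and tracks
the *fraction* of load in each compartment, rescaling to µg afterwards.
A useful exact consequence: at fixed total patch load, the needle count
does not change the curve at all (bit-for-bit), since the per-needle
geometry fixes the fraction and the rescaling is
`fraction × load_per_needle × n_needles`.

### The receptor compartment

The default receptor is a finite, well-mixed volume (`receptor_volume`,
default 5000 µL — a typical Franz cell; no canonical value exists).
Its 2D capacity is the liquid height under the diffusion window
(`volume / window_area`) times the unit-cell width; bottom-row cells
exchange `D·dt/dy² × (cell concentration − receptor concentration)`
per step, bidirectionally and conservatively. This is what produces
the late-time plateau: needle, skin and receptor approach a common
concentration. A `"sink"` mode pins the receptor at zero concentration
and is used for validation against the closed-form slab solution
(below); with a sink the percentage tends to 100%.

### Reporting scale

Measured cumulative amounts refer to the diffusion window between donor
and receptor: 1.00 cm² for the vertical device and 1.13 cm² for the
horizontal one. The simulator divides the permeated mass by the window
area and reports µg per 1 cm², the same normalization
`normalize_amount()` applies to experimental records. The percentage
is `100 · m_t / m_total` of the total patch load.

### Validation against an independent solution

With a degenerate "needle" spanning the full cell width and depth and a
sink receptor, the 2D problem collapses to a uniformly loaded 1D slab
with one sealed face and one perfect-sink face, whose fractional
release has the classical series solution implemented independently in
`slab_release_oracle()` (series summed to 1e−12). The solver tracks it
within 1% absolute at dx = 2 µm; the residual discrepancy is the
first-order offset of the discrete sink boundary (half a cell plus the
ghost-cell distance), which shrinks with `dy`.

Qualitative behaviours are asserted as properties: amounts increase
with D, needle length and loading; loading moves the curve
proportionally (linearity) and hence more strongly than length over the
study ranges; curves are non-decreasing in time; grid refinement
(20 → 10 → 5 µm) changes the 24 h percentage by successively smaller
amounts.

## The statistical models

Seven features enter every learner: skin type (rat/human), MN type
(hydrogel/plastic — "solid" in some sources; read as plastic), MN
length (µm), MN patch surface area (mm²), drug loading (µg),
permeation time (h) and molecular weight (Da). The drug label itself is
deliberately not a feature. Patch surface areas follow the frustum /
square-pyramid formulas (top cap plus lateral faces; the base is glued
to the backing and excluded) times the needle count.

Encoding: the fixed 9-column one-hot layout (both levels of each
binary categorical, then the five numeric features). For the linear
model this design is rank-deficient by construction once an intercept
is added, so `fit_mlr()` returns the minimum-norm least-squares
solution (SVD pseudoinverse) with a warning; on full-rank designs it
coincides with the normal-equation solution, which the tests verify
against an independent `solve(X'X, X'y)`. The random forest instead
consumes the 7-column frame with factor categoricals, so its `mtry`
(5 for the amount target, 6 for percentage) counts semantic features;
XGBoost uses the one-hot matrix with max_depth 4, eta 0.4, nround 100
(amount) and 3, 0.2, 45 (percentage). The boosting regularizers γ and
λ stay at the library defaults (0 and 1), there being no published
setting. Two separate models are fitted per family, one per target,
never one multi-output model.

Feature importances are impurity-based for the forest (permutation
available via `type = "permutation"`) and gain-based for XGBoost, with
one-hot pairs summed back to their semantic feature; both are
normalized to 100%.

Evaluation follows the study protocol: a single 7:3 random split
(`split_train_test()`, training size rounded half-up — 134/57 at
N = 191), RMSE and R² (`1 − SS_res/SS_tot`, reported as computed, so
possibly negative on test data) on the test rows only. A repeated-split
reading is available simply by mapping `compare_methods()` over seeds.
Fick's-law predictions join the comparison only when per-drug simulator
configs are supplied (`fick_predict()`), since their diffusion
coefficients come from literature, not from training; without configs
the column is omitted rather than guessed. `leave_one_drug_out()`
probes extrapolation to unseen compounds.

## The synthetic data generator

`generate_dataset()` exists so that every downstream stage is testable
without the experimental database. It emulates how such a database is
actually assembled from prior studies:

* **Drugs.** Six permeants spanning the study's MW range (copper 64 Da
  to BSA 66,430 Da) with the published per-drug record counts — 191
  rows, of which lidocaine contributes 73 (38%). The published
  per-drug shares are mutually inconsistent as percentages (they sum
  past 100), so beyond the verifiable lidocaine pair the remaining
  counts are a consistent reading: BSA 33, GHK 24, copper 23,
  rhodamine 19, caffeine 19.
* **Diffusion coefficients.** `mw_to_diffusion()` maps MW to D with a
  Stokes–Einstein-like `D = c·MW^(−1/3)`, anchored so a mid-range
  small molecule (194 Da) gets 600 µm²/min and clipped to the 50–1000
  µm²/min range used in skin modelling.
* **Protocols and replicates.** Each source study used its own
  formulation, so loadings cluster per drug: each drug has a loading
  window (union spanning 50–70,940 µg) and a small set of protocols —
  needle type × skin type combinations cycled Latin-square-style, each
  with one log-uniform loading draw and a geometry from the pool (four
  64-needle hydrogel frustum patches, 700–999 µm long, plus the
  351-needle pyramid patch; the two published lengths above 1 mm are
  excluded because they exceed the 1 mm skin domain, and the frustum
  radii behind the published patch areas are not public, so plausible
  radii landing in the same 27–37 mm² area range are fixed here).
  Protocols are sized so each gets at least ~3 replicate curves,
  mirroring replicate Franz cells sampled at shared times — the
  structural reason tree models can approach the noise ceiling on
  these data.
* **Sampling and noise.** The default time grid is a typical Franz
  schedule (0.25–48 h, nine points). Amounts get multiplicative
  lognormal noise, sd 0.15 on the log scale — ordinary replicate
  variability for Franz experiments (10–20% CV) — winsorized at ±3 sd
  so records stay physical; the percentage is recomputed from the
  noisy amount so each row remains internally consistent (and is
  flagged, not dropped, if it exceeds 100). The generator is fully
  deterministic given its seed.
* **Problem sizes.** The generator runs the simulator at dx = dy =
  10 µm rather than the 2 µm default: one curve then costs a fraction
  of a second instead of minutes, and the 24 h percentage differs from
  the fine grid by far less than the noise level. The solver keeps
  2 µm as its own default.

What passing tests on these data do and do not show: they demonstrate
that the pipeline recovers planted structure (linear laws exactly;
monotone drivers; the loading-dominates-importance pattern; the
out-of-range leave-one-drug-out collapse) and that the method ranking
XGBoost > RF > MLR emerges on curved, saturating response surfaces with
replicate structure. They do not certify performance on real skin data,
whose noise is not lognormal-iid, whose curves include partitioning and
binding effects the diffusion model omits, and whose metadata are
messier than the canonical schema.

## Known limitations

* 2D unit-cell model: no out-of-plane geometry; the 3D patch enters
  only through the per-needle load and needle count.
* Uniform, constant D; no partition coefficients at needle–skin or
  skin–receptor interfaces; no binding, metabolism, swelling or needle
  degradation; temperature effects neglected.
* Explicit time stepping: fine grids at high D are expensive
  (dt ∝ dx²/D); no implicit/ADI option.
* The linear-model collinearity warning is intrinsic to the fixed
  one-hot encoding; interpret individual MLR coefficients only through
  identifiable contrasts or predictions.
* Method-comparison bands depend on the synthetic design (replicate
  counts, loading windows, noise level); they transfer to other
  datasets only insofar as those share that structure.
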