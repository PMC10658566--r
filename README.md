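# mnperm

Mechanistic and statistical prediction of drug permeation through
microneedle-treated skin.

Microneedle (MN) patches carry sub-millimetre needles that pierce the
stratum corneum — the skin's main permeation barrier — so that a drug
loaded in (or applied over) the patch can diffuse into the skin and on
into the receptor compartment of a Franz diffusion cell. Measuring the
resulting cumulative permeation curves in vitro is slow and expensive;
`mnperm` provides the two complementary ways to predict them without the
wet lab:

1. **A mechanistic simulator.** Fick's second law,
   `∂C/∂t = D (∂²C/∂x² + ∂²C/∂y²)`, is solved with an explicit
   forward-time centred-space (FTCS) finite-difference scheme on the 2D
   half unit cell of one needle plus its surrounding skin, with no-flux
   boundaries on the symmetry axis, the midline to the neighbouring
   needle and the top, and a receptor compartment (well-mixed finite
   volume, or a perfect sink) coupled to the bottom row. The receptor
   mass fraction times the patch load, normalized to the 1 cm² diffusion
   window, gives the cumulative amount (µg/cm²); dividing by the total
   load gives the permeation percentage.
2. **Statistical learners.** Multiple linear regression, random forest
   (500 trees, mtry 5/6) and XGBoost (max_depth 4/3, eta 0.4/0.2,
   nround 100/45 for the amount/percentage targets) fitted on seven
   device/drug features — skin type, MN type, MN length, MN surface
   area, drug loading, permeation time and molecular weight — with RMSE
   and R² model comparison on a 7:3 random split, gain/impurity feature
   importances, and leave-one-drug-out validation.

Patch geometry is handled explicitly: a frustum (hydrogel) needle has
surface area `S = πr² + πl(R + r)`, a square-pyramid (plastic) needle
`S = 4·(a/2)·√((a/2)² + h²)`, and a patch `S_total = S · n`.

A synthetic data generator drives the simulator over realistic study
designs (per-drug protocols, replicate Franz cells, multiplicative
lognormal measurement noise) and emits datasets in the standard
ten-column permeation schema, so the whole pipeline can be exercised
without any experimental data.

## Worked example

```r
library(mnperm)

# -- geometry: the 351-needle plastic patch --------------------------------
needle <- pyramid_needle(base_edge = 0.075, height = 0.7)    # mm
round(pyramid_surface_area(needle), 3)
#> [1] 0.105                                  # mm^2 per needle
patch <- patch_layout(needle, n_needles = 351, "plastic")
round(patch_surface_area(patch), 2)
#> [1] 36.91                                  # mm^2 per patch

# -- mechanistic curve: 64-needle hydrogel patch, 1 mg load ----------------
cfg <- simulation_config(
  needle = frustum_needle(80, 120, length = 700),  # um
  D = 500,                       # um^2/min
  t_end = 48 * 60,               # min
  load_per_needle = 1000 / 64, n_needles = 64,
  dx = 10, dy = 10, output_times = c(1, 4, 8, 24, 48) * 60)
curve <- run_simulation(cfg)
round(as.data.frame(curve), 2)
#>   time_min time_h amount_ug_per_cm2 percentage
#> 1       60      1             30.49       3.05
#> 2      240      4            211.11      21.11
#> 3      480      8            408.47      40.85
#> 4     1440     24            806.66      80.67
#> 5     2880     48            951.31      95.13
```

The curve is the classic MN permeation shape: a lag while drug leaves
the needle, a fast middle phase, then a plateau as needle, skin and
receptor approach equilibrium. At 24 h, 806.7 µg/cm² of the 1000 µg
load (80.7%) has reached the receptor.

```r
# -- synthetic study + method comparison -----------------------------------
g <- generate_dataset(generator_config(seed = 42))
summarize_dataset(g$records)
#>        drug  n share_pct
#> 1 lidocaine 73        38
#> 2       BSA 33        17
#> 3       GHK 24        13
#> 4    copper 23        12
#> 5  caffeine 19        10
#> 6 rhodamine 19        10

compare_methods(g$records, seed = 1)
#>    method     target     rmse    r2 n_test
#> 1     MLR     amount 12405.91 0.490     57
#> 2      RF     amount  6666.05 0.853     57
#> 3 XGBoost     amount  4214.38 0.941     57
#> 4     MLR percentage    13.48 0.793     57
#> 5      RF percentage     7.82 0.930     57
#> 6 XGBoost percentage     6.85 0.946     57
```

XGBoost gives the lowest RMSE and highest R² for both targets and the
first-order MLR the worst — the boosted trees capture the saturating,
interaction-heavy response surface that a linear model cannot.

## Command line

A thin CLI over the same functions ships in `inst/scripts/mnperm.R`:

```sh
Rscript inst/scripts/mnperm.R simulate --config sim.yaml --out curve.csv
Rscript inst/scripts/mnperm.R synth    --seed 42 --out synth.csv
Rscript inst/scripts/mnperm.R compare  --data synth.csv --seed 1 --out table.csv
Rscript inst/scripts/mnperm.R lodo     --data synth.csv --drug lidocaine
```

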