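# leadrisk

Risk classification of dietary lead in vegetables by spectral clustering.

`leadrisk` is for food-safety assessors who have censored contaminant
monitoring data (per-sample lead concentrations by region and vegetable
category), a consumption table, and regulatory limits, and who want an
ordered, data-driven risk grade for every region × category combination
rather than a hand-drawn banding of index values.

## The model

Every region–category combination is reduced to three dimensionless indexes:

- **Nemerow integrated pollution index.** With single-factor pollution index
  `P = X / S` (concentration over the category's regulatory limit),

  `Pc = sqrt((Pmax^2 + Pave^2) / 2)`

  computed from the combination's maximum and mean concentration. `Pc`
  always lies in `[Pmax/sqrt(2), Pmax]`: one hot sample dominates, the
  average tempers it.

- **Hazard index** (non-carcinogenic risk at high exposure):

  `HI = EDI95 / RfD`, `EDI95 = FC * X95 / W`

  with `FC` the mean daily consumption (kg/day), `X95` the 95th-percentile
  concentration, `W` the reference body weight (60 kg) and `RfD` the oral
  reference dose for lead, 3.5 µg/(kg·day). HI < 1 is conventionally
  acceptable.

- **Margin of exposure** (chronic risk at median exposure, protective —
  larger is safer):

  `MOE = BMDL01 / EDI50`, `EDI50 = FC * X50 / W`

  with `BMDL01 = 0.6 µg/(kg·day)` for lead.

Non-detects are filled in first by the WHO GEMS/FOOD substitution rule:
below a 60% non-detect proportion every non-detect becomes LOD/2, at or
above 60% it becomes the LOD.

The `(Pc, HI, MOE)` triples are z-scored, turned into an RBF affinity
`A[u,v] = exp(-γ ||z_u - z_v||²)`, and clustered spectrally (symmetric
normalised Laplacian, k smallest eigenvectors, row normalisation, k-means).
The kernel width γ (grid 1–10) and the cluster count k (grid 3–7) are chosen
by maximising the Calinski–Harabasz index on the standardised features, so
the number of risk levels is selected by the data, not by the analyst.
Clusters are then ordered into risk levels 1 (lowest) … k by their mean
composite score `z(Pc) + z(HI) − z(MOE)`.

A synthetic-data module generates censored lognormal sampling tables with
planted risk tiers, so the whole pipeline can be validated against a known
ground truth.

## Worked example

```r
library(leadrisk)

cfg <- scenario_config(seed = 1)      # 20 regions x 9 categories, 5 planted tiers
run <- run_pipeline(run_config(scenario = cfg, seed = 1))
run
#> <lead_risk_run> 180 combinations from 5400 samples; selected parameter 1, k = 5 (CH 2.652e+04)
#>   levels 1-2: 40.00%   level 3: 20.00%   levels 4-5: 40.00%

head(tidy(run), 4)
#> # A tibble: 4 x 7
#>   region    category       pc     hi   moe risk_level composite_score
#> 1 region_01 category_01 0.15  0.0180  9.50          1         -4.18
#> 2 region_01 category_02 0.712 0.0342  5.63          2         -1.73
#> 3 region_01 category_03 1.27  0.0505  4.05          3         -0.0841
#> 4 region_01 category_04 1.65  0.0758  2.52          4          1.44
```

The grid search selected k = 5 risk levels at kernel width 1, and the
assigned levels recover the generator's five planted tiers exactly (the
default scenario plants 36 combinations per tier, hence the 20/20/20/20/20
level split). `autoplot(run)` draws the region × category level heatmap;
`autoplot(run$grid)` draws the CH score surface over the (γ, k) grid.

Real data enter through four files instead of a scenario:

```r
run <- run_pipeline(run_config(
  sampling = "sampling.csv",       # region, category, concentration_mg_per_kg, detected, lod_mg_per_kg
  consumption = "consumption.csv", # region, category, fc_kg_per_day
  limits = "limits.csv",           # category, limit_mg_per_kg
  tox = "tox.yaml",                # rfd_ug_per_kg_day, bmdl01_ug_per_kg_day, body_weight_kg
  seed = 0, output_dir = "out"
))
```

`limit_preset()` supplies the Chinese national lead limits (0.3 mg/kg for
Brassica and leafy vegetables, 0.2 for legume vegetables, 0.1 for the other
monitored categories).

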