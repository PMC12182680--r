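# forestcarbon

Projection of forest aboveground biomass (AGB) and carbon sequestration under
climate change, for carbon-cycle and forest-policy analysts who need a
spatially explicit, reproducible pipeline from field survey data to
scenario-level carbon budgets.

## The model

Future AGB of a forest pixel is decomposed additively into the effects of
stand aging, climate change and CO₂ fertilization:

    C = C^age + C^climate + C^co2

The age–biomass relationship per forest type is one of three saturating
growth curves with asymptote μ (Mg/ha), augmented by a linear climate term in
mean annual temperature (MAT, °C) and precipitation (MAP, mm):

| family | f(t) |
|---|---|
| Michaelis–Menten (MM) | μ t / (k + t) |
| Monomolecular (MO) | μ (1 − c e^(−αt)), c ≥ 1 |
| Logistic (L) | μ / (1 + c e^(−αt)), c ≥ 1 |

    C_t^(age+climate) = f(t) + a·MAT + b·MAP + d

All parameters are estimated jointly per forest type by constrained nonlinear
least squares from survey records (age, AGB, MAT, MAP); the best family is
chosen by AIC (RMSE tie-break). The age component evaluates the fitted model
at the future stand age with baseline climate; the climate component is the
difference when future climate is substituted; the CO₂ component is
(F − 1)·C^age, where F = cVeg(ppm_t)/cVeg(371.8 ppm) is the fertilization
ratio read off Earth-system-model cVeg responses to CO₂ and averaged over
each 20-year projection period.

Forest dynamics are driven by habitat suitability: per-type suitability
probabilities P thresholded at the MTSS (maximum training sensitivity plus
specificity). Under the **nature scenario** a forest pixel whose own type
still qualifies (P > MTSS) ages by N years; otherwise it is replaced by the
most suitable qualifying other type at stand age N/2, or lost if none
qualifies. Under the **afforestation scenario**, linearly interpolated
national area targets minus the remaining nature-scenario forest give a
planting demand that is allocated uniformly at random over suitable
non-forest pixels (most suitable type, age N/2), repeated over replicate
seeds and averaged.

Baseline maps are fused from three cover products (majority on forest types,
then a reliability-rank cascade; forest = tree cover ≥ 20%) and three
stand-age products (priority fill; the oldest-epoch product is adjusted by
+10 years).

A synthetic-world generator fabricates every input — survey records on known
growth laws, discordant cover/age products, climate fields and futures,
suitability surfaces with known MTSS, CO₂ trajectories and cVeg curves, area
targets — with the generating truth recorded, so the full pipeline is
testable without any external rasters.

## Worked example

```r
library(forestcarbon)

# a synthetic study system with known ground truth
w <- generate_world(synthetic_config(seed = 1, grid_rows = 20,
                                     grid_cols = 20, survey_n = 240))

# fit the three growth families to one type's survey records, keep the best
fit <- fit_growth_models(subset(w$survey, type == 1), label = "1")$best
fit
#> Climate-augmented MM growth fit [1] (n = 49)
#>       mu        k        a        b        d
#> 103.8658 107.7057   2.7979   0.0364  12.0508
#> RMSE 11.669 Mg/ha, R2 0.876, AIC 250.78
```

The generating law for this type was MM with μ = 105, k = 120, a = 2,
b = 0.05: the selected family is correct and the asymptote is recovered
within a few Mg/ha from 49 noisy records.

```r
res <- run_pipeline(synthetic_config(seed = 1, grid_rows = 20,
                                     grid_cols = 20, survey_n = 240),
                    seeds = 1:5)
res$summary[res$summary$period %in% c("2020", "2050s"),
            c("period", "ssp", "scenario", "total_agb_pgc", "mean_density",
              "mean_age", "area_mha", "loss_rate", "change_rate")]
#>   period    ssp      scenario total_agb_pgc mean_density mean_age area_mha
#> 1   2020   <NA>      baseline         4.297        211.9    60.03    20.28
#> 6  2050s SSP245        nature         4.992        257.6    80.48    19.38
#> 7  2050s SSP245 afforestation         6.230        225.4    60.92    27.64
#> 8  2050s SSP585        nature         4.841        265.2    74.43    18.26
#> 9  2050s SSP585 afforestation         6.403        231.2    54.18    27.69
#>   loss_rate change_rate
#> 1        NA          NA
#> 6     4.441       11.05
#> 7     4.441       11.05
#> 8     9.973       17.60
#> 9     9.973       17.60
```

Reading the 2050s rows: without intervention total stored carbon rises from
4.30 to ~4.9–5.0 PgC as stands age, but 4.4% (SSP245) to 10.0% (SSP585) of
the 2020 forest area is lost and 11–18% shifts composition; planting to the
area target adds ~8 Mha of young forest and another ~1.2–1.6 PgC. Densities
are Mg/ha; totals use the configurable carbon fraction (default 1, i.e.
densities already in carbon units).

## Package tour

- `synthetic_config()`, `generate_world()`, `write_world()` — synthetic study
  system with recorded truth
- `fuse_cover()`, `fuse_age()`, `forest_mask()` — baseline map fusion
- `fit_growth()`, `fit_growth_models()`, `select_model()`, and the
  `growth_fit` methods (`print`, `summary`, `coef`, `predict`, `plot`,
  `simulate`, `AIC`) — the statistical core
- `compute_F()`, `period_mean_F()`, `co2_component()` — CO₂ fertilization
- `prune_correlated()`, `is_suitable()`, `best_type()` — suitability layer
- `step_nature()`, `allocate_afforestation()`, `run_ensemble()`,
  `fit_area_targets()` — scenario engine
- `total_agb()`, `rates()`, `sequestration_rate()`, `summarize_state()`,
  `summarize_by_region()` — reported metrics
- `run_pipeline()`, `write_pipeline()` — end-to-end orchestration with a
  reproducibility manifest

The methods vignette (`vignettes/projection-methods.Rmd`) documents the model
assumptions, parameter choices, numerical details and limitations.
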