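# scalesiacarbon

Carbon sequestration modelling for restored *Scalesia pedunculata* stands
in Galapagos agroforestry systems.

*Scalesia pedunculata*, the endemic tree of the Galapagos humid highlands,
has lost most of its range to farmland. Restoration programmes replant it
into coffee plantations and monitor every seedling quarterly. This package
is aimed at restoration ecologists and carbon-accounting practitioners who
want to turn such monitoring data into a defensible estimate of how much
carbon a restored stand will store — and what that means at archipelago
scale. It implements the full pipeline as a carbon sequestration model
(CSM):

1. **Synthetic cohorts** (`generate_cohort`) — monitoring tables with the
   statistical structure of the 2013–2023 field campaign (426 plants, 10
   sites, 6 planting treatments, quarterly censuses), so every stage is
   testable without access to field data.
2. **Survival** (`fit_survival_glmm`) — a repeated-measures logistic mixed
   model, `alive ~ treatment + age + (1 | plant) + (1 | site)`, fitted by
   Laplace-approximated ML (lme4), with Wald chi-square term tests and
   population-level survival curves:
   logit Pr(alive) = β₀ + γ_treatment + β_age · age + b_plant + c_site.
3. **Size and biomass** (`fit_dbh_model`, `dry_mass`, `tree_carbon`) —
   DBH estimated as a linear function of age and height (multi-stem trees
   reduced to an equivalent diameter, DBH = 2·√Σr²), then two-compartment
   allometry M_woody = 0.01540·(DBH²)^1.60906, M_foliage =
   0.01769·(DBH²)^0.77946 (kg), with carbon = 48% of dry mass.
4. **Stand projection** (`project_stand`) — C(t) = density × S(t) × c(t)
   × F(t)/1000 in Mg C/ha at 530 trees/ha over 10 years, where F(t) is a
   mean-one geometric Brownian noise with 20% standard deviation at the
   horizon; means ± SE over 500 replicates.
5. **Footprint accounting** (`footprint_reduction`) — the stored CO₂
   equivalent (44/12 × C) as a percentage of the archipelago footprint
   (723 ha of coffee, 523,000 Mg CO₂/yr).

See the vignette (`vignettes/carbon-sequestration-model.Rmd`) for the
model details, calibration choices and known limitations.

## Worked example

```r
library(scalesiacarbon)

rec <- generate_cohort(seed = 1)        # 6732 records for 426 plants
fit <- fit_survival_glmm(rec)
print(fit)
#> Logistic mixed survival model (Laplace)
#>   6732 records, 426 plants, 10 sites; logLik -978.39; converged: TRUE
#>   random effects: var(plant) = 0.642, var(site) = 0.862
#>   fixed effects:
#>     (Intercept)                     4.318  (SE 0.382)
#>     treatmentCocoon+Hydrogel        2.059  (SE 0.550)
#>     ...
#>     age                            -0.266  (SE 0.038)
```

The refitted coefficients recover the generating (published) values —
intercept 3.932, age slope −0.234 — within sampling error. DBH estimation
and the stand projection:

```r
dfit <- fit_dbh_model(build_dbh_subsample(rec), rec)
print(dfit)
#> Linear DBH estimator: dbh ~ age + height
#>   dbh = 0.2992 + 0.7884 * age + 0.00768 * height   (n = 400, residual SD 1.049 cm)
#>   Pearson r of estimated DBH: age 0.918, height 0.966

tree <- per_tree_trajectory(dbh_fit = dfit)      # kg C per surviving tree
pr <- project_stand(projection_config(seed = 101), survival_fixed_effects(),
                    tree, arm_weights = cohort_config()$treatment_allocation)
print(pr)
#> Stand carbon projection
#>   scenario: all-data; 530 trees/ha; 10-year horizon; 500 replicates; noise 20%
#>   carbon at year 10: 22.04 +/- 0.19 Mg C/ha (survival 0.861)
```

A default stand therefore sequesters on the order of 21 Mg C/ha in 10
years (the estimate varies by a few percent with the generator seed
through the DBH calibration). Scaling to the Galapagos coffee area:

```r
offset_report(offset_inputs(per_ha_carbon = 22.04))
#>   total_carbon_Mg total_co2e_Mg footprint_reduction_pct
#>          15935.23      58429.18               -1.117193
```

about 15–16 thousand Mg of carbon, i.e. a ~1.1% reduction of the
archipelago's 10-year CO₂ footprint. The estimated DBH correlations
(0.92 with age, 0.97 with height), the ~46 kg C stored per surviving
tree at year 10, and the high survival (0.86 population-level at 10
years) are the intermediate quantities that drive this result.

An end-to-end run that writes every intermediate table plus a JSON
manifest is `run_pipeline(out_dir, seed = 1)`; a thin command-line
wrapper with per-stage subcommands lives at
`inst/scripts/scalesia-pipeline.R`.

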