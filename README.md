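# ionbudget

Input–output element budgets for long-term forest monitoring plots:
annual ion fluxes in charge equivalents, dry-deposition estimates, a
stoichiometric proton budget for nitrogen transformations, cumulative
topsoil sulfur storage with remobilization-window detection, and
emission-inventory harmonization with S/N ratio tracking — plus a seeded
synthetic monitoring-data generator with known ground truth for
parameter-recovery testing.

## Who it is for

Ecosystem biogeochemists and monitoring programmes (ICP-Forests-style
Level II plots) who hold decades of sampling-period solution chemistry
for bulk precipitation, throughfall and seepage together with daily
water fluxes, and want reproducible, tested budget arithmetic instead of
spreadsheet pipelines.

## The core accounting

All fluxes run in millimoles of ion equivalents (mmol_IE m⁻² yr⁻¹,
millimoles of charge). The three central pieces are:

**Annual fluxes.** A sampling period contributes
`concentration × Σ daily water flux` (µeq L⁻¹ × mm, 1 mm = 1 L m⁻²);
periods spanning a year boundary are split pro-rata by water so annual
fluxes stay exactly additive. Dry deposition ≈ throughfall − bulk for
ions with negligible canopy exchange.

**Proton budget.** For nitrogen turnover with process rates n
(nitrification), u_a (NH₄⁺ uptake), u_n (NO₃⁻ uptake + denitrification)
and m (ammonification), the rule-level proton sum `2n + u_a − u_n − m`
collapses, under the flux mass balances, to the closed form

```
L = (NH₄_in − NH₄_out) + (NO₃_out − NO₃_in)
```

so the load is computable from four measured fluxes alone. Adding the
direct H⁺ input with throughfall and comparing with the H⁺ output at
40 cm gives the buffered percentage of the topsoil.

**Sulfur storage.** Annual ΔS = throughfall SO₄²⁻ − seepage SO₄²⁻
(mmol_IE m⁻²), accumulated — after dividing by the sulfate charge 2 —
against an initial element-molar stock. A cubic trend of ΔS plus an
MAE-derived "natural fluctuation zone" (MAE rounded to the nearest 10,
ties toward zero) yields the sulfate remobilization window: the maximal
run of years whose fitted ΔS lies below −threshold.

## Worked example

```r
library(ionbudget)

report <- run_pipeline(pipeline_config(scenario = scenario_config()))
report
#> <budget_report> 36 years
#>   S remobilization window: 1995-2017 (22 years, threshold 20 mmol_IE m-2)
#>   remaining topsoil S: 82.8%
#>   buffered protons first/last 5 years: 97.4% / 97.4%
```

The default scenario emulates a 1985–2020 spruce-stand record
(throughfall SO₄²⁻ falling 160 → 10, NH₄⁺ 150 → 70 mmol_IE m⁻² yr⁻¹,
drought years with collapsed seepage). On this synthetic record the
pipeline detects a 22-year sulfate remobilization window (fitted ΔS
below the MAE-derived threshold of 20 mmol_IE m⁻² from 1995 to 2017),
finds that ~83 % of the initial topsoil S stock remains, buffers ~97 %
of the proton load in the topsoil, and recovers the tight coupling of
proton load to nitrate discharge (R² = 0.90):

```r
report$summary$r2_proton_load_no3_seepage
#> [1] 0.9007
```

Dry deposition of sulfate collapses over the span, as designed into the
scenario — about 123 mmol_IE m⁻² yr⁻¹ in 1985 and ~0 (occasionally
negative, flagged) by 2019:

```r
dry_deposition_estimate(report$annual_fluxes, "SO4")
```

Desk-scale conversions reproduce published worked values:

```r
mass_flux_to_equivalent_flux(9.7, "NH4")   # 69.25  (~69 mmol_IE m-2 yr-1)
mass_flux_to_equivalent_flux(0.9, "SO4")   # 5.61   (~5.5)
molar_stock_to_mass_stock(2281.3, 32.06)   # 731.4 kg ha-1
livestock_units(1069900, 642540)           # 1172706.4
```

Each result type has a plot helper (`autoplot()` on trend fits,
`plot_annual_fluxes()`, `plot_storage_trajectory()`,
`plot_proton_budget()`, `plot_sn_ratio()`) and the trend-fit object has
broom-style `tidy()`, `glance()` and `augment()` methods. See the
vignette (`vignettes/element-budgets.Rmd`) for the model, its
assumptions and every tunable default.

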