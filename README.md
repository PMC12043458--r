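# ofsgrain

`ofsgrain` is an R package for evaluating **agronomic biofortification of
wheat by organic fertilizer substitution (OFS)** — replacing 15% or 30% of
chemical nitrogen fertilizer with organic fertilizer — from field-trial
agronomy all the way to population health and economic impact. It is aimed
at agronomists and nutrition/public-health modellers who need a tested,
reproducible pipeline from plot-level trial data (observed or simulated) to
treatment comparisons, nutritional quality indices and an ex-ante
disability-adjusted life year (DALY) assessment.

## What it computes

**Nutritional yield.** For a nutrient with grain content *C* (mg kg⁻¹), dry
grain yield *GY* (kg ha⁻¹) and daily reference intake *DRI*:

    NY = C · GY / DRI / 365        (adults ha⁻¹ year⁻¹)

the number of adults whose annual reference intake one hectare can satisfy.
Energy uses 339 kcal per 100 g of wheat (4.184 kJ kcal⁻¹) against a DRI of
8.47 MJ day⁻¹; mineral DRIs are Fe 13.00, Mn 2.05, Cu 0.90, Zn 9.50
mg day⁻¹.

**Bioavailability.** Phytate-to-mineral molar ratios
(PA/*M* = (PA/660.04)/(mineral/molar mass)), the standard inverse proxy for
mineral absorption, with the conventional absorption-friendly thresholds
PA/Zn < 15 and PA/Fe < 1.

**Trial statistics.** Closed-form one-way ANOVA, Fisher's LSD pairwise
comparisons encoded as compact significance letters (insert-and-absorb),
descriptive statistics with CV, and Pearson correlation — the standard
reporting toolkit for multi-site fertilizer trials.

**Health and economic impact.** For each OFS treatment, coverage scenario
(20% pessimistic / 60% optimistic) and demographic group: the grain Fe/Zn
increase over a reference treatment is carried through milling recovery
(21.7% Fe, 31.0% Zn) into additional daily intake, % of the recommended
nutrient intake (RNI), a linear deficit gap closure, DALYs saved
(burden × coverage × gap), % reduction of the current burden, and a net
economic benefit (DALYs saved × per-capita net income − organic fertilizer
cost over the cultivated area).

**Synthetic trials.** A calibrated generator reproduces the 5-site ×
5-treatment × 3-replicate design with the observed means, CVs, treatment
effects and yield–mineral dilution correlation, so the entire pipeline is
testable without the unpublished raw plot data.

## Worked example

```r
library(ofsgrain)

plots <- generate_trial(generator_config(), seed = 1)   # 75 plots
treatment_summaries(plots, variables = "yield")
#> # A tibble: 5 × 6
#>   variable treatment     n  mean    sd letters
#>   <chr>    <chr>     <int> <dbl> <dbl> <chr>
#> 1 yield    OF15         15  9.53  1.47 a
#> 2 yield    OF30         15  9.33  1.21 a
#> 3 yield    OPT          15  9.23  1.26 a
#> 4 yield    FP           15  8.83  1.29 ab
#> 5 yield    CK           15  8.07  1.26 b
```

Yields are in Mg ha⁻¹; treatments sharing a letter are not significantly
different at α = 0.05, so here only the unfertilized control falls behind —
the simulated trial reproduces the calibrated pattern in which 15%
substitution gives the highest yield while the control is significantly
lowest.

```r
energy_nutritional_yield(c(8.00, 9.58))
#> [1] 36.7033 43.9522
```

One control hectare feeds ~36.7 adults for a year on energy; the 15%
substitution treatment ~44.

```r
res <- run_health_assessment(load_health_params())
dplyr::filter(res$groups, nutrient == "Zn", treatment == "OF15")[,
  c("scenario", "group", "intake_with_ofs", "pct_rni", "dalys_saved")]
#> # A tibble: 4 × 5
#>   scenario    group    intake_with_ofs pct_rni dalys_saved
#>   <chr>       <chr>              <dbl>   <dbl>       <dbl>
#> 1 pessimistic Infants             4.96    71.9        771.
#> 2 pessimistic Children            6.12    76.5       5254.
#> 3 optimistic  Infants             4.96    71.9       2313.
#> 4 optimistic  Children            6.12    76.5      15762.
```

Under 20% coverage the 15%-substitution grain saves ~771 infant DALYs per
year in the modelled province; tripling coverage to 60% triples the saving
exactly, because the model is linear in coverage below the gap cap. The
packaged demographic parameters are a synthetic, back-solved set (see
`inst/extdata/health_params_synthetic.yaml`); swap in your own YAML via
`load_health_params()`.

`full_run(run_config(seed = 1, out_dir = "out"))` writes the whole report
bundle (descriptives, treatment letters, molar ratios, impact JSON, log)
deterministically.

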