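---
title: "Methods: from field plots to DALYs with ofsgrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from field plots to DALYs with ofsgrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofsgrain)
```

`ofsgrain` models the chain by which a fertilization practice — partial
substitution of chemical nitrogen by organic fertilizer (OFS) — changes
wheat grain micronutrient density, and what that change is worth
nutritionally, epidemiologically and economically. This vignette explains
each model, its assumptions, the tunable parameters, and the design
choices made where the design was genuinely open.

## Data model and units

A trial is a tibble of plot records: `site`, `treatment` (one of `CK`,
`FP`, `OPT`, `OF15`, `OF30` — unfertilized control, farmers' practice,
optimized fertilization, 15% and 30% organic substitution), `replicate`,
`yield` (dry grain, Mg ha⁻¹), `grain_fe`/`grain_mn`/`grain_cu`/`grain_zn`
(mg kg⁻¹), `phytic_acid` (g kg⁻¹), and optional descriptive `soil_*`
covariates. Units are fixed by column name and never inferred: silent unit
drift (Mg vs kg, g vs mg) is the dominant failure mode for this kind of
arithmetic, so every conversion lives in one documented place in the code.
Yields are treated as oven-dry mass; if your file records fresh weights,
`read_plot_table(..., moisture_fraction = )` converts on ingestion. This
"already dry" default is an assumption, stated here rather than guessed
per file.

Validation is strict and row-addressed: non-positive yields, negative
concentrations, non-integer replicates, unknown treatment labels and
duplicate `(site, treatment, replicate)` keys are all rejected with the
offending rows named. `write_plot_table()` then `read_plot_table()` is an
exact identity on numeric fields.

## The synthetic trial generator

Raw plot-level data for trials of this design are rarely published, so the
generator makes the whole pipeline testable. Its default configuration
encodes the trial conditions the package targets: 5 sites × 5 treatments ×
3 replicates; site mean yields 9.85, 9.47, 7.07, 9.60, 9.31 Mg ha⁻¹
(grand mean 9.06, span 7.07–9.85); grain means Fe 37.13, Mn 31.26,
Cu 4.42, Zn 24.61 mg kg⁻¹ and phytic acid 8.5 g kg⁻¹; total CVs
yield 15.08%, Fe 27.56%, Mn 17.64%, Cu 23.60%, Zn 10.16% (phytic acid
10%, our choice — treatment means of PA typically sit in a narrow
8.2–8.9 g kg⁻¹ band, implying a CV of roughly this size). Treatment
factors are calibrated so that, relative to the control, 15% substitution
raises yield by 19.75% and the substitution treatments raise Fe by 24.69%
and Zn by 19.19%, with Mn, Cu and PA unaffected.

A plot value is `site mean × normalized treatment factor × multiplicative
noise`:

* **Noise model.** Log-normal by default, parameterized by mean and CV,
  because concentrations are strictly positive and CVs reach ~28% — a
  normal model would produce negative Fe contents in the tails. A
  truncated-normal alternative (`noise_model = "truncnorm"`) is offered;
  note it acquires a small positive mean bias at large CV from the
  truncation.
* **Variance allocation.** Configured CVs are *total* variation. At
  config construction they are split into the fixed components implied by
  the treatment factors (and, for yield, the site means) plus a residual:
  `cv_res² = cv_total² − cv_treatment² − cv_site²`, clamped at zero. Site
  effects are multiplicative on yield only; the site-to-site variation in
  grain contents that a real multi-site trial shows is therefore absorbed
  into the plot-level residual. This keeps the treatment calibration exact
  and the total CVs right, at the cost of overstating within-site content
  variation — a documented simplification.
* **Dilution.** Higher-yielding plots tend to have lower mineral
  concentrations (growth dilution). No functional form for this is
  established, so the mechanism is ours: one latent standard-normal plot
  factor loads on the yield residual and (with the sign of
  `yield_content_correlation`, default −0.5) on the four mineral
  residuals, giving residual correlations equal to the configured value
  (recovered to within ~0.01 after the log-normal transform at these CVs).
  Phytic acid is left out of the dilution channel.
* **Reproducibility.** One root seed; per-site streams are derived
  arithmetically from it, and the variance split is frozen when the config
  is built, so appending a site to a config never perturbs the draws of
  existing sites. Identical seeds give bit-identical tables.

`recover_parameters()` closes the loop: at `n_reps = 200` every configured
mean is recovered within 3 standard errors and every CV within 15%
relative error (tested), which is what "calibrated" means here. What
passing these tests does *not* show: the generator has no weather, no
spatial blocking geometry, no site-by-treatment interaction and no
heavy-tailed measurement error, so conclusions about real trials still
require real data.

## Trial statistics

The inferential toolkit is implemented from its closed forms (base R's
`aov()` and `cor.test()` serve as independent oracles in the test suite):

* **One-way ANOVA.** Textbook decomposition `SS_total = SS_between +
  SS_within`, `F = MS_between / MS_within`, p from the upper tail of the F
  distribution. Degenerate inputs follow fixed conventions: no
  between-group variation → `F = 0, p = 1`; zero within-group variance
  with unequal means → `F = ∞, p = 0`.
* **Fisher's LSD.** Pair (i, j) differs iff `|mean_i − mean_j| >
  t(1−α/2, df_w) · sqrt(MS_w (1/n_i + 1/n_j))` at α = 0.05 two-tailed.
  The pairwise decision matrix is encoded as compact letters by the
  insert-and-absorb procedure, so two treatments share a letter *iff*
  they are not declared different (property-tested against a brute-force
  matrix on random instances). Letters start at "a" for the highest mean;
  exact ties fall back to the canonical treatment order CK, FP, OPT,
  OF15, OF30 for reproducibility. The default is *unprotected* LSD
  (letters reported regardless of the global F test), matching how trial
  tables are conventionally lettered; `protected = TRUE` gates the
  pairwise tests on ANOVA significance.
* **Pooling.** Treatment comparisons pool all sites and replicates (n = 15
  per treatment in the default design), matching the one-letter-set
  presentation of multi-site trial tables; per-site analyses are available
  by filtering the plot table. A site-blocked mixed model would be the
  more efficient analysis but is deliberately out of scope.
* p-values are computed from distribution functions, printed to 4
  decimals.

## Nutritional yield and bioavailability

`NY = C · GY / DRI / 365` (adults ha⁻¹ year⁻¹), with C in mg kg⁻¹, GY
converted from Mg ha⁻¹ to kg ha⁻¹, and DRIs of 13.00 (Fe), 2.05 (Mn),
0.90 (Cu), 9.50 (Zn) mg day⁻¹. Energy uses 339 kcal per 100 g and a DRI
of 8.47 MJ day⁻¹; the kcal→MJ factor is fixed at the thermochemical
4.184 kJ kcal⁻¹ (the choice among 4.184/4.186/4.2 moves the result by
<0.1%). NY is bilinear in content and yield (property-tested). The
default summary computes NY per plot and averages within treatment
(matching mean ± SD table presentation); applying the formula to
treatment means instead differs by the mean-of-products vs
product-of-means gap, about 1–5% at these CVs — both modes are exposed.

Phytate molar ratios use fixed molar masses: phytic acid
(C₆H₁₈O₂₄P₆) 660.04, Fe 55.845, Mn 54.938, Cu 63.546, Zn 65.38 g mol⁻¹.
The ratio is invariant under common rescaling of both concentrations and
strictly decreasing in mineral content. Absorption-friendly thresholds
are < 15 for PA/Zn and < 1 for PA/Fe; no thresholds exist for Mn/Cu, so
`bioavailability_flag()` refuses them rather than inventing one. Typical
wheat values (PA ≈ 8 g kg⁻¹, Zn ≈ 25 mg kg⁻¹) give PA/Zn ≈ 33 — far above
the threshold, which is why fertilization alone improves but does not
solve bioavailability.

## The health and economic model

For each nutrient (Fe, Zn), OFS treatment and coverage scenario, per
demographic group:

1. Δcontent = OFS grain content − reference grain content. The reference
   defaults to the optimized-fertilization treatment `OPT` (the policy
   question is "switch from optimized chemical fertilization to OFS", not
   "fertilize vs nothing"); it is configurable.
2. additional intake = Δcontent × (wheat intake / 1000) × milling
   recovery. Fe and Zn sit mostly in the bran, so only 21.7% of Fe and
   31.0% of Zn survive into flour.
3. intake with OFS = baseline + additional; % RNI = 100 × intake / RNI.
4. gap closure = min(1, additional / (RNI − baseline)), 0 for groups at or
   above the RNI. This **linear capped deficit fraction is the package's
   own modelling choice**: ex-ante DALY frameworks delegate this step to a
   dose–response assumption, and the linear form is the simplest one
   consistent with exact coverage linearity. It is isolated in one
   operation (`gap_closure()`) precisely so a sigmoidal or
   intake-distribution form can be swapped in.
5. DALYs saved = baseline burden × coverage × gap closure, with coverage
   0.20 (pessimistic) or 0.60 (optimistic) — hence the exact 3× relation
   between the scenarios, which the acceptance tests check.
6. % burden reduction = 100 × saved / Σ group burdens;
   economic benefit = total DALYs saved × PCNI − 900 RMB ha⁻¹ × 4.0 × 10⁶
   ha (flat organic-fertilizer cost over the provincial wheat area; labor
   is assumed comparable between fertilizer regimes).

A De Steur-style burden calculator (`dalys_lost()`) is provided for
building baseline burdens from mortality, life expectancy and morbidity
outcomes; discounting defaults to off (r = 0), with
`(1 − e^{−rL})/r` available for the common 3% convention — a documented
option, not an asserted setting.

The packaged parameter file `health_params_synthetic.yaml` is **synthetic**:
RNIs, burdens and PCNI are back-solved (arithmetic in the file's comments)
to be internally consistent with the reference scenario table the package
targets at 15% substitution. Two things cannot be made simultaneously
consistent under any single gap-closure model: the per-group saved-DALY
rows and the printed total-burden percentages, and the four economic cells
under one PCNI. The model therefore reports `% reduction` against the sum
of the configured group burdens and treats absolute economic output as
property-tested (linearity, sign, cost offset) rather than reproduced.
Within those limits, the 15%-substitution intake, %RNI and DALY columns
are reproduced to rounding, and the 30% columns to a few percent (their
printed intake and DALY rows are mutually inconsistent at rounding
precision; the fixture follows the intake rows).

## Numerical and testing choices

Degenerate inputs have fixed conventions (see above); concentrations can
never go negative under either noise model; all randomness flows from
explicit seeds. Test problem sizes are chosen to make Monte-Carlo error
negligible while keeping the suite fast: 200 random instances for the
letter-display equivalence, 10,000 null replicates for the ANOVA type-I
error (3 binomial SEs ≈ ±0.65 percentage points around 5%), 200
replicates per cell for generator parameter recovery, and 10,000 plots for
dilution-correlation recovery.

## Known limitations

No site-by-treatment interaction or mixed-effects analysis; no absorption
model beyond the molar-ratio proxy (no Miller-type equations); no
uncertainty propagation over the DALY parameters (point estimates only);
the generator's content variation is not spatially structured; and the
economic module prices DALYs with a single PCNI scalar.
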