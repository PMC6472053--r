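# milknmr

Proton-NMR lipid profiling of bovine milk: simulate 1D ¹H spectra of milk
lipid extracts with known fatty-acid composition, quantify minor
unsaturated fatty acids from signal integral ratios, and discriminate
organic from conventional milk cohorts with a PLS-DA chemometrics
workflow.

## What it does

Milk fat is a triacylglycerol mixture whose minor unsaturated chains —
linoleic, α-linolenic, the conjugated linoleic acid (CLA) isomers and
caproleic acid — are sensitive markers of the production system (organic,
forage-based feeding vs conventional, concentrate-based). A single ¹H
spectrum of the lipid fraction resolves diagnostic signals for each, so
composition can be read off as integral ratios. With
`I_TL = I₀.₈₈ + I₀.₉₅` (three methyl protons per acyl chain) the package
computes, as mole % of acyl chains:

- α-linolenic = 100 · 3 I₂.₈₁ / (4 I_TL)  (4 bis-allylic H per chain)
- linoleic = 100 · 3 I₂.₇₇ / (2 I_TL)  (2 bis-allylic H)
- cis/trans CLA = 100 · 3 I₆.₂₈ / I_TL  (H11, 1 H)
- trans,trans CLA = 100 · 3 I₅.₉₉ / (2 I_TL)  (H10 + H11)
- caproleic = 100 · 3 I₅.₈₀ / I_TL, cross-checked against 100 · 3 I₄.₉₉ / I_TL
- **UFA = 100 (D + 2 I₄.₉₉) / (2 C)** with D the allylic (2.02 ppm) and C
  the α-carbonyl (2.33 ppm) integral — the `2 I₄.₉₉` term corrects for
  caproleic acid, the only milk MUFA whose terminal double bond carries 2
  instead of 4 allylic protons
- SFA = 100 − UFA, MUFA = UFA − PUFA − CLA, ω-6:ω-3 = 2 I₂.₇₇ / I₂.₈₁

Around the equations sit a forward simulator (Lorentzian lines, areas ∝
mole fraction × proton count × Ernst-angle steady-state relaxation
factor, first-order multiplets, Gaussian noise), spectrum processing
(shift referencing at 0.172 ppm, window integration, 0.01-ppm bucketing of
0.03–6.34 ppm into 631 bins) and the multivariate layer: methyl-sum
("NorCont") normalization, Pareto scaling, PCA, NIPALS PLS-DA, VIP
scores, segmented cross-validation (Q², % correct, Fisher's exact test),
permutation validation and Hotelling-T² outlier screening.

## Worked example

```r
library(milknmr)

# one organic-type spectrum: simulate, recalibrate, quantify
sp <- simulate_spectrum(milk_preset("organic"), seed = 1)
sp <- reference_shift(sp)
round(composition_report(extract_integral_set(sp)), 3)
#>   alpha_linolenic linoleic cla_ct cla_tt caproleic    ufa   mufa    sfa omega_ratio
#> 1           1.059    3.057  0.972  0.203     0.222 28.024 22.733 71.976       2.888
#> Warning: caproleic estimates from H9 (0.199%) and H10a (0.244%) disagree by
#> more than 10% relative
```

The seeded composition was 1.05% α-linolenic, 3.05% linoleic, 1.0%
cis/trans CLA, 0.2% trans,trans CLA, 0.2% caproleic and 28.0% UFA — each
recovered to within the integration noise of one spectrum. The caproleic
warning is the built-in cross-check between its two one-proton estimates,
which is noise-limited for so small a signal.

```r
# a 14 organic + 16 conventional cohort, classified end to end
coh <- simulate_cohort(cohort_spec(n_per_class = c(organic = 14, conventional = 16),
                                   seed = 11))
bm  <- normalize_norcont(bucket_matrix(coh$spectra, coh$classes, coh$sample_ids))
scaled <- pareto_scale(bm)
fit <- plsda_fit(scaled, bm$classes, n_components = 2)
fit
#> <plsda_model> 2 component(s), classes organic vs conventional, R2Y(cum) = 0.832
plsda_cv(scaled, bm$classes, n_segments = 7, seed = 2)
#> <validation_report> Q2 = 0.792, 100.0% correct, Fisher p = 6.88e-09
permutation_test(scaled, bm$classes, n_permutations = 100, seed = 3)
#> <permutation_report> 100 permutations; R2Y = 0.832, Q2 = 0.785;
#> intercepts R2 = 0.109, Q2 = -0.351; model valid
```

A perfectly classified 14-vs-16 cohort gives the Fisher exact p-value
1/C(30,14) ≈ 6.9 × 10⁻⁹; the negative Q² permutation intercept is the
standard validity reading. `run_pipeline(run_config(...))` wires the same
steps (plus outlier screening, VIP scoring, figures and a run manifest)
into one reproducible run directory, and `make_report()` renders it as
markdown.

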