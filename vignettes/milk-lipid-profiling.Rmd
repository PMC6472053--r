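---
title: "Quantifying and classifying milk lipid profiles from 1H-NMR spectra"
author: "milknmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying milk lipid profiles from 1H-NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bovine milk fat is a mixture of triacylglycerols whose acyl chains range
from butyric acid (4:0) to polyunsaturated C18 species. A handful of minor
unsaturated chains — linoleic (18:2 n-6), alpha-linolenic (18:3 n-3), the
conjugated linoleic acid (CLA) isomers and caproleic acid (9-decenoic) —
carry most of the nutritional interest and respond strongly to the feeding
regime, which makes them natural markers for distinguishing organically and
conventionally produced milk. A single 1D proton spectrum of the extracted
lipid fraction resolves diagnostic resonances for each of these species, so
their mole percentages can be read off as ratios of signal integrals, and
the bucketed spectrum doubles as a multivariate fingerprint for
classification.

`milknmr` implements that entire analysis as testable code: a forward
simulator that generates lipid-extract spectra from known compositions, the
integral-ratio quantification equations, and the chemometric workflow
(normalization, Pareto scaling, PCA, PLS-DA with VIP scores, segmented
cross-validation, permutation validation, Fisher's exact test, Hotelling
T-squared outlier screening).

```{r, eval = FALSE}
library(milknmr)
sp <- simulate_spectrum(milk_preset("organic"), seed = 1)
composition_report(extract_integral_set(reference_shift(sp)))
```

## The forward model

`simulate_spectrum()` builds a spectrum as a sum of Lorentzian lines. Each
entry of `assignment_table()` — a proton group of one acyl species, with its
chemical shift, proton count per chain, optional first-order couplings and
longitudinal relaxation time T1 — contributes area

```
mole fraction x protons per chain x lipid scale x steady-state factor(T1)
```

The steady-state factor is the fraction of equilibrium magnetization
available per scan under repeated pulsing,

    f = (1 - E) / (1 - E cos(theta)),  E = exp(-TR / T1),

with recycle time TR and flip angle theta. At the default operating point —
TR = 9.3 s and a 30-degree pulse — even the slowest-relaxing milk lipid
protons (the caproleic terminal vinyl pair, T1 = 3.2 s) retain 99.2% of
their equilibrium signal, so integrals are quantitative to within a
fraction of a percent. The factor is monotone increasing in TR and
decreasing in flip angle; `steady_state_factor()` exposes it directly.

Only the caproleic terminal-vinyl T1 is an experimentally anchored milk
value; the remaining groups carry plausible lipid-extract values between
0.7 and 2.5 s, chosen so that 3.2 s remains the slowest relaxer. These
values affect only the realism of simulated intensities (sub-percent
effects at TR = 9.3 s), not any quantification equation.

Multiplets are simulated by first-order splitting with binomial
intensities (the butyric C2 triplet, 3J = 7.2 Hz, is the one structured
pattern encoded); this is sufficient because quantification consumes
window integrals, not lineshapes. Glycerol-backbone signals are added at
one backbone per three chains plus a small 1,2-diacylglycerol term, and
the chemical-shift reference (hexamethylcyclotrisiloxane) is placed at
0.172 ppm with a fixed, lipid-independent area. Gaussian noise of standard
deviation `noise_sd` (default 0.05, in units where one proton at unit
lipid scale has unit area) is added last.

Default linewidth is 0.8 Hz FWHM at 500 MHz — roughly the natural width of
well-resolved lipid resonances in CDCl3 plus the 0.3 Hz exponential
broadening conventionally applied before Fourier transform. The choice
matters: Lorentzian tails are heavy, and the fraction of a line's area
captured inside a finite integration window (or leaking into a
neighbouring one) scales with the linewidth. At 0.8 Hz the complete
simulate-integrate-quantify chain recovers every seeded mole percentage
to within 0.05 percentage points over the realistic milk composition
envelope (butyric 8-13, lumped saturates 55-72, oleic pool 15-28,
linoleic 1-4, alpha-linolenic 0.4-1.5, cis/trans CLA 0.3-1.2,
trans,trans CLA 0.05-0.3, caproleic 0.15-0.6 mol%); at 1.5 Hz the
allylic/alpha-carbonyl tail imbalance alone can push the total-UFA error
past 0.1 points.

## Quantification

All percentages are mole percent of acyl chains. The chain count comes
from the terminal methyls: every methyl-bearing chain contributes three
protons to `I_TL = I0.88 + I0.95`, so for a signal with `k` protons per
chain of species `s`, the mole percentage is `100 * 3 I_s / (k I_TL)`:

| quantity          | integral           | protons per chain |
|-------------------|--------------------|-------------------|
| alpha-linolenic   | I2.81 bis-allylic  | 4                 |
| linoleic          | I2.77 bis-allylic  | 2                 |
| cis/trans CLA     | I6.28 (H11)        | 1                 |
| trans,trans CLA   | I5.99 (H10 + H11)  | 2                 |
| caproleic         | I5.80 (H9) or I4.99 (H10a) | 1         |

Caproleic acid is estimated twice, from two chemically independent
one-proton signals; `pct_caproleic()` returns both and warns when they
disagree by more than 10% relative. Under the default noise level this
cross-check is dominated by integration noise on two very small signals,
so occasional warnings on single noisy spectra are expected behaviour, not
a defect.

Total unsaturation uses the allylic integral `D` (2.02 ppm) and the
alpha-carbonyl integral `C` (2.33 ppm):

    UFA% = 100 (D + 2 I4.99) / (2 C)

Every internally unsaturated chain carries 4 allylic protons into `D` and
every chain carries 2 protons into `C`. Caproleic acid is the only milk
MUFA with a terminal double bond: it brings just 2 allylic protons, so its
deficit is restored from the one-proton 4.99 ppm integral (`+ 2 I4.99`
adds back 2 proton-equivalents per caproleic chain). Both structural
limits check out exactly — a pure-oleic and a pure-caproleic pool each
evaluate to 100% — and the published rendering of this equation, whose
typography is ambiguous, is resolved in favour of the form that satisfies
those limits. SFA is the complement `100 - UFA`; MUFA subtracts the
individually quantified PUFA and CLA percentages from UFA; the
omega-6:omega-3 ratio reduces to `2 I2.77 / I2.81`.

One bookkeeping subtlety: caproleic acid has no terminal methyl (its chain
ends in `CH2=`), so it is invisible to `I_TL`. Percentages referenced to
`I_TL` therefore slightly overstate species fractions, by a factor of about
`1/(1 - f_capro)`. At realistic caproleic levels (0.2-0.6 mol%) this bias
is below 0.03 percentage points — smaller than the method's integration
noise — and is accepted rather than corrected.

Negative integrals (possible under noise) are floored at zero with a
warning before any equation runs; a `D` below the caproleic-only floor
`2 I4.99` is clipped up with a warning; UFA above 100% or MUFA below 0% is
clipped with a warning. These rules keep percentages interpretable without
masking the anomaly (every clip is reported, and `run_pipeline()` persists
all warnings in the run manifest).

## Integration windows

The published method names integral centres, not bounds, so the bounds are
this package's declared convention (`integration_windows()`, all
overridable). Three choices deserve explanation:

- **I0.88 = 0.82-0.92, I0.95 = 0.92-1.02 ppm.** The two methyl windows are
  adjacent; cross-boundary leakage stays inside their union, so `I_TL` is
  insensitive to the split. The 0.98 ppm alpha-linolenic methyl —
  deshielded by its n-3 double bond — is deliberately covered by the I0.95
  window.
- **D = 1.93-2.09 ppm** follows the allylic region as used in the marker
  analysis, leaving the adjacent 2.09-2.18 ppm band (treated separately
  there) untouched.
- **C = 2.23-2.43 ppm** is set wider and more symmetric than a minimal
  window around 2.32/2.33 ppm, for a quantitative reason: UFA is a `D/C`
  ratio, and with both windows truncating comparable Lorentzian tail
  fractions the truncation bias cancels to first order. The window still
  begins above 2.18 ppm, so the separately treated band stays excluded.

Integration is plain trapezoidal quadrature on the native axis with exact
interpolation at window bounds, no resampling. A per-window linear
baseline (chord through the endpoint intensities) is available but off by
default: on simulated, baseline-free spectra the chord subtracts part of
each peak's own tail and makes recovery worse; it is useful only for real
spectra with residual baseline curvature.

## Bucketing and normalization

`bucket_spectrum()` segments 0.03-6.34 ppm into 631 half-open 0.01-ppm
bins `[left, right)`; the half-open convention (left edges at
`0.03 + 0.01 k`) is declared because the method description does not fix
one. Buckets are computed from the same cumulative-integral machinery as
the windows, so they partition the region exactly: their sum equals the
full-range integral to machine precision.

Two data series feed the chemometrics. `UNor` uses bucket areas as they
are. `NorCont` multiplies each bucket by 3 and divides by the sample's
methyl bucket sum — each bucket then reads as content per acyl chain, which
removes per-sample total-lipid (fat content) differences exactly. One
caveat is intrinsic to the design: the shift-reference peak has a fixed
area per tube, so after NorCont its buckets vary *inversely* with lipid
content. The exact-invariance property is therefore stated (and tested) on
spectra simulated without the reference peak; in full pipelines the effect
is confined to the few buckets around 0.172 ppm.

Pareto scaling (centre, divide by the square root of the column standard
deviation) is applied before PCA/PLS-DA, damping the dominance of the
intense methylene envelope without inflating pure-noise buckets;
constant columns map to zero.

## Chemometrics

PCA is the singular value decomposition of the centred matrix (via
`stats::prcomp`). PLS-DA is a NIPALS implementation written in the
package: latent variables are extracted iteratively (tolerance 1e-12 on
the score vector, at most 500 iterations per component, convergence
failure is an error naming the component) against the centred one-hot
class matrix, deflating both blocks per component. Class prediction uses
the regression coefficients `W (P'W)^-1 Q'` and an argmax rule over the
predicted membership columns (equivalent to a 0.5 threshold for two
classes).

Cross-validation uses stratified random segments (default 7, the common
commercial-software convention); an explicit segment assignment can be
passed instead, e.g. to keep technical replicates of one sample in one
segment. `Q2 = 1 - PRESS/TSS` pools squared out-of-fold prediction errors;
the pooled out-of-fold confusion matrix yields the percentage of correct
predictions and a two-sided Fisher exact p-value (perfect separation of
14 vs 16 samples gives `1/choose(30,14) = 6.9e-9`).

VIP scores follow the standard definition (weights squared, weighted by
the Y-variance each component captures, scaled so the mean squared VIP
is 1); buckets with VIP > 1 are conventionally "important". The
permutation test refits model and cross-validation under label
permutations (default 100) and regresses both R2Y and Q2 on the absolute
correlation between permuted and original labels — the SIMCA-style
validity reading: all permuted values below the originals and a negative
Q2 intercept. Outlier screening computes Hotelling T-squared on the score
columns against the F-based 95% limit (the score-plot confidence
ellipse); `run_pipeline()` applies it one-shot — flag, drop, refit once —
mirroring the usual exclude-and-refit practice, with zero-variance
components dropped from the statistic. Marker t-tests default to Welch
(the pooled variant is available); no multiple-testing correction is
applied by default because raw per-marker p-values are the convention in
this workflow, but `stats::p.adjust` composes trivially downstream.

## The synthetic cohorts

`cohort_spec()` encodes the study conditions the package is tested
against. The class presets place total unsaturation at 28 mol% (organic)
versus 24 mol% (conventional), with the organic preset higher in
cis/trans CLA (1.0 vs 0.6), linoleic (3.05 vs 2.2) and alpha-linolenic
(1.05 vs 0.8) and lower in caproleic (0.2 vs 0.35), and omega-6:omega-3
ratios near 2.9 and 2.75 — the direction and rough magnitude of the
reported organic/conventional contrasts. The default cohort geometry is
14 organic + 16 conventional samples; every organic sample carries
lipid-scale 1 (semi-skimmed) while conventional samples alternate between
scales 1 and 2, emulating a cohort whose conventional half splits between
1.5% and 3% fat.

Per-sample compositions are the class preset perturbed by mean-preserving
lognormal jitter (default 5% relative per species) and renormalized —
lognormal so fractions stay positive by construction. A single cohort
seed drives everything; per-sample noise seeds are drawn from it, so
cohorts are exactly reproducible.

What the simulator does *not* emulate: phase and baseline distortions,
solvent and water artifacts, peak-position drift with temperature or pH,
the many minor milk lipid resonances (cholesterol, phospholipid head
groups, the 2.09-2.18 ppm band), inter-chain shift differences within the
lumped pools, t1-noise, or any matrix effect on T1. Passing tests
therefore demonstrate that the equations, windows and multivariate
machinery are internally correct and statistically well-behaved under the
stated noise model — not that the pipeline is robust to every artifact of
real spectra; real data still need the usual phasing/baseline care
upstream.

## Numerical choices and problem sizes

- Trapezoidal quadrature everywhere; bins and windows share one
  cumulative-integral routine, making partition additivity exact.
- Axis stored descending (display convention); ascending input is
  flipped on construction; reference recalibration requires the candidate
  peak to clear median + 10 MAD of the intensity distribution.
- NIPALS tolerance 1e-12, max 500 iterations; PLS components default
  to 2 (the score planes usually inspected), configurable.
- Default test and validation sizes: cohorts of 14 + 16 or 20 + 20
  samples at 16384 axis points, a 200-point Latin hypercube for the
  round-trip suite, 50-100 permutations — sizes at which the full suite
  runs in a few minutes on one core while keeping every statistical
  check well-powered.
- RNG seeds are explicit arguments on every stochastic function.

## Limitations

- Quantification assumes baseline-corrected, well-phased input; only a
  simple linear per-window baseline option is provided.
- The CLA cis/trans isomers co-resonate at 6.28 ppm and are quantified as
  a lump, as is the 6:0-18:0 saturated pool and the internal-double-bond
  MUFA pool.
- Absolute (mM) quantification is out of scope; the internal standard is
  used only for shift referencing.
- Two-class designs only; no OPLS-DA, no batch correction.
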