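---
title: "Methods: aquaphotomics of drought-stressed leaves with aqualeaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aquaphotomics of drought-stressed leaves with aqualeaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqualeaf)
```

`aqualeaf` analyses near-infrared absorbance spectra of leaves measured
during a drought time course. This vignette explains the models and
procedures the package implements, the choices that were genuinely open
when it was designed, and what its synthetic-data tests do and do not
demonstrate about real instrument data.

## The data model

A `SpectraSet` holds an `n_spectra x n_bands` absorbance matrix
(log(1/R) convention; reflectance calibration is out of scope) on a
strictly ascending wavelength grid, with per-spectrum metadata: genotype
(`line_label`), `plant_id`, `leaf_index` (leaves 2–4), `replicate` (three
measurement positions per leaf), `treatment`
(control / stress / recovery), measurement `day` and a free-text
`stage_tag`. The canonical exchange format is wide CSV — metadata columns
first, then one column per band named by its wavelength in nm — chosen
over vendor formats because it is human-readable, diffable and lossless
(absorbance survives a round trip to better than 1e-10; wavelengths and
metadata exactly).

Two low-level conventions matter downstream. Grids supplied in any order
are normalised to ascending on load, so derivative filters see a single
orientation. `nearest_band_index()` breaks exact-midpoint ties toward the
lower wavelength (with a small floating-point tolerance); ties are
measure-zero on real grids but the rule makes the WAMAC-to-band mapping
deterministic.

## Two pretreatment paths that never mix

The pipeline applies different pretreatments depending on the destination
of the spectra:

* **Aquagram path**: raw absorbance → multiplicative scatter correction
  (MSC) → normalised absorbance. MSC fits each spectrum against the set
  mean by ordinary least squares, `x ≈ a + b·reference`, and corrects to
  `(x − a)/b`, removing the additive offsets and multiplicative scaling
  caused by leaf thickness and surface scattering. The reference is the
  mean of the set being corrected — the canonical MSC choice when no
  master reference exists; `msc_apply()` carries a stored training
  reference to new spectra.
* **Calibration path**: raw absorbance → Savitzky–Golay second
  derivative → restriction to 1300–1600 nm → PLS. The second derivative
  suppresses baseline and enhances band structure; the window restricts
  the model to the first overtone of water.

### Savitzky–Golay settings

The SG filter fits a local polynomial by least squares in a sliding
window and reads off the second derivative at the window centre. Defaults
are `window = 11` points, `polyorder = 2`, `deriv = 2`, i.e. an 11-point
quadratic — a common chemometrics choice at a ~6 nm pixel pitch, wide
enough to suppress noise without flattening the water bands, and every
setting is overridable through `sg_config()`. The software used in
published studies rarely reports its window, so this default is a
package choice, not a reconstruction; results at other windows are a
configuration away. Edge bands where the window does not fit are
*dropped*, not padded: padded derivatives are artifacts, and all analyses
here use interior water bands. The derivative is exact on polynomials up
to the fit order (a property the tests exercise), and `scale = "per_nm"`
divides by the squared grid step for a true d²A/dλ².

## The aquagram

For each of the 19 water matrix coordinates (WAMACs) `λ` the package
computes the normalised absorbance

> Aq_λ = (A_λ − μ_λ) / σ_λ

where `μ_λ` and `σ_λ` are the mean and standard deviation of the
absorbance of **all** spectra passed in, at that wavelength. Design
choices, each configurable but defaulted deliberately:

* `σ_λ` is the sample (n−1) standard deviation, matching common
  statistical software.
* The normalisation population is all spectra together
  (control + stress + recovery), not per group: a shared `μ, σ` is what
  makes the group patterns comparable on one radar chart.
* Aq is computed on MSC-corrected raw absorbance, not on derivatives —
  scatter correction first, normalisation second.
* Each spectrum is normalised individually and group aquagrams are means
  of per-spectrum Aq (rather than normalising group-mean spectra); this
  order keeps per-spectrum values available for the significance tests
  and makes group means size-weighted consistent (they sum to zero over
  the population at every WAMAC).
* WAMACs are mapped to the nearest instrument band; a warning is issued
  when the nearest band is further than half a grid step.

The WAMAC table (`default_wamacs()`) spans 1347.9–1570.9 nm: hydration
and trapped water below 1391 nm, free water at 1409.8 nm, water with 1–4
hydrogen bonds through 1440–1490 nm, and strongly bound / structural
water interacting with protein and cellulose above 1460 nm.

## Significance machinery

Group differences at each WAMAC are tested on the per-spectrum Aq values
with a two-stage procedure: Levene's test for equality of error variances
(group-mean centred, via `car::leveneTest`) gates, at a configurable 0.05
threshold, between Tukey's HSD (homoscedastic case, via `stats::TukeyHSD`)
and Dunnett's T3 (heteroscedastic case) for all pairwise comparisons.
Pairs are labelled with strength bands at cut points 0.001, 0.01 and
0.05, boundary values falling in the more significant band.

Dunnett's T3 is implemented in-package: Welch-type degrees of freedom per
pair and a studentized-maximum-modulus tail probability approximated by
the independence (Šidák-type) bound `1 − (1 − p_pair)^m` over the `m`
comparisons. The approximation is slightly conservative; the test suite
verifies the property that actually matters — under a simulated global
null the per-pair rejection rate at 0.05 stays within [0.03, 0.07], and
in the significant tail (p ≤ 0.05) T3 and Tukey p-values coincide closely
for balanced homoscedastic groups, so the Levene gate cannot flip
reported strength bands by much. "Multivariate ANOVA" is operationalised
as per-WAMAC univariate comparisons because the output of interest is a
per-wavelength pairwise table, not a global multivariate statistic; true
MANOVA is a non-goal. Replicates of the same leaf enter as independent
observations — a deliberate simplification (see Limitations).

The gravimetric leaf hydration index is also provided:
`rwc(fw, dw, ftw) = 100·(FW − DW)/(FTW − DW)`, with a domain error when
the turgor weight does not exceed the dry weight and clamping (with a
warning) when FW < DW.

## PLS calibration of days of drought

The response is the day of drought; the predictors are second-derivative
spectra in 1300–1600 nm of stress-treatment spectra only (controls have
no defined drought day; recovery spectra are excluded). The model is
mean-centred PLS1 (NIPALS; closed form per factor for a univariate
response) with the regression vector `B = W(PᵀW)⁻¹q`, so prediction is the
affine map `ŷ = ȳ + (x − x̄)·B`. With as many factors as the rank of the
centred design, PLS reproduces ordinary least squares — an oracle
equivalence the tests assert to 1e-8.

Cross-validation honours the replicate structure: one fold per
(plant, leaf, occasion), i.e. exactly the three measurement positions of
one leaf on one day, so no fold is ever predicted from its own replicate
siblings. Folds are visited in sorted label order, making the SECV curve
bit-for-bit reproducible. Per factor count `a`:

* `SECV(a) = sqrt(mean((ŷ_cv − y)²))`, denominator `n` (RMSEP-style; the
  exact denominators of commercial packages are unpublished, so one
  convention is used consistently).
* The chosen dimension is the argmin of the SECV curve, ties toward
  fewer factors; the search range defaults to 1–10.
* `SEC` is the analogous calibration error of the full-data fit at the
  chosen dimension; `R²cv`/`R²cal` are squared Pearson correlations, with
  the `1 − PRESS/SStot` variant also reported (`r2cv_press`) because
  reporting conventions differ between packages.

Interpretation outputs mirror standard chemometrics practice: the
regression vector per wavelength, the correlation spectrum (per-band
Pearson r against the response; zero-variance bands get r = 0 with a
warning), and `important_bands()` ranking bands by |coefficient|.

## The synthetic experiment

Real spectra from such studies are rarely deposited, so the package
carries a generator that emulates the *statistical structure* the
analysis assumes, with closed-form ground truth. The design constants are
the study conditions: two inbred lines (one drought-sensitive, onset
day 3; one tolerant, onset day 7), 10 stressed + 10 control plants per
line, leaves 2–4, three replicate positions, measurements on drought days
3, 7, 10, 12, 14, 17 and on days 3–4 after rewatering — 2880 spectra in
the default experiment.

The forward model is a sum of Gaussian bands over a gently sloping
baseline: the 930 and 1155 nm water bands plus the 19 WAMACs, with widths
12–20 nm. Stress moves band amplitudes linearly after the line's onset
day: the free / weakly bound group (≤ 1422 nm, dominated by a
0.010 absorbance/day decline at 1409.8 nm) shrinks while the strongly
bonded group (≥ 1441 nm, +0.005/day) grows — the inverse relationship
characteristic of dehydrating leaves. Recovery spectra hold the day-17
state (leaves do not rehydrate within the rewatering window) with a small
extra gain above 1500 nm where bound, cellulose-associated water
dominates desiccated tissue. Wavelengths sit on a uniform 6.1945 nm pixel
pitch spanning 908–1670 nm (124 bands), with the 19 grid points nearest
the WAMACs snapped to their exact coordinates.

Noise terms, each defaulted to what a handheld NIR instrument on leaves
plausibly shows and all configurable:

| parameter | default | meaning |
|---|---|---|
| `scatter_slope_sd` | 0.05 | per-spectrum multiplicative scatter `b ~ N(1, ·)` |
| `scatter_offset_sd` | 0.01 | per-spectrum additive offset (absorbance) |
| `noise_sd` | 0.003 | iid band noise (absorbance) |
| `leaf_effect_sd` | 0.02 | per-(plant, leaf) multiplicative amplitude effect |
| `progression_jitter_sd` | 0.12 | relative per-(plant, occasion) drying-rate jitter |

The progression jitter deserves its own paragraph because it was a
genuine design decision. Individual plants do not dry at identical rates;
the generator models this as `effective days past onset
= max(0, day − onset)·(1 + jitter)`, with the jitter shared by all leaves
and replicates of a plant on one occasion. Scientifically it is the
dominant irreducible error of any drought-day calibration — a perfect
spectral model can only read the plant's actual hydration state, not the
calendar. Statistically it gives the grouped-CV SECV curve a genuine
minimum at a small number of factors: without it the curve is nearly flat
beyond two factors and its exact argmin wanders with the seed, because
additional factors keep chipping away at scatter-induced structure. The
closed-form attainable error is exposed as `expected_day_rmse()`
(≈1.05 days for the sensitive line, ≈1.33 for the tolerant line, whose
days 3 and 7 are spectrally indistinguishable by construction), and the
test suite checks that the PLS SECV lands within [0.8, 1.5] of it.
Multiplicative jitter (rather than additive day noise) keeps the tolerant
line exactly at baseline through its onset day, preserving the
early-drought contrast between genotypes.

**What the generator does not emulate**: asymmetric band shapes and band
position shifts with hydrogen bonding, temperature effects, instrument
drift, detector nonlinearity, water-vapour interference, and any
radiative-transfer description of leaf optics. Passing tests therefore
demonstrate that the *pipeline* is correct and well-calibrated on data
with the assumed structure — not that a real instrument in a real
growth chamber will achieve any particular SECV. The amplitude
trajectories are linear after onset (the simplest monotone drying model);
real trajectories saturate.

## Numerical choices and degenerate inputs

* SG kernels are solved from the local-polynomial normal equations; the
  window must be odd, ≥ 5, larger than the polynomial order and smaller
  than the band count.
* MSC refuses spectra whose fitted slope is below 1e-12 in magnitude
  (a flat spectrum carries no scatter information), naming the offending
  spectrum.
* Aquagram normalisation refuses populations of fewer than two spectra
  and WAMACs with standard deviation below 1e-12.
* PLS stops early (with fewer factors) if the residual covariance
  between X and y vanishes, and refuses constant responses.
* Grouped CV caps the factor search at the smallest training fold and
  refuses a single all-encompassing group.
* The pipeline aborts at the first failing stage, naming the stage; all
  outputs are plain CSV/JSON and contain no timestamps, so a fixed seed
  reproduces the bundle byte for byte.

## Problem sizes used in the tests

The test suite runs the full pipeline at the default experiment size
(2880 spectra × 124 bands) across five seeds for the recovery checks
(drought-day R²cv, aquagram sign pattern, genotype onset contrast), uses
1000 simulated null datasets for the post hoc calibration check, and
small analytic fixtures everywhere else. The complete suite and the
reproduction script each run in well under a minute on a laptop-class
machine.

## Known limitations

* Replicate spectra of one leaf are treated as independent observations
  in the significance tables (the grouped structure is honoured only in
  the PLS cross-validation); a mixed-effects treatment would be more
  faithful but is out of scope.
* No multiplicity correction is applied *across* the 19 WAMACs — the
  table reports per-wavelength pairwise comparisons, each adjusted only
  within its group pairs.
* The Dunnett T3 tail probability uses the independence bound rather
  than the exact studentized maximum modulus; it is slightly
  conservative at mid-range p-values.
* Aquagram confidence bands, temperature-perturbation aquaphotomics,
  PLS2, variable-selection schemes (iPLS, VIP) and classification are
  non-goals.
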