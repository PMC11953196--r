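---
title: "Methods: the Photoreceptor Integrity Index and its synthetic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Photoreceptor Integrity Index and its synthetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piin)
```

## The model

A full-thickness macular hole (FTMH) seen en face is a bright annulus of
surviving photoreceptors around a dark lumen. Three areas describe it: the
total hole area TA (inside the hyperreflective edge line), the luminal
area LA, and their difference PRA = TA − LA, the photoreceptor-remnant
annulus. PRA alone is confounded by hole size, so both PRA and LA are
min-max normalized over the study cohort and combined into

$$\mathrm{PIIN} = \frac{\mathrm{NORM\text{-}PRA}}{\mathrm{NORM\text{-}LA} + 1},$$

which is dimensionless and bounded in $[0,1]$ (the $+1$ avoids division by
zero at the cohort's LA minimum). The index is increasing in normalized
PRA, decreasing in normalized LA, and equals normalized PRA exactly when
the eye has the cohort's smallest lumen.

Two consequences matter in practice and are asserted by tests:

* **Cohort relativity.** Scores depend on the cohort min/max; adding an
  eye with a new extreme changes every other eye's score. A fitted
  normalization model can be applied to a prospective eye, either
  strictly (out-of-range is an error, the default) or with clamping into
  $[0,1]$ (`clamp = TRUE`); which behaviour the original protocol intended
  is unstated, so both are provided.
* **Degeneracy.** A cohort with zero range in PRA or LA leaves the index
  undefined; the fit raises an error rather than emitting 0/0, because
  silent zeros would corrupt every downstream statistic.

## Measurement: automated stand-in for a manual protocol

The reference protocol is manual (caliper-free tool, two graders, senior
adjudication). The package automates it as an operator chain on a
grayscale en-face raster of a 3 mm × 3 mm field:

1. Gaussian smoothing, $\sigma = 1$ px (default).
2. Otsu threshold to find the bright ring. If the first split isolates
   the dark lumen instead (bright class > 30% of the field), the upper
   class is re-split — the ring is always a small minority class.
3. *Half-maximum refinement*: the final threshold is the midpoint between
   the background plateau (median of the non-ring class) and the ring
   plateau (75th percentile of the ring class). A blurred step edge
   crosses its half-maximum exactly at the true boundary, so this removes
   the area bias that raw Otsu class boundaries introduce.
4. Morphological closing (disk, 3 px) to bridge speckle gaps, largest
   8-connected component, interior hole filling: the filled region is the
   TA mask (ring included).
5. The lumen is segmented inside the TA mask the same way (Otsu, then
   half-maximum between lumen and ring plateaus), keeping the largest
   dark component, holes filled. A candidate lumen must be darker than
   the image background and at least `min_lumen_contrast` (default 0.15)
   below the ring plateau, otherwise "no lumen" is reported — this
   rejects uniformly bright interiors.
6. Areas are foreground-pixel counts times the squared pixel pitch; no
   sub-pixel refinement. At the default 10 µm/px this is accurate to well
   under 1% for hole-scale structures, and results change by < 2% when
   the same geometry is rendered at 5 µm/px.

All operator parameters live in `seg_params()` and are logged with every
result. Precomputed masks can be supplied to `measure_eye()` to mirror the
manual workflow (and to run intergrader analyses on real gradings).
Pixels are assumed square to 1%; intensities are rescaled to $[0,1]$ on
load. PNG is the supported raster format (8- or 16-bit); the acquisition
steps upstream of the en-face raster (slab selection, device specifics,
signal-strength gating) are out of scope.

## Synthetic phantoms

`generate_phantom()` renders a dark elliptical lumen (semi-axes $a, b$),
a bright ring whose outer boundary is the ellipse grown by the ring width
$w$ in both semi-axes, optionally perturbed radially by
$A\cos(k\theta + \phi)$ ("bumpy border"), on a mid-gray background
(defaults: background 0.40, ring 0.90, lumen 0.05), with optional
multiplicative speckle $I(1+\sigma Z)$ clipped to $[0,1]$. Ground truth is
analytic ($\mathrm{LA} = \pi ab$, $\mathrm{TA} = \pi(a+w)(b+w)$) for
smooth boundaries and 4096-vertex polygon quadrature for bumpy ones
(refinement from 2048 to 4096 vertices changes the area by < 0.5%).

The phantom emulates the *geometry* the measurement stage must solve — a
bright annulus with a dark core, speckle, bumpy borders — and not the
biophysics of OCT speckle, cystic intraretinal spaces (the protocol
excludes them by tracing the edge line), shadowing, or acquisition
artifacts. A green segmentation test therefore establishes that the
operator chain recovers annulus geometry at realistic contrast and noise,
not that it would survive every clinical image.

## Synthetic cohorts

No per-patient data are published, so the cohort generator reproduces the
published *summary* statistics: the baseline five-number summaries
(median, quartiles, range) per variable, the index-vs-variable Spearman
correlations, and the intergrader concordance.

**Margins.** Each variable's margin is a piecewise-linear quantile
function through its five printed statistics, which reproduces
median/q1/q3/min/max exactly and respects the printed range by
construction. The originally considered shifted lognormal (fitted to
median/q1/q3, truncated to the range) is kept as
`margin_family = "lognormal"`, but it cannot fit the minimum-diameter
margin at all (its quartiles are left-skewed) and, truncated at the
printed LA minimum, it shifts the LA median by ~20% — so it is not the
default. The piecewise family's corners are an accepted artificiality.

**Dependence.** A Gaussian copula with a single-factor structure. LA and
PRA are drawn first from a bivariate copula; TA = LA + PRA (conservation
is exact by construction); the index is then computed on the generated
cohort exactly as it would be on real data, and its rank-transformed
value serves as the common factor. Every other variable loads on that
factor with the printed Spearman value, converted to the latent Pearson
scale by $r = 2\sin(\pi\rho_s/6)$. Because the factor is the *computed*
index, the emitted table reproduces each printed correlation within
sampling noise ($\pm 0.05$ at $n = 2000$) without any per-variable
tuning. The single-factor structure implies
$\mathrm{corr}(X_j, X_k) \approx r_j r_k$ for unspecified pairs; the full
inter-variable dependence is not identified by the published table, and
`nearest_psd()` is available for user-supplied full matrices.

Two quantities need more care:

* **Index vs total area** (printed 0.948) is emergent — TA is derived,
  not loadable. It is controlled by the latent LA–PRA correlation, which
  `calibrate_la_pra_rho()` root-finds on a 20,000-eye simulation; the
  calibrated value 0.9517 is the frozen default. Anatomically this says
  large holes have both larger lumens and larger remnant annuli, which is
  what the strong printed TA correlation implies.
* **Change variables.** |∆-BCVA|, |∆-EZ|, |∆-ELM| are drawn from their
  printed margins with their printed loadings, and follow-up values are
  realized as T1 = T0 − ∆ when the change fits inside the baseline
  defect, and T1 = T0 + ∆ (worsening) otherwise. The printed variables
  are absolute changes, so both directions reproduce the margin exactly,
  and no truncation is applied — flooring T1 at zero, the obvious
  alternative, distorts the realized rank correlations by up to ~0.07
  because it replaces the change by the baseline for the floored eyes.
  Each change's copula residual is additionally coupled to its baseline's
  residual (`delta_baseline_coupling = 0.8`, chosen a priori as "recovery
  potential scales with the baseline defect") so that worsening remains
  the minority outcome. The printed table's −0.578 for |∆-BCVA| is used
  as-is even though the surrounding narrative suggests the opposite sign;
  `flip_delta_bcva_sign` flips it for sensitivity runs.

**Grader replicates.** A second grader is modeled as
$X(1+\varepsilon)$, $\varepsilon \sim N(0, \sigma_g^2)$, independently
per area channel (LA and PRA; the replicate TA is their sum). The
channel noise is calibrated to the printed concordance targets
(CCC 0.997 for LA, 0.962 for PRA) by 1-D root finding on a 20,000-sample
Monte-Carlo estimate; the population identity
$\mathrm{CCC} = 2s^2/(2s^2 + \sigma_g^2\,\mathrm{E}[X^2])$ provides an
independent closed form used as a test oracle. The replicate TA
concordance (~0.994) then emerges close to the printed 0.995 without
being targeted.

All randomness flows from one top-level seed expanded into named streams
(cohort, grader, phantom, speckle, geometry), so changing only the grader
seed leaves the primary measurements bit-identical.

## Statistics

All named statistics are implemented in-package and checked against
independent oracles (enumeration, closed forms, and base-R reference
implementations):

* Descriptives: median/q1/q3/min/max with linear interpolation between
  order statistics (quartile convention unstated in the protocol; this is
  the mainstream default, documented so table comparisons reproduce).
* Spearman's ρ with listwise deletion and average ranks for ties;
  two-sided p by the t approximation for $n \ge 10$ and exact permutation
  enumeration below (at most $9! = 362{,}880$ permutations).
* Wilcoxon: the protocol names the two-sample rank-sum test for the
  paired T0/T1 comparison; the default reproduces that literally, and the
  conventional paired signed-rank test is available behind a flag. Exact
  p-values by complete enumeration for small tie-free samples, otherwise
  normal approximation with continuity and tie correction.
* Jarque–Bera with population (1/n) moments, $\chi^2_2$ reference,
  $n \ge 5$.
* Univariate OLS with adjusted $R^2 = 1-(1-R^2)(n-1)/(n-2)$ and two-sided
  slope p.
* Lin's CCC with population moments (Lin's original convention; the
  1/n vs 1/(n−1) choice is unstated in the protocol) and a 95% CI via
  the Fisher z-transform with Lin's asymptotic variance. Degenerate
  cases (perfect agreement, zero cross-correlation) collapse the CI to a
  point rather than propagating an infinite transform.
* Significance flagged at p ≤ 0.05 per test, no multiplicity correction —
  matching the protocol's convention. Exact p-values are printed; the
  published table flattens small p-values to "0.001", which is not
  reproduced.

## Numerical choices and degenerate inputs

* Normalized inputs to the index are validated to $[0,1]$ within 1e-12.
* Otsu's threshold maximizes between-class variance on a 256-bin
  histogram; on a flat argmax plateau (well-separated classes) the
  plateau midpoint is returned.
* Zero-variance vectors raise errors in correlation, concordance,
  normality, and regression rather than returning NaN.
* Missing values: deltas propagate missingness; correlations use listwise
  deletion; tables encode missing as empty fields, never sentinels.
* Exact tests switch to approximations at documented sizes (Spearman
  n ≥ 10; rank-sum when ties or $\binom{n}{n_1} > 5\cdot 10^4$;
  signed-rank when ties or m > 14).

## Known limitations

* The generator reproduces printed *marginal* and *index-linked* summary
  statistics; the true inter-variable joint distribution is unidentified,
  so statistics that depend on it (e.g. partial correlations) are not
  faithful.
* The piecewise margins have corners at the quartiles and carry no tail
  beyond the printed range.
* The phantom's intensity model is three-level plus speckle; real en-face
  slabs have texture, vignetting and cystic structure the segmentation has
  not been exercised against.
* The index itself is cohort-relative by design; scores from different
  cohorts are not comparable without a shared normalization model.
* Eyes whose hole failed to close were excluded from the source cohort;
  nothing here supports claims about surgical failure.
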