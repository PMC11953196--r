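# piin — Photoreceptor Integrity Index for full-thickness macular holes

`piin` implements a quantitative pipeline for assessing photoreceptor loss
at the edge of full-thickness macular holes (FTMH) from en-face optical
coherence tomography (OCT), for vitreoretinal clinicians and imaging
researchers who want a reproducible, testable implementation of the index
and its surrounding analysis.

On an en-face slab through the hole, surviving photoreceptors form a
hyperreflective rim around the dark lumen. Three areas are measured per
eye:

- **TA** — total hole area, the region enclosed by the hyperreflective
  circumferential line (mm²);
- **LA** — luminal area, the dark central lumen (mm²);
- **PRA = TA − LA** — the photoreceptor-remnant annulus (mm²).

PRA and LA are min-max normalized over the study cohort,

    NORM-X = (X − min X) / (max X − min X),

and the index is

    PIIN = NORM-PRA / (NORM-LA + 1),

bounded in [0, 1]: values near 0 mean poor photoreceptor survival at the
hole edge, values near 1 maximal survival. The `+ 1` keeps the denominator
away from zero at the cohort's luminal minimum. Note the index is
*cohort-relative*: a score only has meaning against the cohort whose
min/max bounds were used.

The package covers:

- **Index core** — area arithmetic, normalization fit/apply (with a clamp
  mode for prospective eyes), the index, hole-size classification by
  minimum diameter (small ≤ 250 µm < medium ≤ 400 µm < large), and
  absolute T0→T1 change variables.
- **En-face segmentation** — an automated stand-in for the manual
  three-step caliper protocol: Gaussian smoothing, Otsu threshold with
  half-maximum refinement, morphological closing, largest connected
  component, hole filling; plus a manual-override path for precomputed
  masks.
- **Synthetic data** — phantom en-face images with analytic ground truth,
  and a Gaussian-copula cohort generator whose margins and correlation
  structure are calibrated to the study's published summary tables, so the
  whole pipeline is testable without any patient data.
- **Cohort statistics** — five-number descriptives, Jarque–Bera normality,
  Spearman correlation with listwise deletion (exact permutation p below
  n = 10), Wilcoxon rank-sum / signed-rank change tests (exact for small
  samples), univariate OLS with adjusted R², and Lin's concordance
  correlation coefficient with Fisher-z confidence intervals.
- **CLI** — `measure`, `score`, `simulate (cohort | phantom |
  imaging-cohort)`, `stats`, `run-all` via the installed `exec/piin`
  script or `piin_cli()`.

## Worked example

```r
library(piin)

## a synthetic 38-eye cohort calibrated to the published summary tables
cohort <- generate_cohort(cohort_spec(n = 38, seed = 1))
scored <- score_cohort(cohort)
scored$model
#> Min-max normalization bounds (n = 38 eyes)
#>   PRA: [0.0306, 0.2577] mm^2
#>   LA : [0.0307, 0.4735] mm^2

report <- build_report(scored$cohort)
print(report)
#> == Spearman correlations with the index ==
#>   minimum_diameter_um    rho +0.766  p 2.053e-08 *  (n=38)
#>   ta_mm2                 rho +0.958  p 4.923e-21 *  (n=38)
#>   bcva_t0_logmar         rho +0.045  p 0.7906      (n=38)
#>   abs_delta_bcva_logmar  rho -0.562  p 0.0002418 * (n=38)
#>   elm_t0_um              rho +0.961  p 8.811e-22 * (n=38)
#>   ...
#> == Regression: |delta BCVA| ~ index ==
#>   slope -0.7241  intercept 0.5636  adj.R2 0.3091  p 0.0001725
#> == Intergrader concordance (CCC, 95% CI) ==
#>   la_mm2   0.9967 (0.9946 - 0.9979)  n=38
#>   pra_mm2  0.9721 (0.9471 - 0.9854)  n=38
#>   ta_mm2   0.9940 (0.9890 - 0.9967)  n=38
```

The index correlates strongly with total area and baseline ELM defect and
negatively with the absolute BCVA change, reproducing the published
correlation structure on a synthetic cohort of the study's size.

Measuring a phantom image recovers its analytic ground truth:

```r
ph <- generate_phantom(phantom_spec(lumen_a_mm = 0.20, ring_width_mm = 0.10,
                                    speckle_sigma = 0.1, seed = 1))
ph$truth
#> En-face hole areas (mm^2): TA 0.2827 | LA 0.1257 | PRA 0.1571
measure_eye(ph$image)
#> En-face hole areas (mm^2): TA 0.2828 | LA 0.1264 | PRA 0.1564
```

End-to-end from the shell:

```sh
piin run-all --outdir out --n 38 --seed 1        # simulate -> image -> measure -> score -> stats
piin simulate cohort --n 38 --seed 1 --out cohort.csv
piin measure eye*.png --out measured.csv
```

## Vignette

`vignettes/methods.Rmd` documents the model, the synthetic-data design and
its calibration, the numerical choices, and what the synthetic evaluation
does and does not establish.
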