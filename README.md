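# fibroCMR

Systematic comparison of in-vivo cardiovascular magnetic resonance (CMR)
measurements against high-resolution histological fibrosis quantification in
the left ventricle, built around a chronic-infarct study design: one
short-axis slice per animal, late gadolinium enhancement (LGE) scar
delineation by several threshold families, wall thickening and
feature-tracking-style strain from cine contours, trichrome colour-fraction
histology per angular wedge section, rotational landmark registration
between the CMR and histology frames, and random-intercept mixed models
scored by the Snijders & Bosker explained-variance statistic.

**Who it is for.** Imaging scientists validating scar-quantification or
deformation measures against sectioned histology, and methodologists who
need a fully synthetic, ground-truthed test bed for such pipelines.

## The statistics at the core

Per histology section *j* of animal *i*, log-fibrosis is modelled with a
random animal intercept:

    null:  log f_ij = b0 + u_i + e_ij,          u_i ~ N(0, tau00), e_ij ~ N(0, sigma2)
    full:  log f_ij = b0 + b1 * x_ij + u_i + e_ij

where `x` is a CMR covariate (%TM by FWHM / 2-3-5 SD-from-remote, MSI,
end-systolic wall thickening, circumferential or radial strain), fitted by
maximum likelihood. The explained variance of a covariate is

    R^2 = 100 * (1 - (sigma2_full + tau00_full) / (sigma2_null + tau00_null))

When the intercept-variance estimate hits the zero boundary the two
components are pooled (`pooled = TRUE`, tau00 = 0) rather than reporting a
spurious tiny tau.

Scar thresholds: FWHM takes half the maximal intensity in the scar seed
region (`>=` rule); nSD-from-remote takes the remote mean plus n population
SDs (`>` rule). %TM is area-based per 1-degree wedge: scar pixels over
myocardial pixels.

## Worked example

Run the complete synthetic pipeline at the study scale (15 animals x 8
wedge sections, noiseless high-contrast LGE):

```r
library(fibroCMR)
run <- runPipeline(list(seed = 1, phantom = list(noiseSd = 0)))
run$results[, c("covariate", "sigma2", "tau00", "pooled", "r2_display")]
#>      covariate sigma2  tau00 pooled r2_display
#> 1       (null)  1.176 0.0566  FALSE          0
#> 2  tm_fwhm_pct  0.365 0.1498  FALSE         58
#> ...
#> 10    es_wt_mm  0.290 0.2667  FALSE         55
#> 11     ecc_pct  0.588 0.4036  FALSE         20
#> 12     err_pct  0.673 0.1894  FALSE         30
#> 13    ft_wt_mm  0.674 0.1725  FALSE         31
```

Reading: the null model splits the total log-fibrosis variance (1.23 here)
into within-animal (1.176) and between-animal (0.057) parts. Adding the
FWHM transmurality covariate leaves a total of 0.51, i.e. it explains 58%
of the variance in measured fibrosis; LGE-derived measures rank above wall
thickening, which ranks above the feature-tracking-style strain exports —
the expected ordering of the design (single cohorts carry a few points of
sampling noise).

Sections stratified by FWHM transmurality show fibrosis rising with scar
depth:

```r
s <- stratifyByTransmurality(run$table)
s[s$variable == "fibrosis_pct", ]
#>      bin     variable  n median    q1    q3
#> 1      0 fibrosis_pct 75   2.88  1.97  4.55
#> 2   0-25 fibrosis_pct 19   9.88  6.09 19.73
#> 3  25-50 fibrosis_pct 17  24.89 17.38 32.58
#> 4  50-75 fibrosis_pct  7  23.89 21.02 29.30
#> 5 75-100 fibrosis_pct  2  43.38 29.77 56.98
```

Individual stages are exposed as plain functions — `generatePhantomSlice()`,
`simulateCine()`, `fwhmMask()` / `sdRemoteMask()` / `applyManualCorrection()`,
`transmuralityProfile()`, `msiProfile()`, `endSystolicWT()`,
`strainProfiles()`, `classifyPixels()` / `sectionFibrosis()` /
`buildOverview()`, `midlateralAngle()` / `rotateProfile()`,
`averageToSections()`, `fitNullModel()` / `fitFullModel()` /
`r2SnijdersBosker()` / `compareAll()` — and user data enters through
`analyzeSlice()` plus the readers in `R/io.R` (contours as JSON, images as
TIFF/PNG, partitions as JSON, tables as CSV). See the vignette in
`vignettes/` for the model, parameter and design rationale.

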