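---
title: "Comparing CMR scar and function measures against histological fibrosis"
author: "fibroCMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing CMR scar and function measures against histological fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroCMR)
```

## The problem

Late gadolinium enhancement (LGE) CMR is the non-invasive reference for
detecting myocardial fibrosis, but there is no consensus on how to threshold
the enhanced signal into "scar", and functional surrogates (wall thickening,
feature-tracking strain) are only indirectly related to collagen content.
Judging any of these measures requires a spatially resolved histological
reference: whole short-axis heart slices cut into angular wedge sections,
stained with Masson's trichrome, and quantified as a collagen area fraction
per section.

`fibroCMR` implements that comparison as a reusable pipeline:

1. **LGE quantification** — scar delineation by full-width-at-half-maximum
   (FWHM) and n-SD-from-remote thresholds (2/3/5 SD, with optional manual
   correction), exported as fraction of transmurality (%TM) and myocardial
   signal intensity (MSI) in 360 equal angular sectors.
2. **Cine quantification** — end-systolic wall thickening in 60 sectors and
   contour-geometric circumferential/radial strain in 48 sectors, with
   end-diastole as the Lagrangian reference.
3. **Histology quantification** — per-pixel colour classification of
   trichrome sections into connective (blue), cardiomyocyte (red) and
   adipose (pseudo-green) classes; fibrosis percentage per section; a
   360-sector schematic overview.
4. **Registration** — rotation of all CMR sector profiles about the LV
   centre into the histology frame anchored at the mid-lateral landmark (the
   point opposite both RV hinge points), then averaging over the wedge
   spans of the histology sections.
5. **Statistics** — random-intercept linear mixed models on log-fibrosis and
   the Snijders & Bosker explained-variance statistic

   $$R^2 = 100\left(1 -
     \frac{\sigma^2_{\mathrm{full}} + \tau_{00,\mathrm{full}}}
          {\sigma^2_{\mathrm{null}} + \tau_{00,\mathrm{null}}}\right),$$

   where $\sigma^2$ is the within-animal residual variance and $\tau_{00}$
   the between-animal intercept variance.

Because the original porcine data are not deposited anywhere, a synthetic
phantom and cohort generator with known ground truth stands in for them and
makes every stage testable end to end.

## The phantom and what it does (and does not) emulate

`PhantomSpec()` describes one short-axis slice: a circular annular
myocardium (defaults 20/30 mm radii on a 128×128 grid at 1.5 mm, the LGE
acquisition resolution), an anteroseptal scar wedge (90° wide) whose
transmural depth grows from the endocardium outward as in
ischemia-reperfusion infarcts, piecewise-constant fibrosis (scar 50% — near
the observed experimental maximum — over a 3% remote background), LGE signal
linear in local fibrosis with five-fold contrast plus additive Gaussian
noise, and a 30-frame cine in which healthy wall thickens by 4 mm and scar
is akinetic, blended over a 20° border by a cosine ramp.

Deliberate simplifications, and what they imply for test conclusions:

* **Gaussian, not Rician, image noise.** The pipeline uses only relative
  thresholds, for which the distinction is second-order at the simulated
  contrast; the noise model is a single switch point in the generator.
* **Circular contours and piecewise-constant fibrosis.** Real infarcts have
  irregular borders and graded border zones; passing tests therefore
  demonstrate correctness of the sampling, thresholding, registration and
  statistics machinery, not robustness to anatomical irregularity.
* **Feature tracking is emulated geometrically.** Commercial FT tracks
  grey values; here strain is computed from contour geometry (midwall arc
  length and sector-mean thickness), which reproduces the meaning of the
  exported quantities and is exactly testable. On top of this,
  `trackContours()` emulates the characteristic FT error mode — the
  contour is traced once at end-diastole and propagated, accumulating
  spatially smooth tracking error — as angularly correlated radius jitter
  (correlation length 30°) growing linearly away from the reference frame.
  Its magnitude (1.5 mm at end-systole, about three quarters of the 2 mm
  cine pixel) was set so that the emulated FT degradation is of the order
  reported for FT against per-frame segmentation; without it, synthetic
  strain would be exactly as informative as wall thickening, which would
  misrepresent the study design the generator stands in for.
* **Global contraction.** `simulateCine(globalInwardMm =)` adds a
  whole-ring inward drift (wall thickness unchanged), because in real
  hearts circumferential shortening is dominated by global contraction and
  is not a strictly local readout of fibrosis. The pipeline draws it per
  animal from 0.5–2.5 mm.
* **One slice, no through-plane motion, no 3-D heart.**

The synthetic cohort couples these phantoms at the design scale of the
emulated study: 15 animals × 8 wedge sections (the study had 7–8 sections
per slice, 108 analysed sections), animal-varying anatomy (endocardial
radius 18–22 mm, wall 8–12 mm), scar transmurality uniform on 0.2–1, and an
arbitrary in-plane acquisition rotation so that registration is always
exercised. Section fibrosis is the polar mean of the true fibrosis field
modulated multiplicatively by animal-level (τ~00~ = 0.1) and section-level
(σ² = 0.3) lognormal biological noise, rendered into a synthetic trichrome
image, and then *measured back* by the colour classifier — so the response
variable has passed through the same quantification path real data would.

## Numerical and statistical choices

* **Angular convention.** Degrees, counterclockwise about the LV centre;
  sector $k$ of $K$ spans $[k\,360/K, (k+1)\,360/K)$, half-open; after
  registration 0° lies at the mid-lateral landmark. One convention repo-wide
  avoids off-by-one sector errors.
* **Threshold boundary rules.** FWHM uses ≥ (half the seed-region maximum is
  scar); SD-from-remote uses > ("higher than" the mean + nSD). The remote SD
  is the population SD (divisor N); a sample-SD switch exists. These
  boundary behaviours are unit-tested.
* **%TM is area-based.** Scar pixels over myocardial pixels per wedge —
  pixel counting, not per-ray chords. Wedges without myocardial pixels (at
  360 sectors and 1.5 mm pixels some wedges are empty) are flagged missing
  and dropped from section averages.
* **Rotation of profiles, not pixels.** Only section-averaged exports are
  compared, so registration acts on sector profiles. Fractional-sector
  shifts default to a spectral (FFT phase) shift, which is exact for
  band-limited profiles and reduces to exact relabelling at integer shifts;
  circular linear interpolation was considered as the default but attenuates
  any non-constant profile on a round trip, which would violate the
  round-trip exactness the registration stage is tested against. The
  pipeline itself rotates the piecewise-constant %TM exports with the
  linear option, which cannot overshoot the [0, 100] range.
* **Estimation by ML, not REML.** The explained-variance statistic compares
  variance totals across models with different fixed effects; ML totals are
  the conventional choice there. REML is available behind a flag. Fits use
  `lme4`.
* **Boundary pooling.** When the random-intercept variance estimate hits
  the zero boundary (below 10⁻⁸), the joint information matrix is not
  positive definite and a tiny spurious τ would be reported; instead the
  residual and intercept variances are pooled: `pooled = TRUE`, σ² holds
  the ML total about the fixed part, τ~00~ = 0. Degenerate designs with no
  within-animal variation (where the profiled likelihood is numerically
  undefined) are handled by the closed-form balanced one-way ML
  decomposition, which the degenerate-case tests pin down (e.g. two animals
  at ±1 with no within noise give σ² = 0, τ~00~ = 1).
* **Log transform.** Natural log with a configurable additive offset
  (default 0.1 percentage points) so zero-fibrosis sections stay finite;
  the offset is recorded on the table. For parameter-recovery simulations,
  where generated fibrosis is strictly positive, offset 0 is the clean
  choice — the offset otherwise attenuates low-fibrosis variance.
* **Negative R².** A full model worse than the null yields a negative
  value; it is returned with a warning, never clipped — an honest
  diagnostic of an uninformative covariate.
* **Transmurality bins.** `{0}`, (0, 25], (25, 50], (50, 75], (75, 100]:
  zero (no enhancement) is its own group and the printed 25/26-style labels
  are read as half-open intervals on the continuous %TM scale.
* **Display rounding.** R² is reported in full precision with an
  integer-percent display column, matching how such tables are printed.

## Worked example

```{r example, eval = FALSE}
library(fibroCMR)

run <- runPipeline(list(seed = 1, phantom = list(noiseSd = 0)))
run$results[, c("covariate", "sigma2", "tau00", "pooled", "r2_display")]
stratifyByTransmurality(run$table)
```

At the default study scale this takes on the order of ten seconds. The
test suite exercises the same machinery at reduced sizes (4–8 animals for
schema and determinism checks; the expected-ordering check averages five
15-animal cohorts; variance-component recovery uses 100 abstract cohorts of
15 × 8 sections) so that a full run stays inside a few minutes on one CPU.

## Known limitations

* The synthetic phantom cannot validate behaviour on irregular scar
  morphology, microvascular obstruction, partial-volume border zones, or
  misregistration beyond pure rotation — the study's own limitation that
  rotational landmark error mainly affects mixed healthy/infarcted
  sections applies here too.
* The FWHM seed region defaults to the whole myocardium ("auto"); a
  user-supplied seed region reproduces software that seeds from a manual
  scar ROI.
* Absolute explained-variance values on real porcine data are not
  reproducible from synthetic cohorts; only the qualitative ordering of
  methods (LGE transmurality > wall thickening > strain) is a designed
  property of the generator, and it is a property of means over cohorts —
  single 15-animal draws carry a few points of sampling noise.
* Histology colour classification is a fixed hue/saturation partition
  intended for separable trichrome classes; it is not a stain
  deconvolution and has no robustness claim for faded or variant staining.
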