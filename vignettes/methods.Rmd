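---
title: "Methods: unified CT/MR abdominal adipose tissue quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unified CT/MR abdominal adipose tissue quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind each pipeline stage, the parameters that matter, what the
phantom generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The measurement model

A single axial abdominal slice is quantified into four areas, all in cm²:
the *outer* region (the whole body cross-section inside the skin), the
*inner* region (inside the abdominal wall), *SAT* (subcutaneous adipose
tissue: classified fat between the two boundaries) and *VAT* (visceral
adipose tissue: classified fat inside the inner boundary). The same
geometric machinery serves CT and fat-only Dixon MR; only the fat
classification rule and one MR-specific preprocessing step differ.

Fat classification is thresholding, not model fitting:

* **CT** — pixels with −190 ≤ HU ≤ −45, inclusive on both ends. The
  literature uses a family of windows (−190/−30, −190/−50, −140/−30, ...);
  the −190/−45 window is the package default because it balances SAT/VAT
  consistency across modalities, and both bounds are configuration-exposed
  (`adipoquant_config(ct_window = ...)`). Inclusivity at the bounds is a
  convention this package fixes explicitly so boundary pixels are
  reproducible.
* **MR** — pixels at or above a fraction (default 0.5) of the *robust
  maximum* intensity inside the body. "Maximum" is implemented as the
  99.5th percentile rather than the literal maximum so a single hot pixel
  cannot move the threshold; with a fat-only Dixon reconstruction the
  background is near zero, so fraction-of-maximum and fraction-of-range
  coincide. Both the fraction and the percentile are configuration keys.
  The rule is scale-free: multiplying the image by any c > 0 multiplies the
  threshold by c exactly.

## MR bias-field correction

Dixon fat-only images carry a smooth multiplicative B1-related intensity
field; because the MR threshold is defined relative to the image's own
maximum, the field must be removed *before* thresholding (it is the first
pipeline stage for MR). The cited correction methods in the application
literature are not specified at the algorithmic level, so the package makes
a deliberate, documented choice: a homomorphic estimate. Bright
(fat-dominated) pixels — above 25 % of the robust maximum — are selected,
their log-intensities are low-pass filtered by normalised convolution with
a Gaussian of scale `mr_bias_smoothing_mm` (default 60 mm: well above
tissue texture, below the body diameter), and the exponential of the
filtered log is divided out. The estimate is iterated to its own fixed
point (at most 8 passes, stopping when the update falls below 0.05 % on
bright pixels), which makes the operator idempotent to within about 1 %;
the output is rescaled so the mean intensity over the body is unchanged.
Restricting the estimate to fat-dominated pixels matters: filtering the
whole body mixes the large fat/muscle log-contrast into the field estimate
and *adds* variation to the corrected fat signal.

What this is not: an N4-style iterative B-spline fit or multi-coil
sensitivity estimation. For single slices with smooth fields the
homomorphic estimate removes ≥ 50 % of the fat-signal coefficient of
variation at field amplitude 0.3 (the acceptance script measures ~80 %) and
post-correction fat classification agrees with the unbiased image on
≥ 98 % of body pixels.

## Body mask

CT body masks threshold at > −190 HU, MR at the 50 %-of-robust-maximum rule
applied image-wide. Components are labelled with 8-connectivity; components
touching the bottom image border with area under 20 % of the largest are
discarded (scan-table removal); the component containing the image-centre
seed is grown and hole-filled. Two fallbacks guard the seed, which the
source methods leave unspecified: if the centre is background, the largest
component is used; and if the centre component (after hole filling) is less
than half the size of the largest, the largest is used as well. The second
rule is essential on fat-only MR, where the dark organ background means the
centre pixel often lands on a small visceral fat island — without it the
"body" would be that island. Hole filling absorbs bowel gas; on MR, where
muscle and organs fall below the fat threshold, it is the hole-filled
subcutaneous ring that reconstitutes the full body cross-section.

## The two-stage snake

Both wall boundaries are found by a closed parametric active contour
minimising the Kass energy (tension α|v′|², rigidity β|v″|², external image
energy) with a balloon pressure term. The internal energy is handled
semi-implicitly — the cyclic pentadiagonal system `(I + γA)` is inverted
once — and the external and balloon forces explicitly. The solver contains
no randomness.

The two stages differ only in initialisation and edge map:

* **Outer**: initialised at the convex hull of the body mask dilated by
  2 px; attracted to the gradient magnitude of the Gaussian-smoothed
  (σ = 2 px) body mask; balloon −0.3.
* **Inner**: initialised at the outer contour scaled by 0.98 toward its
  centroid; attracted to the gradient of a *fat-likelihood indicator* —
  one where a pixel is classified fat or lies outside the body, zero over
  muscle and organs; balloon −0.5. Shrinking from the skin, the first ridge
  of this map is the inner edge of the subcutaneous fat ring, so the snake
  rests at the fat/muscle transition. In a subject with no subcutaneous
  fat the indicator's ridge sits at the skin itself and the inner contour
  stops just inside the outer one — the degenerate case resolves itself.
  Because muscle pixels are never classified fat, SAT and VAT totals are
  identical for any resting position within the muscle band; the package
  defines the inner region by the fat/muscle interface.

Computing edge maps from masks and indicator images rather than raw
intensities is the mechanism that unifies the modalities: the snake never
sees Hounsfield units or arbitrary MR units, only geometry.

Numerical choices that proved load-bearing:

* **Area-preserving resampling.** Uniform arc-length resampling every
  iteration replaces arcs by chords, shrinking the enclosed area by
  ~r(1 − cos(π/n)) per iteration. Over hundreds of iterations this bias
  drags a force-balanced contour through its edge. The resampled polygon is
  therefore rescaled about its centroid to preserve the enclosed area
  exactly.
* **Crest refinement.** Under balloon pressure the equilibrium sits where
  the edge force balances the pressure — slightly *inside* the edge crest.
  Left there, the outer contour excludes the outermost ring of fat pixel
  centres and biases SAT several percent low. After the balloon phase
  converges, up to `refine_iter` (default 60) iterations run with the
  balloon off, letting the contour relax onto the crest itself.
* **Convergence on the maximum point displacement** (tolerance 0.05 px),
  not the mean: a short arc still sliding into a flank concavity must keep
  the contour iterating even though the average is tiny.
* **Containment guard.** In degenerate cases the converged inner contour
  can graze the outer polygon; points outside it are pulled toward the
  centroid in 1 % steps until containment holds.

Defaults (α = 0.05, β = 0.5, γ = 1, n = 200 points, ≤ 500 iterations,
edge weight 2) were tuned on phantoms and are all exposed through
`snake_params()`; they are choices of this implementation, not reproduced
values. Known limitation: like all parametric balloon snakes, the contour
can leak through the corners of deep, narrow, sharp-cornered concavities
(verified experimentally with a rectangular notch). Smooth flank
indentations of the kind real body outlines show are followed correctly,
and the tests exercise exactly that case.

## SAT/VAT partition and areas

Pixel membership is decided by an even-odd point-in-polygon test of the
pixel centre with a half-open vertex rule, so every pixel gets a definite,
reproducible answer; the test suite checks it against an independent
winding-number oracle. SAT = fat ∧ inside(outer) ∧ ¬inside(inner);
VAT = fat ∧ inside(inner); fat outside the outer contour — skin-surface
partial volume — is discarded rather than counted as SAT, which keeps SAT
bounded by the annulus area. Mask areas are pixel counts × pixel area;
contour areas use the shoelace formula. One pixel is
`row_mm × col_mm / 100` cm², and pixel spacing must always be supplied
explicitly — a silent 1 mm default would corrupt every area.

## Editing

The manual-correction step of clinical workflows is represented
programmatically: exclusion grids (removal-only by construction — SAT + VAT
can never grow) and contour replacement with requantification.
`auto_exclude_spine()` proposes exclusions for the classic false-positive
classes: on CT, small fat components (< 0.3 cm²) whose centroid is enclosed
by bone (> 150 HU) in at least 7 of 8 ray directions within 25 mm — the
spinal-canal and foraminal islets; on MR, where no bone intensity signature
exists, small components in a posterior midline box. The proposal is
advisory and off by default, since in clinical use these were human
judgments; the area guard keeps genuine visceral depots untouched.

## Agreement statistics

`compare_modalities(x, y)` uses the MR-minus-CT sign convention:
bias = mean(y − x). Limits of agreement are bias ± 1.96 × SD of the
differences with the n−1 (sample) SD — the Bland–Altman convention — and
their 95 % confidence half-width uses the standard
`t(0.975, n−1) × SD × sqrt(3/n)` approximation. Normality is assessed per
variable with the Lilliefors-corrected Kolmogorov–Smirnov test (parameters
estimated from the sample; `nortest::lillie.test`), a deliberate choice
where the variant is otherwise unspecified; it needs n ≥ 5 and non-zero
variance, and returns NA otherwise. Degenerate conventions: zero-variance
differences give a t p-value of 1 when the bias is zero and 0 otherwise;
zero-variance inputs make Pearson r undefined (NA with a warning) while the
bias remains defined.

## The phantom generator

`phantom_spec()` renders what the pipeline needs to be tested against, with
exact analytic truth: nested ellipses (body with subcutaneous fat ring,
muscle wall, visceral cavity), elliptical visceral fat blobs, an optional
posterior vertebral ring (bone) with a ~0.2 cm² fat islet in the spinal
canal, optional bowel gas, per-modality Gaussian noise, and for MR a smooth
multiplicative field `1 + A·sin(πu)cos(πv)`. The same specification renders
pixel-identical geometry for CT and MR; truth masks come from the noiseless
labels, and the confounder islet is excluded from VAT truth (it is a false
positive by definition).

Default study conditions: 256 × 256 grid at 1.75 mm pixels (448 mm field of
view), tissue values fat −100 HU / 1000 a.u., muscle +50 / 150, organ
+40 / 120, air −1000 / 0, bone +700 / 30; noise 10 HU (CT) and 3 % of the
fat intensity (MR); cohort bodies spanning outer areas of ~420–980 cm²
(the adult abdominal range), subcutaneous ring 12–40 mm, muscle wall
8–15 mm, 3–6 visceral blobs, MR bias amplitude 0.1–0.3. The noise levels
are deliberately small relative to the tissue contrasts so that a failed
recovery indicates a pipeline bug, not an unlucky noise draw.

What the phantoms do *not* emulate — and hence what passing tests do not
show about clinical data: partial-volume mixing at tissue interfaces,
anatomically realistic mesenteric fat (blobs are smooth ellipses),
intramuscular fat texture, organ heterogeneity, motion and peristalsis, or
slice-position mismatch between the paired images. One consequence is
worth stating plainly: because the rendered tissue intensities separate
cleanly, CT and MR quantifications of the same phantom agree essentially
exactly (Pearson r = 1 to machine precision), which is *stronger* than the
high-but-imperfect agreement achievable on patients. The phantom cohort
exercises the agreement machinery; it cannot reproduce clinical
between-modality variability. The bowel-gas confounder is rendered as a
plain air pocket without a fat-intensity rim: its role here is to exercise
hole filling, and the labelled target for the editing stage is the spine
islet.

## Problem sizes and determinism

The test suite and acceptance script use a 20-phantom recovery suite and a
21-pair agreement cohort at the default 256 × 256 resolution (about half a
second per slice), with smaller 128-pixel phantoms for unit tests; these
sizes give every stage a realistic workload while keeping a full run in the
tens of seconds. All randomness — phantom geometry, noise, Monte-Carlo
statistics checks — flows from explicit integer seeds, and the pipeline
itself is deterministic: identical inputs produce bit-identical masks and
contours.
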