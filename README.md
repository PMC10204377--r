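# adipoquant

Unified quantification of abdominal adipose tissue from CT and fat-only
Dixon MR images.

## The problem

Abdominal fat distribution — subcutaneous adipose tissue (SAT) versus
visceral adipose tissue (VAT) — is a standard imaging biomarker for
cardiometabolic risk. It is usually measured on a single axial slice at a
lumbar disc level, on either CT (where fat occupies a known Hounsfield-unit
range) or fat-only Dixon MR (where fat is the bright component in arbitrary
units). Most tools handle only one modality; `adipoquant` implements one
pipeline that serves both, so CT- and MR-derived measurements can be
compared directly within the same framework.

The pipeline, per slice:

1. **Body mask** — intensity thresholding (CT: > −190 HU; MR: > 50 % of the
   robust maximum after bias-field correction), 8-connected region growing
   from the image centre, scan-table removal, hole filling.
2. **Outer contour** — an active contour (snake) initialised at the convex
   hull of the body mask shrinks under balloon pressure onto the skin
   boundary. The snake minimises the Kass energy
   `E = ∫ α|v′(s)|² + β|v″(s)|² ds + E_image(v)` with a semi-implicit
   update; the image energy is the Gaussian-smoothed gradient magnitude of
   the body mask.
3. **Inner contour** — the outer contour, scaled slightly inward, shrinks
   until it locks onto the inner edge of the subcutaneous fat ring. Its edge
   map is the gradient of a fat-likelihood indicator (classified fat or
   outside-body vs muscle/organ), which is what makes the same snake work on
   both modalities.
4. **Fat classification** — CT: −190 ≤ HU ≤ −45 (inclusive); MR: intensity ≥
   0.5 × the 99.5th percentile inside the body.
5. **SAT/VAT partition** — SAT is classified fat between the contours, VAT
   is classified fat inside the inner contour (pixel-centre point-in-polygon
   membership). Areas are reported in cm².
6. **Editing** — programmatic removal-only correction of false-positive fat
   (spinal canal, neural foramina, intramuscular fat), including an advisory
   automatic spine-exclusion proposal.
7. **Agreement statistics** — Pearson r, Bland–Altman bias and limits of
   agreement (`LOA = bias ± 1.96 × SD` of paired differences), Lilliefors
   KS normality, paired t-test, with scatter and Bland–Altman plots.

A parametric phantom generator renders paired CT/MR slices of the same
ground-truth geometry (elliptical body, subcutaneous fat ring, muscle wall,
visceral fat blobs, spine confounder, noise, MR bias field), so every stage
is verifiable without patient data.

## Worked example

```r
library(adipoquant)

spec <- phantom_spec(seed = 1)             # 256x256, 1.75 mm pixels
ph   <- generate_phantom(spec, "CT")
q    <- quantify_slice(ph$image)
q$result
#> <quant_result> phantom-1 CT  outer 601.9  inner 401.7  SAT 199.7  VAT 31.7 cm^2
ph$truth[c("outer_area_cm2", "sat_area_cm2", "vat_area_cm2")]
#> outer 603.2, SAT 200.3, VAT 31.5 cm^2   (recovered within ~1 %)
```

The outer area is the whole cross-section, the inner area the region inside
the abdominal wall; SAT (199.7 cm²) is the fat between those contours and
VAT (31.7 cm²) the fat inside the cavity, all within about 1 % of the
phantom's exact ground truth.

Cross-modality agreement over a paired cohort:

```r
coh <- generate_cohort(5, seed = 2)
sat_ct <- sapply(coh, function(p) quantify_slice(p$ct)$result$sat_area_cm2)
sat_mr <- sapply(coh, function(p) quantify_slice(p$mr)$result$sat_area_cm2)
compare_modalities(sat_ct, sat_mr)
#> <agreement> n=5  r=1.0000  bias=0.000  LOA [0.000, 0.000]  t p=1
```

On phantoms the two modalities agree essentially exactly (see the vignette
for why this is stronger than what clinical data can show).

### Command line

```sh
exec/adipoquant phantom  --n 21 --seed 7 --out-dir phantoms/
exec/adipoquant quantify --input phantoms/phantom-01_ct.dcm \
    --csv-out ct.csv --overlay-out-dir overlays/
exec/adipoquant compare  --ct ct.csv --mr mr.csv --out-dir report/
```

Overlays are RGB secondary-capture DICOM files: outer contour green, inner
red, SAT magenta, VAT cyan.

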