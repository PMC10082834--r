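---
title: "Quantifying tumor metabolism in small-animal PET: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor metabolism in small-animal PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petquant)
```

petquant quantifies therapy response in preclinical FDG-PET: it converts
reconstructed activity volumes to SUV images, delineates the metabolic tumor
volume without operator-dependent contouring, corrects the partial-volume
effect with recovery coefficients, and classifies longitudinal response from
percentage changes. This vignette explains the models behind each stage, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-phantom validation does and does not
demonstrate.

## The SUV image

The standardized uptake value normalizes the activity concentration by the
injected dose per gram of animal:

$$\mathrm{SUV} = \frac{C\ [\mathrm{Bq/mL}]}{A_{inj}\ [\mathrm{Bq}]}\times w\ [\mathrm{g}]$$

which is dimensionless on the conventional g/mL scale. The conversion is
implemented exactly as written, with decay correction of the injected
activity as an explicit opt-in (`decay_correct = TRUE`,
`F18_HALF_LIFE_MIN = 109.77`): the defining formula carries no decay term,
whether SUVs are decay-corrected is a site convention, and making the flag
explicit keeps the two conventions distinguishable in a run manifest. All
volumes use axis order (z, y, x), 1-based indices, voxel-center coordinates
and millimetre units; NIfTI-1 is the canonical on-disk format (the NIfTI
header stores spacing as 32-bit floats, so only dyadic spacings round-trip
bit-exactly). DICOM series import is not included; series should be
converted to NIfTI upstream.

## Operator-independent MTV segmentation

The user's only input is a coarse bounding box that contains the tumor. The
pipeline then:

1. finds the axial slice with the maximum SUV inside the box (ties broken
   to the lowest (z, y, x), so the result is well defined);
2. grows a 4-connected 2D region on that slice from the in-slice maximum,
   including voxels at or above `rg_fraction` (default 0.40, a standard
   fixed-fraction-of-max choice) of the slice maximum;
3. extrudes the contour by `extrude_slices` (default 2) slices to give a 3D
   surface initial cross-slice support, and evolves the surface to
   convergence.

### The active-surface region criterion

A conventional two-phase (inside-mean / outside-mean) criterion was
evaluated first and rejected on evidence: with a realistic point-spread
function, a lesion of 2 mm equivalent diameter peaks at only about a third
of its true contrast, and thresholding at the two-phase midpoint
over-segments it by several hundred percent. No intensity-only rule can
recover sub-resolution volumes; the criterion must know the scanner's
resolution — exactly as the recovery-coefficient correction downstream
does.

Each iteration of the surface evolution therefore fits an explicit forward
model:

* **Background** is the *median* SUV outside a support band (the current
  surface region dilated by the PSF support). The median ignores the
  lesion's own blur skirt and is insensitive to how much background the
  operator's box happens to include — this is what makes the final mask
  bitwise identical across different boxes.
* **Size and amplitude** come from the cumulative radial mass profile of
  the background-subtracted image around the intensity-weighted centroid.
  Deviations are deliberately not clipped at zero, so zero-mean voxel noise
  cancels from the sums instead of rectifying into spurious mass, and the
  profile is computed on a count-normalized 3×3×3 box mean that damps the
  noise further. All statistics are confined to a cut ball of radius
  R + 2.5σ around the core: background-level estimation error grows with
  integration volume, and confining the fit removes that amplification.
* The measured profile is matched, by least squares over a refined grid of
  candidate radii, against **calibration spheres simulated through the same
  forward model**: voxelized on the same grid at the measured sub-voxel
  offset, blurred with the same discrete Gaussian kernel, box-smoothed the
  same way. This absorbs every discretization effect (degenerate voxel
  shells, center alignment, kernel truncation) that a closed-form blurred
  profile cannot represent.
* The surface then moves to the **calibrated boundary iso-level**: the
  intensity midpoint between including and excluding the fitted sphere's
  own voxelization, scaled by the fitted amplitude and offset by the
  background. The threshold is capped at `peak_cap` (default 0.95) of the
  peak contrast, which guarantees the surface can never evolve to an empty
  set and makes the procedure collapse to exact thresholding on crisp
  uniform objects — the property the thresholding-oracle test pins down.

Convergence is declared when the mask is unchanged for
`ac_converged_window` (default 3) consecutive iterations, when any recent
state recurs (noise can trap the surface in a short limit cycle; detecting
the cycle keeps the result deterministic), or at `ac_max_iter` (default
500, never reached in practice — typical runs converge in 3–6 iterations).
The final mask is the 26-connected component containing the seed maximum,
so a second lesion inside the box is never swallowed.

`psf_sigma_mm` (default 0.8 mm) is a scanner calibration constant of the
same standing as the RC table; it is not estimated from the data. Setting
it to 0 handles resolution-free data. `ac_smoothing` (default 0) adds
27-voxel majority-filter passes per iteration for very noisy data, at the
cost of surface exactness on crisp objects.

## Lesion QC

Recovery coefficients are tabulated for uniform spheres, so the correction
is gated on the lesion resembling one.

**Sphericity.** "Diameter" is operationalized as the extents along the
principal axes of the voxel-coordinate cloud (plus the projection of one
voxel, so a single voxel has extent one edge); principal-axis extents are
rotation-tolerant where axis-aligned boxes are not. The gate is
100·(d_max − d_min)/d_max < 50, read strictly: exactly 50 fails.

**Uniformity.** The underlying notion is qualitative — "one population of
uptake values". The default operationalization counts modes of a kernel
density estimate of the in-mask SUVs, keeps modes of height at least
`min_prominence_frac` (default 0.10) of the tallest, and merges adjacent
modes unless the valley between them drops below half the lower mode. The
merging rule is the load-bearing part: resolution blur smears even a
perfectly uniform sphere into a broad, flat, sometimes U-shaped intensity
continuum whose literal 16-bin histogram shows many bin-level "peaks"
separated by empty bins, while genuinely heterogeneous uptake (a necrotic
core, a two-compartment lesion) produces a deep interior valley between
populations. A literal equal-width-histogram peak counter
(`method = "histogram"`, `n_bins` = 16) is retained for crisp data and for
transparency, but it misclassifies the canonical blurred uniform lesion
and is therefore not the default. The verdict is invariant under affine
SUV rescaling in either method.

## Quantification and partial-volume correction

MTV is voxel count × voxel volume, exactly. The sphere-equivalent diameter
d = (6·MTV/π)^(1/3) indexes the RC table (defaults 0.04/0.19/0.41/0.54/0.70
at 1–5 mm). Between tabulated points the RC is interpolated linearly — the
table's provenance gives no functional form, and linear interpolation is
monotone and exact at the anchors. Above 5 mm no correction is applied
(RC = 1), which makes the lookup deliberately discontinuous at 5 mm: that
is the stated no-correction rule, not an artifact. Below 1 mm the RC is
clamped to the 1 mm value with a warning rather than extrapolated toward
implausibly large corrections. Corrected SUV = measured / RC. TLG =
SUVmean × MTV, using the corrected SUVmean by default when a correction was
applied (`use_corrected_for_tlg`); the uncorrected variant is a flag away.
If QC failed, the correction is skipped, `rc_applied` is 1 and a warning is
raised — the run continues, because an uncorrected measurement is still a
measurement.

## Response assessment

ΔX = 100·(X_post − X_pre)/X_pre for SUV (corrected SUVmean), MTV and TLG.
The classifier is driven by ΔSUV alone: > +25 progressive, < −15 partial
response, otherwise stable. The printed rules are strict inequalities on
all three branches, leaving the boundary values unassigned; they are
assigned to stable disease (the closed-interval convention), and the test
suite pins exactly that behavior.

The cohort comparison implements the decision tree as printed: Shapiro–Wilk
per group, then homogeneity of variance, then Student's t / ANOVA +
Holm–Šidák or Kruskal–Wallis. Two open details are resolved as follows: the
variance test is a Levene-type test on absolute deviations (robust, and the
conventional companion of this tree), and groups too small for Shapiro–Wilk
(< 3 observations) or with zero variance fall to the nonparametric branch
with a warning rather than silently passing assumptions that were never
tested. The Holm–Šidák step-down is implemented directly
(adj₍ᵢ₎ = max
ⱼ≤ᵢ 1 − (1 − p₍ⱼ₎)^(m−j+1)) and checked against a hand
computation.

## The synthetic phantom

The generator emulates the study conditions the pipeline targets: 0.5 mm
isotropic voxels; one or more spherical lesions of known radius and uptake
(default 4 mm radius, true SUV 2 — a typical FDG-avid subcutaneous tumor —
on background 0.1, typical of mouse soft tissue); an isotropic Gaussian PSF
of σ = 0.8 mm, chosen to produce a visible partial-volume loss for lesions
up to about 5 mm diameter, the regime where the RC table matters; optional
Gaussian or scaled-Poisson voxel noise behind an explicit seed. Truth
(crisp masks, voxelized and analytic volumes, true uptake) is recorded
before blur and noise. Blurring uses symmetric boundary padding, which
keeps a constant background exactly constant, so total image mass is
conserved to well under 0.1% for interior lesions — the property that makes
mass-based size estimation legitimate. Paired scans scale uptake by the
prescribed ΔSUV and radius by the cube root of the prescribed ΔMTV, so the
truth hits the prescribed percentages exactly before discretization. The
default grid in the package specification is 128³; tests and the
acceptance script use 64³ with lesions centred well inside — large enough
that every lesion keeps full PSF support, small enough to keep the suite
desk-scale (the full suite runs in about four minutes, the acceptance
script in about one).

What the phantoms do *not* emulate: anatomical background structure,
spatially correlated reconstruction noise, non-Gaussian and spatially
varying scanner PSFs, motion, and non-spherical real tumors. Passing the
phantom suite therefore demonstrates that the algorithms are correct under
their stated model — not that segmentation accuracy on real mice will match
the 2–3% seen here. In particular, the RC defaults are scanner calibration
constants: on phantoms blurred with our σ = 0.8 mm PSF they restore the
SUVmean *toward* truth for every sub-5-mm lesion (the directional property
the tests assert), but exact recovery is neither expected nor claimed,
because the table belongs to a physical scanner, not to our synthetic PSF.

## Numerical choices and degenerate inputs

* Ties in maxima resolve to the lowest (z, y, x) lexicographically;
  segmentation is bitwise deterministic for fixed inputs and config.
* An all-zero box, an empty initial contour, or a surface that evolves to
  empty raise errors naming the condition; a QC failure does not abort.
* Masks round-trip NIfTI bit-exactly (uint8); scalar volumes round-trip
  within double precision.
* The per-10-HPF summary sums the first ten fields by default, averages
  ×10 on request, and extrapolates with a warning below ten fields.
* The extent-score bins close the printed integer categories' real-valued
  gaps with half-integer cuts ([0,5), [5,30.5), [30.5,50.5), [50.5,75.5),
  [75.5,100]); every printed anchor stays in its printed bin and the bins
  partition [0, 100].

## Known limitations

Single-lesion scope (the surface keeps one connected component); no
learning-based or multi-observer segmentation; no model-based PVE
correction (geometric transfer matrix, deconvolution); the DICOM importer
is out of scope; the uniformity check is a one-dimensional intensity
criterion and will not flag spatially structured heterogeneity with a
unimodal histogram.
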