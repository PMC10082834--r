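# petquant

Quantitative analysis of small-animal FDG-PET tumor scans: an
operator-independent pipeline that turns a reconstructed activity volume and
a coarse tumor box into partial-volume-corrected uptake metrics and a
longitudinal response call.

## Who this is for

Preclinical imaging groups following subcutaneous tumor models (for example
glioblastoma xenografts) with serial µPET, who need metabolic tumor volume
(MTV), SUV statistics and total lesion glycolysis (TLG) that do not depend
on which operator drew the region of interest, plus the standard
semi-quantitative pathology scores for the matching histology.

## The model

**SUV image.** Each voxel of activity concentration *C* (Bq/mL) becomes a
standardized uptake value

&nbsp;&nbsp;&nbsp;&nbsp;SUV = C / A<sub>inj</sub> × w

with A<sub>inj</sub> the injected activity (Bq) and *w* the body weight (g),
optionally decay-correcting A<sub>inj</sub> to scan start (¹⁸F half-life
109.77 min).

**Operator-independent MTV.** The user supplies only a coarse bounding box.
The pipeline finds the axial slice holding the maximum SUV in the box, grows
a rough 4-connected 2D contour at 40% of the slice maximum, extrudes it into
an initial 3D surface, and evolves a region-based active surface to a
deterministic fixed point. The surface's inclusion criterion is calibrated
against the scanner's point-spread function: at each iteration the lesion's
radius and amplitude are recovered by fitting the measured cumulative radial
mass profile to forward-simulated blurred spheres, and the surface moves to
the calibrated boundary iso-level. Any box that contains the lesion yields
the identical mask.

**Lesion QC.** A lesion is eligible for partial-volume correction only if it
is near-spherical (relative spread of principal diameters below 50%) and its
uptake is uniform (a single population in the in-lesion SUV distribution).

**Partial-volume correction.** Measured SUVs of small lesions are divided by
a recovery coefficient (RC) tabulated against the sphere-equivalent diameter
d = (6·MTV/π)^(1/3): 0.04, 0.19, 0.41, 0.54, 0.70 at 1–5 mm, linear in
between, and 1 (no correction) above 5 mm.

**Response.** For paired scans, ΔX = 100·(X_post − X_pre)/X_pre for SUV, MTV
and TLG (= SUVmean × MTV); ΔSUV > +25% is progressive disease, ΔSUV < −15%
partial response, anything between (boundaries included) stable disease.

**Cohort statistics.** Shapiro–Wilk normality per group and a Levene-type
variance check route each comparison to Student's t (2 groups) or one-way
ANOVA with Holm–Šidák pairwise adjustment (>2 groups), falling back to
Kruskal–Wallis otherwise.

**Histology scoring.** Intensity score (0–3) × extent score (0–4, binned
from percent immunopositivity: <5, 5–30, 31–50, 51–75, >75) =
immunoreactivity score (0–12); cell counts are reported per 10 high power
fields.

Everything is validated on synthetic phantoms with known ground truth:
spherical lesions on low background, Gaussian PSF blur that creates a real
partial-volume effect, optional noise, and paired scans with prescribed
effect sizes.

## Worked example

```r
library(petquant)

spec <- phantom_spec(
  shape = c(64, 64, 64),
  lesions = list(list(center_mm = c(16, 16, 16), radius_mm = 2, suv = 2)),
  background_suv = 0.1, psf_sigma_mm = 0.8, seed = 1)
ph <- make_phantom(spec)               # image + ground truth (32.125 mm^3)

bb <- bbox3d(c(10, 55), c(10, 55), c(10, 55))
mask <- segment_mtv(ph$image, bb)
#> <lesion_mask> 64 x 64 x 64 voxels (z,y,x), 251 in mask (31.375 mm^3)

qc <- qc_report(ph$image, mask)
#> diameters: 3.50 / 3.50 mm, sphericity 0.0% -> spherical
#> histogram peaks: 1 -> uniform
#> PVE-correction eligible: TRUE

quantify(ph$image, mask, qc)
#> MTV: 31.375 mm^3 (0.03138 mL), d_equiv 3.913 mm
#> SUVmean 1.143 (corrected 2.161), SUVmax 1.798 (corrected 3.401), RC 0.529
#> TLG: 67.81 SUV*mm^3

pair <- make_response_pair(spec, delta_suv_pct = -20)
run_pipeline(pair$pre$image, pair$post$image, bb, bb)$response
#> <response_assessment> dSUV -20.5%, dMTV +2.4%, dTLG -18.6% -> partial_response
```

Reading the numbers: the segmented MTV (31.4 mm³) sits within 3% of the
voxelized truth; the blurred lesion's raw SUVmean (1.14) under-reads the true
uptake of 2 because a 3.9 mm object loses signal to the 0.8 mm PSF, and
dividing by the interpolated RC of 0.53 restores it to 2.16; the prescribed
−20% uptake change is measured at −20.5% and classified partial response.

A thin command-line wrapper over the same functions ships in
`inst/cli/quant.R` (`Rscript inst/cli/quant.R segment --in suv.nii
--bbox 40:90,40:90,40:90 --out mask.nii`, etc.).

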