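---
title: "Dose-mass histogram analysis of breath-hold radiotherapy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-mass histogram analysis of breath-hold radiotherapy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In left-sided breast irradiation, deep-inspiration breath-hold (DIBH) expands
the lung and pulls the heart posterior-inferiorly, away from the tangential
fields. The standard plan-evaluation tool, the cumulative dose-volume
histogram (DVH), ranks plans by the *volume* of an organ receiving at least
each dose level. Between free breathing (FB) and DIBH, however, the lung's
local mass density changes dramatically (cohort means around 0.31 g/cm^3 in
FB versus 0.17 g/cm^3 in DIBH at nearly conserved total mass), so equal
irradiated volumes contain very different amounts of tissue. The dose-mass
histogram (DMH) weights every voxel by its mass (density x voxel volume) and
therefore compares breathing states on the amount of irradiated lung tissue
rather than the amount of irradiated space.

`dosemass` implements this comparison end to end: voxel containers and
format I/O, HU-to-density conversion, DVH/DMH computation with Dmean/Vx/Mx
metrics, a B-spline deformable-registration workflow for quantifying lung
expansion, a paired FB/DIBH phantom generator with known ground truth, and
cohort statistics (paired deltas, Wilcoxon tests, DVH-DMH regression with
zero-crossing thresholds, Spearman correlation tables).

# Conventions

All geometry is axis-aligned LPS: +x patient left, +y posterior, +z
superior; "anterior" displacement is `-y` and "caudal" is `-z`. Deltas are
always DIBH minus FB; relative deltas are normalized to the FB value. The
deformation field maps FB positions to DIBH positions (FB is the fixed
image), so a positive anterior mean indicates expansion towards the chest
wall.

# Dosimetry

For a structure mask aligned to the dose grid (dose is resampled onto the
CT/density grid first, because mass accounting is defined per CT voxel):

* DVH: `cumulative[k]` = (count of masked voxels with dose >= edge_k) x
  voxel volume.
* DMH: the same with each voxel weighted by `density x voxel volume`.
* `Dmean` (volume- and mass-weighted), `Vx` and `Mx` are computed from the
  raw masked voxel samples by exact recount with the ">= x" convention, not
  by interpolating the binned curve. This removes any bin-width dependence
  from the reported metrics; the histograms themselves (default bin width
  0.1 Gy) are for plotting and export. The ">=" convention follows the
  definition "receiving at least a certain dose"; an exclusive ">" would
  differ only on measure-zero ties.

Degenerate inputs are contracts, not surprises: an empty mask and a
zero-mass structure raise an `empty_structure` error, negative densities a
data error, misaligned grids a geometry error.

# HU to density

A piecewise-linear calibration table maps HU to mass density, clamped to the
end densities outside the table range. The shipped default is a four-point
air/water/bone curve ((-1000, 0.00121), (0, 1.0), (1000, 1.6),
(3000, 2.5) g/cm^3); any table can be supplied as CSV. Treatment planning
systems publish HU-to-*electron*-density curves; this package follows the
source analysis in using the calibration directly for mass density, which is
an excellent approximation in the thorax (air, lung, soft tissue) and keeps
the table invertible — the phantom generator inverts it to derive HU from
construction densities, closing the unit-test loop.

# Lung expansion

The three-step registration workflow mirrors clinical practice for
breath-hold analysis:

1. `split_tissue()` separates each CT into a lung image and a non-lung image
   (fill value -1000 HU, configurable), preventing cross-tissue gradients at
   the lung border from distorting either registration.
2. `register_deformable()` runs a multi-resolution cubic B-spline free-form
   deformation minimizing mean squared intensity error, by default over 6
   stages with control-point spacing halving down to 10 mm and images
   block-averaged to a matching pyramid level at the coarse stages.
   Optimization is L-BFGS-B with the analytic gradient; it is fully
   deterministic. Non-convergence is not an error: per-stage MSE
   diagnostics are attached, and the final MSE is checked against the
   identity-transform MSE.
3. `merge_dvf()` composes the lung field inside the mask with the non-lung
   field outside, cross-faded linearly over a morphological boundary band
   (default 3 voxels) to avoid a discontinuity at the lung surface.

One numerical choice deserves emphasis. Under mass-conserving expansion the
same lung tissue is systematically *darker* in DIBH (about -830 vs -690 HU
in the phantom world), and a raw squared-error metric then prefers wrong
correspondences for the interior. `register_deformable()` therefore matches
the moving image's foreground intensities (mean/SD, excluding the fill
background) to the fixed image before optimizing. Without this step the
caudal expansion component was recovered at roughly half its true value on
phantoms; with it, all components recover within fractions of a millimetre
to about 1.5 mm.

`expansion_metrics()` averages the field components over the FB-frame
structure (the frame choice is configurable by passing a different mask; the
FB frame is the default because deltas are anchored to FB). The 3-D
expansion is reported as the Euclidean norm of the mean component vector
(`expansion_3d`), with the voxel-wise mean displacement magnitude also
available (`expansion_3d_voxelwise`) since "3-D expansion from the mean
expansions" admits both readings. The breathing-pattern index,
`(caudal - anterior) x 100 / anterior` %, is negative for chest-dominant
breathing; with near-zero anterior expansion it is flagged undefined rather
than thrown.

`warp_mask()` is a pull-back warp (output at x samples the input at
x + u(x)): with the FB-to-DIBH field it deforms a DIBH-frame structure onto
the FB anatomy, which is exactly the operation used to compare the DIBH V20
region with the FB V20 region on one CT.

# The phantom world

The generator emulates the cohort the analysis was designed for, with
defaults stated once and not tuned:

* body: elliptic cylinder, 175 x 135 x 320 mm, soft tissue (1.04 g/cm^3);
* FB left lung: ellipsoid of 1432 cm^3 at 0.31 g/cm^3, with a smooth
  non-periodic sinusoidal density texture (amplitude 25 %, wavelengths
  42-56 mm) that acts as interior structure for the registration, plus
  density noise (SD 0.02 g/cm^3) and CT noise (SD 10 HU);
* DIBH lung: the affine image of the FB lung — center shifted by the mean
  expansions (1.5 mm left, 16.0 mm anterior, 12.2 mm caudal), half-axes
  scaled anisotropically (volume factor 1.8 split as exponents
  0.08/0.55/0.37 over x/y/z, anterior-dominant). Density is material-mapped
  and divided by the volume factor, so lung mass is conserved *by
  construction*; the ground-truth deformation field is this affine map
  inside the lung with a smooth Gaussian falloff outside. Because the map
  is affine and the lung ellipsoid is symmetric, the mean field over the
  lung equals the center shift — the stated expansions — independent of the
  scaling;
* heart: 40 mm sphere, anterior-inferior-medial, displaced 18 mm posterior
  and 12 mm inferior in DIBH;
* dose: a geometric opposed-tangential model — prescription dose
  anterior-left of a field border plane anchored 30 mm posterior to the
  anterior lung surface of each phase (a constant central lung distance,
  as planners keep it), within the PTV's longitudinal window, Gaussian
  penumbra (sigma 5 mm), exponential scatter floor (5 % / 50 mm), zero
  outside the body, renormalized so the median PTV dose is exactly 50 Gy.
  This is a field-shape model, not a transport calculation: the analysis
  consumes dose grids, and algorithm-level accuracy is out of scope;
* PTV: a breast-like ellipsoid on the anterior-left chest. In DIBH it
  follows the chest wall anteriorly (80 % of the anterior expansion), and
  at least far enough that the field border keeps covering it with a
  penumbra margin — without this coupling, independently sampled large
  volume factors let the lung surface overtake the PTV, and the
  median-PTV renormalization then inflates the DIBH dose unphysically.

Cohort sampling uses truncated normal distributions matching the emulated
cohort's means and SDs (lung volume 1432 +/- 290 cm^3, density
0.31 +/- 0.05 g/cm^3, volume change 84 +/- 26 %, expansions 1.5 +/- 2.4,
16 +/- 4, 12.2 +/- 4.6 mm, PTV volume 969 +/- 377 cm^3), truncated to
ranges that keep every sampled anatomy inside the body. Parameters are
sampled independently; the real cohort's correlation structure is not
recoverable from summary statistics and is deliberately not invented.

## Adverse anatomies

A configurable fraction of patients (default 4/31) is constructed so that
DIBH *increases* the irradiated lung mass, the phenomenon observed in a
minority of real patients with unfavourable anatomy. A natural first
construction — extra lung volume replacing heart tissue inside the field —
turns out to be mathematically incapable of producing the observed sign
pattern: with near-uniform lung density and conserved mass, M20 in *both*
phases reduces to `rho_FB x V_FB x (relative in-field fraction)`, the same
quantity that drives Dmean(DVH), so an increased M20 would force an
increased Dmean(DVH), contradicting the universal volumetric benefit. The
implemented construction uses density heterogeneity instead: adverse
patients breathe shallowly (volume factor ~1.35) and their anterior
in-field lung band remains poorly aerated in DIBH — its density is raised
by 80 % with the excess mass debited proportionally from the rest of the
lung, so total mass stays conserved. This reproduces higher Dmean(DMH) and
M20 in DIBH while leaving every volumetric delta negative, and is the
physiologically plausible mechanism (dependent atelectasis / regional
compliance differences carried into the field).

## What a green test does and does not establish

The phantom has analytic organs, a single tissue class per organ, no ribs,
vessels or motion artefacts, and a geometric dose model. Green acceptance
tests therefore establish that the *analysis chain* is correct (oracle
equality of the dosimetry, exact mass conservation handling, registration
parameter recovery on known deformations, correct statistics), and that the
qualitative cohort signs follow from the stated anatomy. They do not
validate dose-calculation accuracy, real-tissue registration robustness, or
the clinical magnitudes of the emulated study, which are properties of its
patient data.

# Statistics

* Wilcoxon signed-rank: zero differences dropped, midranks for ties; exact
  null distribution by convolution (valid with ties) up to n = 25, normal
  approximation with tie correction beyond. Two-sided p values, no
  multiple-testing correction (matching the emulated analysis).
* DVH-DMH regression: unweighted OLS of the relative DMH delta on the
  relative DVH delta; the zero crossing `-intercept/slope` estimates the
  volumetric benefit below which no mass benefit is expected. The axis
  choice (DMH on DVH) follows the dashed-line construction of the source
  figures; the reverse regression would give a slightly different
  threshold.
* Spearman correlations: Pearson correlation of midranks with a two-sided
  t-approximation p, stars at p < 0.05 / p < 0.01, constant inputs flagged
  `NA` rather than thrown.
* Cohort relative deltas are reported as the mean of per-patient relative
  deltas (the convention of the emulated cohort table, where the mean
  relative delta does not equal the ratio of means); the delta-of-means is
  also emitted for transparency.

# Design choices that were genuinely open

* **Expansion frame.** Means are taken over the FB-frame structure. The
  alternative (DIBH frame) weights the expanded lung periphery more; both
  are available by choosing the mask.
* **Expansion source in cohort runs.** `run_cohort()` defaults to the
  phantom's analytic ground-truth field for expansion statistics, keeping
  the default 31-patient run inside its time budget; the full registration
  workflow is validated separately against ground truth and can be enabled
  with `expansion_source = "registration"`.
* **Rasterization.** Voxel-center inclusion with the even-odd rule and
  nearest-slice assignment within half a slice spacing. Overlapping
  contours toggle, so holes are representable; disjoint contours union.
* **DICOM.** A minimal explicit-VR little-endian reader ingests CT series
  and RT Dose (grid scaling honored). RT Structure Sets are not parsed —
  the research JSON contour format is the structure interchange; oblique
  orientations, compressed syntaxes and undefined-length elements are
  rejected with clear errors.

# Known limitations

Axis-aligned geometries only; no contour interpolation between slices; the
registration is single-metric MSE without regularization beyond the
B-spline parameterization (sufficient for the phantom world, not tuned for
clinical image quality); the phantom's dose model has no depth dose,
wedges or segments; exact Wilcoxon p values above n = 25 fall back to the
normal approximation.
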