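# dosemass

Dose-volume **and dose-mass** histogram analysis for breath-hold
radiotherapy of the left breast.

## The problem

Deep-inspiration breath-hold (DIBH) expands the lung and displaces the
heart out of the tangential fields, so it is widely used to spare organs at
risk in left-sided breast irradiation. Plans are conventionally compared
with the cumulative dose-volume histogram (DVH) — the structure volume
receiving at least each dose level — but between free breathing (FB) and
DIBH the *density* of lung tissue changes drastically (≈0.31 → ≈0.17 g/cm³
at conserved total mass). Equal irradiated volumes therefore contain very
different amounts of tissue, and the dose-**mass** histogram (DMH), which
weights each voxel by its mass, is the fairer comparison:

    DVH(d) = Σ_{voxels v in S, D(v) ≥ d} ΔV            [cm³]
    DMH(d) = Σ_{voxels v in S, D(v) ≥ d} ρ(v) ΔV       [g]

with scalar metrics Dmean (volume- or mass-weighted mean dose), Vx and Mx
(volume / mass receiving ≥ x Gy, absolute or % of the structure).

`dosemass` implements the full analysis chain for paired FB/DIBH studies:

* **io**: research formats (MetaImage volumes, JSON contours, CSV density
  tables) plus a minimal DICOM adapter (CT series, RT Dose with grid
  scaling); contour rasterization by the voxel-center even-odd rule;
  piecewise-linear HU → mass-density conversion.
* **dosimetry**: DVH/DMH computation and exact-recount Dmean/Vx/Mx metrics.
* **registration**: the 3-step lung-expansion workflow — tissue splitting,
  multi-resolution cubic B-spline registration minimizing mean squared
  error over 6 stages, deformation-field merging — plus directional
  expansion metrics (left / anterior / caudal means, 3-D expansion,
  breathing-pattern index) and structure warping.
* **phantom**: paired FB/DIBH thorax phantoms with analytic ground-truth
  deformation, mass-conserving lung density change, heart displacement and
  a tangential-field dose model normalized to a 50 Gy median PTV dose.
* **cohort statistics**: paired DIBH−FB deltas, Wilcoxon signed-rank tests
  (exact up to n = 25), DVH↔DMH linear regression with the zero-crossing
  benefit threshold, and Spearman correlation tables.

See `vignettes/dose-mass-analysis.Rmd` for the methods account.

## Worked example

```r
library(dosemass)

## one synthetic patient (6 x 6 x 7.5 mm voxels for speed)
pp   <- phantom_params(spacing = c(6, 6, 7.5))
pair <- generate_pair(pp, seed = 1)

lung_fb   <- rasterize(pair$fb$structures,   pair$fb$ct,   name = "left_lung")
lung_dibh <- rasterize(pair$dibh$structures, pair$dibh$ct, name = "left_lung")
den_fb    <- hu_to_density(pair$fb$ct)

dvh <- compute_dvh(pair$fb$dose, lung_fb)
dmh <- compute_dmh(pair$fb$dose, lung_fb, den_fb)
dose_metrics(dvh, dmh, dose_levels = c(20))

## lung expansion via deformable registration (FB fixed, DIBH moving)
fx  <- split_tissue(pair$fb$ct,   lung_fb)$lung
mv  <- split_tissue(pair$dibh$ct, lung_dibh)$lung
dvf <- register_deformable(fx, mv, stages = 6, finest_spacing = 10)
expansion_metrics(dvf, lung_fb)

## a 31-patient cohort with 4 adverse anatomies
res <- run_cohort(run_config(n = 31, seed = 1, phantom = pp,
                             adverse_fraction = 4 / 31))
print(res)
```

The cohort run prints (output of this exact code):

```
lung volume FB 1427 cm^3, DIBH/FB ratio 1.802
lung mass FB 441.2 g, DIBH 440.3 g (relative difference -0.21%)
expansion recovered (left/anterior/caudal/3D): 1.8 / 16.1 / 11.5 / 19.8 mm
expansion ground truth:                        1.5 / 16.0 / 12.2 / 20.2 mm
<cohort_result> n = 31 patients
  metric                            FB      DIBH     delta    delta%        p
  PTV volume [cm3]              955.17    955.66      0.49      0.1%     0.26
  left lung volume [cm3]       1437.05   2513.87   1076.82     75.4%  1.2e-06
  left lung mass [g]            449.29    449.16     -0.13     -0.0%      0.6
  left lung density [g/cm3]       0.31      0.18     -0.13    -41.9%  1.2e-06
  lung Dmean (DVH) [Gy]           8.35      5.87     -2.48    -29.5%  1.2e-06
  lung Dmean (DMH) [Gy]           8.40      6.44     -1.95    -22.8%  0.00029
  lung V20 [%]                   16.04     10.60     -5.43    -33.7%  1.2e-06
  lung V20 [cm3]                226.24    258.74     32.50     14.3%  1.2e-06
  lung M20 [%]                   16.13     11.89     -4.24    -25.6%   0.0012
  lung M20 [g]                   71.00     53.04    -17.96    -25.7%   0.0048
  heart Dmean (DVH) [Gy]          2.48      0.10     -2.39    -96.2%  1.2e-06
  heart V20 [%]                   3.76      0.00     -3.76   -100.0%  1.2e-06
  heart V40 [%]                   1.63      0.00     -1.63   -100.0%    6e-08
  Dmean regression: slope 2.23, R2 0.66, zero-crossing -19.3%
  V20 regression:   slope 2.78, R2 0.75, zero-crossing -24.5%
```

Reading the numbers: lung volume nearly doubles in DIBH while lung **mass**
is unchanged (mass conservation, the premise of the DMH); every volumetric
lung and heart metric improves; the irradiated lung *volume* in cm³
nevertheless **increases** (V20 [cm³] +14%) because the expanded lung
pushes into the fields — exactly why the relative and mass metrics matter.
The four adverse-anatomy patients are the only ones whose irradiated lung
mass increases in DIBH, and the regression zero-crossings estimate the
volumetric benefit below which no mass benefit is expected. Expansion
means recovered by registration agree with the phantom's ground truth to
fractions of a millimetre.

## Command line

```sh
Rscript inst/cli/dosemass phantom         --n 5 --seed 1 --out data/
Rscript inst/cli/dosemass analyze-patient --input data/patient_01 --out out/
Rscript inst/cli/dosemass analyze-cohort  --input data --out results/
Rscript inst/cli/dosemass report          --input results/
```

(after installation the script is at `system.file("cli/dosemass", package = "dosemass")`).
Exit codes: 0 success, 1 partial per-patient failure, 2 fatal.

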