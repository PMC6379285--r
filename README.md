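# sitvolumetry

Three-dimensional lung nodule volumetry by signal-intensity-threshold
(SIT) segmentation, with a digital phantom bench for validating it.

Nodule management decisions rest on volumetry: growth is an increase of at
least 25% between scans, and a volume doubling time (VDT) under 400 days
is the principal malignancy criterion. CT is the reference modality;
ultra-short echo time MRI reaches comparable resolution in the lung and
would be radiation-free — if its volume measurements agree with CT. This
package implements the segmentation rule used to test that question, the
clinical metrics derived from it, and the agreement statistics that
quantify "agree", all exercised end to end on synthetic phantoms whose
nodule volumes are known exactly.

## The method

**Segmentation.** Inside a spherical region of interest containing the
nodule plus an air margin, record the intensity extremes *I*min, *I*max
and keep every voxel with intensity in

&nbsp;&nbsp;&nbsp;&nbsp;[ *C* (*I*max − *I*min) + *I*min , *I*max ]

where *C* ∈ [0, 1] is the only tunable. `calibrate_threshold()` selects
*C* as the argmax of Lin's concordance ρc against reference volumes over a
grid (default {0.20, 0.30, 0.40, 0.50}).

**Metrics.** Voxel-count volume; sphere-equivalent diameter (6V/π)^(1/3);
caliper-style average diameter (mean of the maximal Feret diameter and its
perpendicular extent on the slice of maximal area); percent difference;
growth calls (≥ 25%, inclusive); VDT = Δt·ln2 / ln(V₂/V₁); a minimum-volume
analysis filter (< 50 mm³ excluded).

**Agreement.** Lin's concordance ρc = ρ·C_b with population moments;
reduced major axis regression (slope ±s_y/s_x); percent-based Bland-Altman
analysis (bias, bias ± 1.96 SD limits of agreement, reference-denominator).

**Phantoms.** Hemispherical/spherical nodules of exactly known volume
(supersampled rasterization, ≤ 0.5% volume error), composed with Gaussian
partial-volume blur, 3 mm-correlated background texture, and Rician (MRI)
or Gaussian (CT) noise; 22 nodules spanning 16–561 mm³ by default, 4 of
them below the 50 mm³ filter. Fully deterministic under a seed.

## Worked example

Generate one degraded MRI-like phantom containing a 150 mm³ hemisphere,
then segment and measure it:

```r
library(sitvolumetry)

spec <- phantom_spec(
  grid_shape = c(64, 64, 64), spacing = c(0.98, 0.98, 0.98),
  nodules = list(nodule_spec("demo", center = c(30.87, 30.87, 30.87),
                             volume_true = 150, shape = "hemisphere")),
  nodule_signal = 100, background_mean = 20, background_texture_sd = 5,
  blur_fwhm = 1.2, noise_model = "rician", noise_sd = 6, seed = 42
)
phantom <- compose_phantom(spec)
roi <- spherical_roi(center = c(30.87, 30.87, 30.87),
                     radius = 2 * (3 * 150 / (4 * pi))^(1/3))
run_single_case(phantom$image, roi = roi, c = 0.5, reference_volume = 150)
#> <nodule_measurement> sit_mri (C = 0.50): 140.2 mm^3, eq diam 6.4 mm, avg diam 8.4 mm
#>   vs reference 150.0 mm^3: -7% (raw -6.51%)
```

The measured 140.2 mm³ is the thresholded voxel count times the voxel
volume; the −7% difference against the known truth reflects
partial-volume blur on a ~4 mm-radius nodule (the average diameter, 8.4
mm, is larger than the equivalent diameter because a hemisphere's widest
slice is its flat face).

The full validation study — generate 22 nodules in both arms, filter,
segment at every threshold, calibrate, and run the agreement analysis:

```r
report <- run_phantom_experiment(experiment_config(seed = 1))
print(report)
#> <study_report> 22 nodules manufactured, 4 excluded (< min volume), 18 analyzed
#>   selected C = 0.50
#>   SIT vs truth: bias -2.91%, LoA [-8.86%, 3.04%], rho_c 0.9977
```

On these phantoms the calibration selects C = 0.50 (the volumetrically
neutral level for their intensity distribution — see the methods
vignette, which also explains why heterogeneous physical nodules push the
optimum towards 0.30), with minimal bias and narrow limits of agreement
against truth. `report$concordance_truth` holds the per-threshold sweep;
`plot_concordance()` and `plot_bland_altman()` draw the standard
method-comparison figures.

## Documentation

The methods vignette (`vignettes/sit-volumetry-methods.Rmd`) documents the
model and its assumptions, the degradation defaults and their physical
rationale, numerical conventions (inclusive bounds, tie-breaks, empty-mask
handling), what the synthetic phantoms do and do not emulate, and known
limitations.
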