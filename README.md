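# thgmyelin

Label-free quantification of myelin swellings in third-harmonic generation
(THG) microscopy stacks.

THG microscopy images myelin without staining: lipid interfaces convert
three near-infrared photons into one UV photon, so myelin sheaths appear as
bright tubes while fluid spaces stay dark. Focal sheath detachments —
*myelin swellings* or blisters — show up as near-spherical dark pockets
bounded by a bright myelin wall, and their density per mm³ is an early
readout of white-matter pathology (e.g. in multiple-sclerosis corpus
callosum under rising bath sodium). This package implements the full
quantification chain for such experiments, for image analysts and
microscopists who want it as tested, scriptable R functions rather than an
interactive tool chain:

* **I/O** — 8-bit grayscale BMP frame sequences, multi-page TIFF z-stacks
  with acquisition geometry, per-frame histogram normalization;
* **preprocessing** — sub-pixel drift registration by phase correlation,
  timepoint selection, inversion, radius-2 disk median filter, CLAHE;
* **probability mapping** — sparse-annotation pixel classification
  (25-channel multiscale feature bank + probability random forest) into a
  per-voxel *non-myelin* probability;
* **detection** — hysteresis thresholding (core 0.85, final 0.5),
  26-connected 3D labeling, isosurface-based sphericity
  (π^⅓(6V)^⅔ / A), size and roundness classification, densities per mm³;
* **statistics** — t tests, one-way ANOVA, mixed repeated-measures ANOVA
  with Greenhouse–Geisser correction (fractional degrees of freedom);
* **optics** — the focused-beam THG intensity integral (Gouy-phase
  cancellation and all) and an edge-spread-function FWHM estimator;
* **synthetic data** — a generator of THG-like white-matter volumes
  (packed myelinated axons, planted blisters, PSF blur, depth attenuation,
  shot/read noise, drift) with voxel-level ground truth, so the whole
  chain is testable without access to human tissue acquisitions.

## A worked example

Simulate one MS-load white-matter volume (60 × 60 × 20 µm at 0.4 µm
voxels), run the detection chain, and compare against the planted truth:

```r
library(thgmyelin)

geom <- acquisition_geometry(fov_um = 60, grid_px = 150, z_step_um = 0.4)
sim  <- simulate_scene(preset_ms(), geom, n_z = 50, seed = 7)
sim$truth$count                    # 22 planted swellings
sim$truth$true_density_per_mm3    # 305556 per mm^3

vol  <- preprocess_volume(stack_volume(sim$stack, 1))   # invert, median, CLAHE
feat <- compute_features(vol)
ann  <- sample_sparse_labels(sim$truth$labels[[1]], 2000, seed = 8)
mod  <- train_pixel_classifier(feat, ann, seed = 9)
prob <- predict_probability(mod, feat, geom)
set  <- detect_from_probability(prob, min_diameter_um = 2,
                                max_diameter_um = 8,
                                sphericity_threshold = 0.75)
set
#> <thg_swelling_set> 22/35 objects accepted in 7.2e-05 mm^3 -> 3.056e+05 per mm^3
```

22 of the 35 dark objects pass the size and roundness rules and are counted
as swellings — matching the 22 planted blisters; the 13 rejected objects
are the irregular dark clutter (lumen fragments, extracellular structure)
the roundness rule exists to exclude. Accepted objects are near-spherical
µm-scale pockets:

```r
head(set$objects[set$objects$accepted,
     c("voxel_count", "equivalent_diameter_um", "sphericity")], 3)
#>    voxel_count equivalent_diameter_um sphericity
#> 32         199               2.897420  0.9089659
#> 33         189               2.848051  0.8881709
#> 46         842               4.686311  0.9090186
```

Group statistics work on plain density vectors (here, densities in units
of 1e5 per mm³ for five MS and six control donors):

```r
two_sample_t(c(3.1, 2.4, 4.4, 2.2, 3.9), c(0.7, 0.5, 0.8, 0.6, 0.55, 0.75))
#> pooled t-test: statistic = 6.613 (df = 9), p = 9.784e-05
```

`run_pipeline(pipeline_config(...))` chains everything — simulation or TIFF
input, registration, preprocessing, classification, detection, group
statistics — from one validated (YAML-loadable) configuration and writes
per-object and per-density CSVs plus a reproducibility manifest. A thin
command-line front end lives in `inst/scripts/thg_pipeline.R`.

## Methods

The methods vignette
(`vignettes/thg-swelling-quantification.Rmd`) documents the THG intensity
model, the synthetic scene generator and what it does and does not emulate,
the probability-mapping and detection protocol with its calibration, the
statistics (including the Greenhouse–Geisser construction), numerical
conventions, and known limitations.
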