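# gliascope

Quantification of microglial reactivity from microscopy images.

Microglia shift from a highly ramified surveillance morphology to an ameboid
reactive state, and this shift is accompanied by remodeling of their
microtubule cytoskeleton and of intracellular trafficking. `gliascope`
implements the image-quantification pipelines needed to measure these
phenotypes reproducibly:

- **Stained-section segmentation** (`run_ihc_pipeline()`): Iba1/DAB images are
  converted to 8-bit grayscale, inverted, background-subtracted (rolling ball,
  radius 50 px) and smoothed (Gaussian, sigma 1). Darker-stained somata are
  detected as connected components above `Th1 = I_max − f1·I_SD` with an area
  floor of 300 px, cells are grown by a seeded watershed restricted to pixels
  above `Th2 = I_mean + f2·I_SD`, and labels not larger than 900 px are
  discarded. Structures whose soma lies outside the section stay background.
- **Culture segmentation** (`segment_invitro()`): CellMask-stained cells are
  seeded from regional maxima with dynamics ≥ h (h-maxima), thresholded at
  10× the per-image minimum intensity, with a 200 px area floor; per-well
  averages are normalized to untreated wells (`aggregate_per_well()`).
- **Morphometrics** (`measure_cells()`): area, Crofton (4-direction)
  perimeter, circularity `4πA/P²`, ramification index `1 − circularity`,
  inscribed radius (distance-transform maximum), maximum Feret diameter
  (convex hull of pixel corners), geodesic diameter (longest intra-mask
  shortest path, weights 1/√2), cell density per mm², and hierarchical
  per-animal means (`aggregate_by_group()`).
- **Plus-tip comet tracking** (`track_comets()`): LoG detection at 0.4 µm
  radius with sub-pixel refinement, LAP frame-to-frame linking (max 1.5 µm)
  with gap closing (≤ 0.5 µm, ≤ 4 frames), filtering to ≥ 4 spots and
  confinement ratio ≥ 0.8, and outward/inward classification: a track is
  outward when its last spot is farther from the centrosome than its first
  (`d_n > d_0`).
- **Spatial intensity statistics**: centrosome enrichment ratio over 20×20 px
  ROIs (`centrosome_ratio()`) and the radius containing 80% of the cumulative
  integrated density around the MTOC (`radial_profile()`,
  `radius_at_fraction()`).
- **Synthetic phantoms** (`generate_microglia_phantom()`,
  `generate_comet_movie()`, `generate_radial_intensity_image()`):
  ground-truthed images and movies with the statistical structure the
  analyses assume, used to validate every stage.

Tables are tibbles; result objects support `tidy()`, `glance()` and
`autoplot()`. A thin command-line front end lives at
`inst/cli/gliascope.R`, and `run_pipeline()` drives multi-stage runs from a
YAML config with a provenance manifest.

## Worked example

```r
library(gliascope)

# a ground-truthed DAB-like phantom: 12 ramified cells, noise at 5% of contrast
ph  <- generate_microglia_phantom(phantom_params(rng_seed = 1))
seg <- run_ihc_pipeline(ph$image)
seg
#> <glia_segmentation> 12 cells (Th1 = 102.89, Th2 = 37.33)
glance(seg)
#> # A tibble: 1 × 6
#>   n_cells n_seeds   th1   th2 mean_ramification_index mean_area_px
#> 1      12      12  103.  37.3                   0.911        2197.
```

All 12 phantom cells are recovered; `Th1`/`Th2` are the soma-seed and
watershed thresholds computed from the preprocessed image, and the mean
ramification index near 0.9 reflects the highly branched morphology.
`tidy(seg)` returns the per-cell table (areas in µm², Feret and geodesic
diameters in µm at the 0.46 µm/px calibration).

```r
# comet movie with known speed (0.1 µm/s) and all tracks outward
mv <- generate_comet_movie(comet_movie_params(fraction_outward = 1,
                                              n_frames = 60,
                                              track_lifetime_frames = c(20, 50),
                                              rng_seed = 1))
tk <- track_comets(mv$frames, tracking_params(detection_threshold = 40),
                   pixel_size_um = 0.11,
                   centrosome_xy_um = (mv$params$centrosome_xy - 1) * 0.11)
glance(tk)
#> # A tibble: 1 × 5
#>   n_tracks mean_speed_um_s mean_displacement_um mean_path_length_um fraction_outward
#> 1       18           0.100                 3.35                3.55                1

# dispersion readout: radius at 80% cumulative integrated density
img <- generate_radial_intensity_image(c(128, 128), sigma_px = 10, amplitude = 100)
radius_at_fraction(radial_profile(img, c(128, 128)), 0.8)
#> r80 = 18.06 px   (analytic value for a Gaussian: sigma * sqrt(2 ln 5) = 17.94)
```

The recovered mean speed matches the generated 0.1 µm/s, the direction
fraction is exact, and the measured r80 agrees with the closed-form value to
within pixel quantization.

See `vignettes/gliascope-methods.Rmd` for the models, parameter choices and
validation design.

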