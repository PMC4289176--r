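# neurokym

Quantitative analysis of radially migrating neurons in multi-channel 3D
time-lapse fluorescence microscopy.

Migrating cerebellar granule neurons move with a two-stroke cadence:
organelles (centrosome, Golgi apparatus, primary cilium) translocate into
the actin-rich proximal leading process first, and the nucleus follows.
Characterizing this choreography — and how actomyosin perturbation breaks
it — requires measurements that respect the cell's 3D shape rather than a
2D projection. `neurokym` implements that measurement stack for
experimentalists working with confocal z-stack time series:

* **Seeded 3D segmentation.** The cell mask is the 6-connected component
  of voxels with intensity ≥ a per-cell threshold that contains a soma
  seed; user-supplied *walls* (polylines of zero intensity, extruded
  through z) keep the mask from bleeding into adjacent cells.
* **Adaptive volumetric kymographs.** Masked fluorescence is accumulated
  in cross-sections one x-y pixel apart along the migration axis (soma
  centroid → leading-process tip at frame 0). Each voxel with projected
  coordinate *s* falls in bin ⌊*s*/Δ⌋ (Δ = pixel size); columns hold the
  sum or max per bin, so for the sum statistic every column total equals
  the frame's total masked fluorescence. Soma-boundary, soma-center and
  organelle overlays are computed alongside.
* **Local concentration.** Mean marker intensity in the intersection of
  the mask with a cylinder of radius 1, 2 or 4 μm around a tracked
  object, versus the whole-cell mean as baseline.
* **Compartment fractions.** The share of a channel's masked fluorescence
  in the leading process (*s* > soma max), soma, and trailing process
  (*s* < soma min), per frame.
* **Velocity kinetics.** Mean step speed per track (mean over
  consecutive-frame pairs of |Δx|/Δt), the ≥5-consecutive-frame inclusion
  rule, the >2-cell-body-length migration rule, pre/post drug-addition
  splits with an excluded settling window, and Welch *t*-tests.
* **FRAP fitting.** Single-exponential recovery
  `I(t) = I_post + (I_plateau − I_post)(1 − e^(−kt))` with fixed bleach
  floor; reports *t*₁/₂ = ln 2 / *k* and the mobile fraction
  (I_plateau − I_post)/(I_pre − I_post) as a classed model object with
  `print`/`summary`/`coef`/`predict`/`plot`/`residuals` methods.
* **Synthetic scenes.** `scene_config()`/`render_scene()` generate
  ground-truthed 4D stacks — soma plus tapered leading and trailing
  processes, two-stroke organelle motion, an actin hotspot riding the
  organelle, lab-frame adhesion puncta, optional drug-induced slowdown,
  Poisson/Gaussian noise — so the whole pipeline is testable without
  external data.

## Worked example

```r
library(neurokym)

cfg <- scene_config(n_frames = 6, n_z = 9, n_y = 40, n_x = 140,
                    voxel_z_um = 1, soma_radius_um = 3,
                    process_length_um = 14, nucleus_speed_um_s = 0.01,
                    lead_amplitude_um = 4, cycle_period_s = 480,
                    start_x_um = 10, seed = 11)
scene <- render_scene(cfg)
scene$stack
#> image_stack: 6 frames x 4 channels x 9 z x 40 y x 140 x
#>   voxel 0.25 x 0.25 x 1 um; frame interval 120 s
#>   channels: nucleus, organelle, actin, adhesion

seg <- segment_sequence(scene$stack, "actin", threshold = 50,
                        seed_voxel = c(40, 19, 4))   # 0-based (x, y, z)
seg
#> segmentation: 6 frames, threshold 50, 0 flagged

ax <- migration_axis(scene$truth$axis_origin_um, mask = seg$masks[[1]],
                     voxel_size_um = scene$stack$voxel_size_um)
kymo <- volumetric_kymograph(scene$stack, "actin", seg, ax, "sum")
kymo
#> volumetric kymograph (sum): 109 bins x 6 frames, bin 0.25 um

tracks <- truth_tracks(scene$truth, noise_sd_um = 0.1, seed = 2)
velocity_stats(tracks, cfg$frame_interval_s)
#> velocity: 0.01029 +/- 0.00251 um/sec (SD), n = 2 of 2 tracks

g <- generate_frap_trace(k = log(2) / 4.26, mobile_fraction = 0.9,
                         pre_level = 100, interval_s = 2, duration_s = 90,
                         noise_sd = 2, seed = 3)
fit_recovery(g$trace$time_s, g$trace$intensity, pre_bleach_level = 100)
#> FRAP fit: k = 0.1652 /s, t1/2 = 4.197 s, mobile fraction = 0.902
#>   plateau 91.94, post 18.08, pre 100; R^2 = 0.9855
```

The kymograph track here moves with the cell at 0.01 μm/sec; the velocity
group mean recovers it from two noisy tracks (nucleus and organelle). The
FRAP trace was generated with a 4.26 s half-life and is fit back to
4.20 s from a single noisy realization.

A command-line front end (`exec/neurokym`, installed with the package)
wraps the same functions:

```sh
neurokym simulate scene --config inst/extdata/demo_scene.yaml --out run/
neurokym segment   --config my_analysis.yaml --out run/
neurokym kymograph --config my_analysis.yaml --out run/
```

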