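# iscattrack

Label-free interferometric scattering (iSCAT) microscopy can watch single
unlabelled biomolecules — here, long double-stranded DNA — transiently
binding to a 2D-material surface (hexagonal boron nitride) in solution, at
millisecond time resolution. `iscattrack` implements the full analysis such
movies need, together with a ground-truthed synthetic movie generator, so
that every stage of the pipeline can be validated without access to raw
instrument data.

The package is aimed at single-molecule biophysicists working with
ratiometric wide-field movies: frames where a bound molecule appears as a
faint, signed contrast blob on a bright static scattering background.

## What it computes

**Background normalisation.** A per-pixel running mean or trailing temporal
median over the `w` frames preceding each frame gives the scattering
background `B`; frames become dimensionless ratiometric contrast
`c = (I − B) / B`, near zero on clean background and signed where a molecule
sits (constructive vs destructive interference).

**Detection and localization.** A DNA coil of radius of gyration
Rg = √(L·b/6) (contour length L, Kuhn length b; ≈337 nm for 20 kbp) spans
several PSF widths, so it images as a superposition of interferometric
point-spread contributions with lobes of either sign. Detection thresholds
the matched-filter-smoothed absolute contrast |c|, segments connected
components, splits merged regions at intensity peaks, and localizes each
blob by its absolute-contrast-weighted centre of mass.

**Tracking and kinetics.** Localizations are linked frame-to-frame by a
globally optimal assignment (Jonker–Volgenant) under a displacement gate.
Trajectories (≥2 frames) carry a dwell time `n_frames × frame period`;
single-frame events are a separate class. Dwell statistics include the
arithmetic mean with a percentile-bootstrap 95% CI, a left-truncated
exponential MLE, a discretisation-aware truncated estimator
(`estimate_dwell_mean`), and Mann–Whitney comparisons between surfaces.

**Spatial statistics.** On lane-patterned surfaces: cross-lane binding
histograms with peak detection relative to lane edges, a contrast-bias
control (rank test of |c| across the lane profile), MSD decomposed along and
perpendicular to the lanes, and an axial (doubled-angle) Rayleigh test of
step-direction isotropy.

**Simulator.** Seeded, bit-reproducible movies: Poisson binding arrivals
over a configurable affinity map (uniform, defect square, lane-edge
enhanced), exponential dwells, 2D surface diffusion with absorbing
field-of-view exits, blobs rendered as K sub-scatterers spread over the coil
footprint with amplitudes `A0·cos(φ0 + 4π·n·z/λ)` (sign flips with
nanometric axial displacement), and shot-noise-like pixel noise.

## Worked example

```r
library(iscattrack)

cfg  <- sim_config(n_frames = 600, seed = 1)          # 3.4 µm FOV, 90.5 Hz
surf <- surface_uniform(103, pixel_nm = 33, margin_nm = 500)
sim  <- simulate_movie(cfg, surf)

cs   <- compute_contrast(sim$movie)                    # trailing median, w = 75
locs <- detect_stack(cs, detection_config(estimate_threshold(cs)))
tr   <- link_localizations(locs,
          link_config(default_max_disp_nm(0.05, 90.5, 33)), 90.5)
tr
#> track_set: 19 trajectories (>= 2 frames), 6 single-frame events

score <- score_detections(subset(sim$truth_table, frame > 75), locs,
                          match_radius_nm = 99)
round(c(precision = score$precision, recall = score$recall,
        rmse_nm = score$rmse_nm), 3)
#> precision    recall   rmse_nm
#>     0.990     0.990    48.873

summarize_dwells(tr$summary$dwell_ms, split_threshold_ms = 110, seed = 1)
#> dwell_summary: n = 19, mean 56.4 [41.3, 73.3] ms
#>   split at 110.0 ms: 17 below-or-equal, 2 above
```

The precision/recall are measured against the simulator's ground truth with
a 3-pixel match radius; the RMSE (~50 nm) is dominated by the random
placement of interference lobes within the coil footprint, not by pixel
noise. The dwell summary splits trajectories at 110 ms (10 frames), the
threshold used to separate brief from long-lived binding.

A shell entry point wrapping the same functions ships in `inst/cli/`
(after installation: `system.file("cli", "iscattrack", package =
"iscattrack")`), with subcommands `simulate`, `track` and `analyze`.

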