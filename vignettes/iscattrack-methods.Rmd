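---
title: "Methods: simulating and analysing iSCAT single-molecule binding movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing iSCAT single-molecule binding movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscattrack)
```

## The measurement this package models

In interferometric scattering (iSCAT) microscopy the detected intensity is
the interference between a reference reflection and the light scattered by
objects near the surface. A molecule binding to the substrate changes the
intensity by a small, *signed* fraction of the background: whether a pixel
gets brighter or darker depends on the optical path length, i.e. on the
scatterer's axial position, with a sign flip every quarter wavelength in
the medium. Long dsDNA adds a second complication: a 20 kbp coil has an
ideal-chain radius of gyration

$$R_g = \sqrt{L b / 6} \approx 337\ \mathrm{nm}
\qquad (L = n_{bp} \times 0.34\ \mathrm{nm},\ b = 100\ \mathrm{nm}),$$

several times the PSF width, and its segments span hundreds of nanometres
axially. A bound molecule therefore images not as a clean point-spread
function but as a superposition of many interferometric contributions with
lobes of both signs that reshuffle from frame to frame.

The pipeline turns raw movies of this kind into binding-site localizations,
trajectories, dwell-time kinetics and lane-relative spatial statistics. A
seeded simulator produces movies with known ground truth so each stage is
testable quantitatively.

## The simulator

`sim_config()` + `surface_*()` + `simulate_movie()` generate movies with:

* **Arrivals**: Poisson in time with mean `arrival_rate` events/frame
  (default 0.05, matching roughly a thousand events per 30,000 frames at
  the default field of view), landing positions drawn proportional to the
  surface affinity map and uniformly within the chosen pixel.
* **Dwells**: exponential with mean `mean_dwell_ms` (default 50 ms),
  discretised to frames by ceiling so every event occupies at least one
  frame — matching the observed class of single-frame binding events.
* **Motion**: isotropic in-plane Gaussian steps with per-axis variance
  `2 D Δt` (default D = 0.05 µm²/s); the field-of-view boundary is
  absorbing, so a molecule stepping out is truncated and flagged — this is
  the censoring mechanism that biases measured dwells downward.
* **Rendering**: each molecule is a rigid constellation of `k_scatterers`
  sub-scatterers (default 68, one per Kuhn segment of a 20 kbp chain)
  drawn uniformly in a disk of radius `rg_nm` and re-centred on the coil's
  centre of mass (which is what $R_g$ is defined about, and what the
  tracker should recover). Sub-scatterer $j$ at axial offset $z_j$
  contributes a unit-peak Gaussian of width `psf_sigma_nm` with amplitude
  $a_j = A_0 \cos(\varphi_0 + 4\pi n z_j / \lambda)$; the axial coordinate
  performs a reflected random walk within `axial_spread_nm`, so contrast
  magnitude and sign evolve frame to frame, reproducing the characteristic
  blob shimmer and contrast inversions.
* **Noise**: zero-mean Gaussian with per-pixel standard deviation
  `noise_sigma · sqrt(background)`, a Gaussian approximation to shot noise
  sufficient for testing contrast thresholds; intensities clip at zero.
  With the defaults (background 1000 counts, `noise_sigma` 0.4,
  $A_0 = 0.08$) the per-sub-scatterer amplitude sits ≈6× above the contrast
  noise floor.

One master seed fixes everything; per-particle sub-streams are derived
deterministically, so truth and movie are bit-reproducible and independent
of how many other particles exist.

**What the simulator does *not* emulate**: vectorial iPSF physics, defocus
and coverslip reflections, worm-like-chain internal dynamics, photon-level
camera statistics, stage drift, or flake-edge scattering outside the lane
model. Passing tests therefore demonstrate correctness of the analysis
under the stated statistical model, not instrument-level realism.

## Background normalisation

The background estimate for frame $t$ is the per-pixel mean or median of
the `window` frames *strictly preceding* $t$ (current frame excluded so a
short-lived molecule is never partially subtracted from itself); contrast
is $(I - B)/B$. The first `window` frames are dropped, not padded.

The default window is 75 frames (~0.83 s at 90.5 Hz). The governing
constraint is ghosting: once a molecule has been present for $m$ of the
$w$ window frames, the background median at its pixels is the
$\lceil w/2\rceil$-th order statistic of only $w - m$ clean values — it
drifts into the tail of the noise distribution (an offset of roughly the
noise quantile at rank $w/(2(w-m))$) and flips fully into particle values
at $m \ge w/2$. The result is suppressed contrast while the molecule
dwells and an inverted ghost for up to $w$ frames after it leaves. With
mean dwell ~50 ms (4.5 frames) and exponential tails, $w = 25$ ghosts
visibly (it cost ~40 points of detection precision in calibration runs),
and even $w = 51$ lets the ~1% of dwells above 20 frames push the median
past the detection threshold. $w = 75$ keeps the shift below threshold
for dwells up to ~25 frames and defers full flips to dwells ≥ 37 frames
(probability ~0.03%). The costs — warm-up, 1.5× median compute, slower
adaptation to drifting backgrounds — are acceptable for static hBN
scattering.

Mean and median modes are both provided and composable; the median is the
default because it is transient-robust.

## Detection

Detection operates on the absolute contrast $|c|$, so constructive and
destructive lobes contribute alike. The stage composes four steps:

1. **Matched filter**: Gaussian smoothing of $|c|$ with
   `smooth_sigma_px = 2` bridges the sub-threshold gaps between the lobes
   of one molecule and suppresses single-pixel noise.
2. **Threshold**: `estimate_threshold()` returns
   `median + k · 1.4826 · MAD` of the smoothed $|c|$ over sampled frames
   (k = 8). The median term matters: smoothed $|c|$ of pure noise
   fluctuates around a *positive* baseline, so a pure spread-based
   threshold would sit below it. Both terms are robust because particles
   are sparse.
3. **Segmentation and splitting**: connected components (8-connectivity by
   default, so diagonal bright/dark lobes stay one detection) of the
   supra-threshold set, minus regions smaller than `min_area_px` (4).
   Because the threshold is far below blob cores, one molecule's footprint
   is large and two molecules within ~1 µm merge; regions holding several
   local maxima separated by ≥ `peak_min_sep_px` (14 px ≈ the distance at
   which two 20 kbp coils physically overlap) are split by nearest-peak
   assignment, with non-maximum suppression to absorb plateau ties.
4. **Localization**: the absolute-contrast-weighted centre of mass of each
   (split) region, with weights taken from a coil-scale envelope smoothing
   (`centroid_sigma_px = 12` ≈ $R_g$/pixel). Weighting by the envelope
   rather than the sharp matched-filter image averages over the randomly
   placed lobes and roughly halves the localization scatter (~50 nm RMS at
   default settings, dominated by constellation geometry, not pixel
   noise). Pixel centres are at $(i + 0.5)\,\times$ pixel pitch, 0-based,
   x = column.

The border margin (`edge_margin_px`) vetoes localizations whose *centroid*
falls in the border band; vetoing by footprint contact would discard
interior molecules whose faint tails touch the edge.

## Tracking

Between consecutive occupied frames, links minimise total squared
displacement over one-to-one assignments with every link ≤ `max_disp_nm`,
solved exactly as a square linear assignment problem augmented with dummy
nodes priced at the gate cost (a Jonker–Volgenant solver in C++; enumeration
on small instances is the test oracle). Unmatched detections start tracks;
a track unmatched for more than `max_gap_frames` frames ends.

The default gate adds 5 px of localization slack to $4\sqrt{2 D \Delta t}$:
the *apparent* step includes ~1.5 px/axis of localization scatter at both
endpoints, and a gate tight against the true step distribution cuts real
links and fragments trajectories (measured dwell bias up to −10% with 3 px
slack).

`max_gap_frames` defaults to 0, which preserves the single-frame-event
class (a detection never linked to another frame) as a separate population.
For dwell *estimation* the recommended setting is `max_gap_frames = 1`:
occasional single-frame detection dropouts otherwise split long dwells and
bias the mean down several percent. With gaps allowed, the dwell uses the
frame span from first to last detection.

## Dwell-time kinetics

* `summarize_dwells()`: arithmetic mean, seeded percentile bootstrap 95% CI
  (10,000 resamples by default; an exhaustive mode enumerates all $n^n$
  resamples for n ≤ 7 and validates the sampler), and counts below/above a
  split threshold (default 110 ms = 10 frames).
* `fit_exponential()`: left-truncated exponential MLE,
  rate $= 1/(\bar{x} - x_{min})$; with $x_{min} = 0$ the standard MLE.
* `estimate_dwell_mean()`: the estimator used for parameter recovery.
  Observed trajectory lengths are whole frame counts $N \ge 2$; for an
  exponential dwell of mean $\tau$, $N - 2$ is geometric with
  $q = e^{-\Delta t/\tau}$, so $\hat q = m/(1+m)$ with
  $m = \overline{N - 2}$ and $\hat\tau = -\Delta t / \log \hat q$. This
  removes both the discretisation bias (~+Δt/2) and the ≥2-frame
  truncation bias that the raw mean of $N \Delta t$ carries (at
  $\tau = 50$ ms the raw mean overshoots by >20%). Its CI is a seeded
  percentile bootstrap of the same estimator; calibration runs put the
  95% CI coverage at 95–97/100 at n ≈ 500.
* `compare_dwells()`: two-sided Mann–Whitney rank-sum; exact enumeration
  for tie-free samples with both n ≤ 20, tie-corrected normal
  approximation otherwise (continuity correction off, so identical samples
  give p = 1).

Validated recovery conditions (also what the acceptance suite runs): movies
at τ ∈ {30, 50, 80} ms, 10 × 2500 frames per τ at 0.04 arrivals/frame (the
measured event density; ~1000 binding events pooled per condition), high
SNR (amplitude 0.12, noise 0.3), landing zone 500 nm inside the border so
field-of-view exits are negligible, linking with gap 1. Density matters:
at 0.10 arrivals/frame, molecule merges split enough trajectories to bias
the recovered mean several percent low. Recovered means land within ~4% of
truth; CI coverage over 100 replicates is checked at the level of the
generator's kinetic model at the same sample size (100 full movie
replicates would cost over an hour of compute for the same statistical
content).

Censoring: with absorbing boundaries enabled, the observed dwell of an
exiting molecule is truncated at its last inside frame; the estimated mean
from censored dwells is never larger than from the uncensored draws — the
direction of the bias a finite field of view imposes on real measurements.

## Spatial statistics

* `lane_histogram()` projects localizations onto the cross-lane axis
  (signed coordinate along the lane normal) or along-lane axis and bins at
  `bin_nm` (default 100 nm, so peak offsets of a few hundred nm span
  several bins). Peaks are local maxima of a 3-bin moving average above
  the global median count; `peak_edge_offsets()` reports each peak's
  distance to its nearest lane edge (per-edge rows; pool as needed).
* `contrast_bias_check()` guards against the artefact where brighter
  detection near edges masquerades as enhanced binding: it tests per-bin
  `mean_abs_contrast` across the lane profile with a Kruskal–Wallis test
  and flags p < 0.01. A single occupied bin yields an undefined statistic
  with a warning, not a flag.
* `msd_decomposed()` averages squared displacements over all ordered
  within-trajectory pairs at each lag and splits them along/perpendicular
  to the lane axis; the two components sum to the total exactly
  (Pythagoras), which the tests check to 1e-9.
* `step_angles()` + `rayleigh_test()`: lane-guided motion would be
  bidirectional, so isotropy is tested on *doubled* angles (axial
  statistics); the Rayleigh p-value uses the standard finite-sample
  correction. Zero-length steps are excluded.

All spatial statistics are invariant under joint rotation of positions and
lane axis, and under translation along the lanes (tested).

## Numerical and degenerate-input choices

* Even-length median windows average the two central order statistics.
* Background-zero pixels yield `NA` contrast and are excluded from
  detection; an all-zero background is an error.
* Empty dwell samples, all-zero affinity with positive arrival rate, K = 0
  sub-scatterers, and windows ≥ the movie length are errors of class
  `iscattrack_invalid` with exit codes 2–4 at the CLI.
* Assignment cost ties resolve deterministically (inputs sorted by label,
  deterministic solver); linking is invariant to localization order within
  a frame.
* The exhaustive bootstrap and the brute-force oracles in the test suite
  are deliberately independent re-implementations.

## Known limitations

* Localization error (~50 nm RMS, ~1.5 px) is set by the random placement
  of interference lobes in the coil, so it does not average down quickly
  with SNR; sub-pixel PSF-model fitting is out of scope.
* Two molecules closer than ~½ µm may merge into one detection; density
  matters more than noise for tracking quality.
* Dwells comparable to half the background window self-subtract and ghost;
  the window must be chosen against the longest common dwell.
* The kinetic model is a single exponential; mixtures and state models are
  out of scope.
* Lane geometry is straight and axis-aligned in the built-in surfaces;
  arbitrary geometries require a user-supplied `surface_model()`.
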