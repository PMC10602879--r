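---
title: "terrafoci: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{terrafoci: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terrafoci)
```

`terrafoci` quantifies telomeric repeat-containing RNA (TERRA) foci in 3D
germline image stacks, tests their colocalization with a second channel,
analyzes single-particle trajectories, and performs delta-Ct qPCR
quantification. Every analysis has a synthetic ground-truth generator next
to it, so each stage can be validated end to end. This vignette describes
the models and the reasoning behind the defaults.

## Nucleus segmentation and the equal-volume sphere

`segment_nuclei()` thresholds the DNA channel with Otsu's method, labels
26-connected components, and optionally splits touching nuclei with a
marker-based watershed (`detection$watershed`, default on): deep cores of
the interior distance map become markers, and boundary voxels are assigned
to the nearest marker. Each nucleus is then summarized by its
*equal-volume sphere*: the sphere centred on the intensity centroid whose
volume equals the segmented voxel volume. The sphere radius is the scale
for all radial measurements.

```{r nuclei}
sim <- simulate_nuclei_stack(
  n_nuclei = 2, shape = c(34L, 160L, 160L),
  focus_channels = list(terra = focus_channel_spec(n_range = c(2L, 6L))),
  seed = 7)
nuc <- segment_nuclei(sim$stack, "dna")
nuc$table[, c("nucleus_id", "x_um", "y_um", "z_um", "r_um")]
```

## Focus detection and measurement

`detect_foci()` runs a Laplacian-of-Gaussian (LoG) filter at the expected
focus scale (`detection$sigma_um`, default 0.15 µm) and keeps local maxima
that exceed `k_mad` (default 5) robust standard deviations (MAD) of the
filtered background. Each seed is grown to the region above
`rel_cutoff` (default 50 %) of its peak response.

Integrated density is measured with a fixed spherical *aperture* of radius
`aperture_factor * sigma_um` (default 3 sigma) around the centroid, with the
local background estimated in a surrounding shell and subtracted. The
aperture is the default (`detection$measure = "aperture"`) because the
grown region's raw sum depends on the arbitrary 50 % cutoff and on the
background level, whereas the background-subtracted aperture converges on
the rendered photon mass of a Gaussian spot; `"region"` is available for
comparison.

```{r foci}
res <- quantify_stack(sim$stack, dna_channel = "dna")
head(res$foci[, c("focus_id", "nucleus_id", "x_um", "volume_um3",
                  "integrated_density", "compartment", "rho", "zone")])
res$summary$zone_fractions
```

## Radial zones

A focus at distance `d` from its nucleus centre has normalized radial
position `rho = d / r` (clamped to 1). Three concentric zones split the
*projected* nuclear disc into equal areas, with boundaries at
`sqrt(1/3)` and `sqrt(2/3)`; zone 1 is peripheral, zone 3 central. Under a
uniform distribution in the sphere the zones are expected to hold 45.6 %,
35.2 % and 19.2 % of foci — peripheral enrichment must be judged against
these baselines, not against 33 % each. An `equal_volume` convention
(boundaries `(1/3)^(1/3)`, `(2/3)^(1/3)`; uniform baseline one third per
zone) is available through `run_config(zonation = ...)`.

## Colocalization with a shuffle null

`match_objects()` pairs the two channels one-to-one inside each nucleus by
greedy nearest centre distance. A pair is colocalized when the distance
does not exceed the sum of the two equal-volume object radii (touching or
overlapping spheres). `shuffle_null()` re-places every channel-A focus
uniformly at random inside its nucleus `n_shuffles` times and uses the
add-one estimator `p = (1 + hits) / (n_shuffles + 1)`, so p can never be
zero and the test is valid at finite shuffle counts. A focus is
*telomeric* when its colocalization is significant at `alpha`
(default 0.05). On independent channels the significant fraction stays at
the nominal alpha, which the test suite verifies.

## Single-particle tracking

`link_tracks()` performs greedy nearest-neighbour frame linking under a
displacement gate, without gap closing; fragments shorter than 5 frames
are dropped.

Two MSD conventions are computed:

* `msd_paper()` — the cumulative sum of squared increments of the distance
  from the first position, `MSD(n) = sum_{i=1..n} (d_i - d_{i-1})^2`. It
  is kept verbatim because published diffusion coefficients were derived
  from it (as the raw slope, no 1/4 factor); note it grows linearly even
  for directed motion and does not saturate under confinement.
* `msd_standard()` — the conventional time-averaged
  `MSD(k) = mean_t |p_{t+k} - p_t|^2`, which obeys 2D diffusion theory
  (`4 D k dt + 4 sigma_loc^2`) and backs all quantitative claims.

`estimate_D()` fits a free-intercept line through the first 4 lags; the
intercept absorbs localization noise.

### Plateau detection

Confinement in a region of radius `R` makes the standard MSD saturate at
about `R^2` with relaxation time `R^2 / (alpha^2 D)` (`alpha ≈ 1.841`).
`detect_plateau()` anchors the curve at the origin (`MSD(0) = 0`), takes
the first-lag secant as the initial slope, and declares a plateau when the
mean secant of the later half of the lags falls below
`plateau_level_frac` (default 0.5) of that initial slope. The plateau time
is the first lag whose local 3-point slope drops below
`plateau_slope_frac` (default 0.15) of the initial slope. The level test
on the averaged tail is what makes the detector usable on single-track
MSD curves, whose lag-to-lag noise defeats window-by-window slope rules:
strict versions either miss real plateaus or fire on noise dips.

### Classification

`classify_motility()` labels a track *stationary* when `D` is at or below
`d_stationary` (0.01 µm²/s), otherwise *confined* when a plateau was
detected, otherwise *diffusive*. Inside `analyze_trajectory()` the
stationary gate uses the short-time secant `MSD(lag_1) / (4 lag_1)` rather
than the multi-lag fit: a strongly confined track's multi-lag fit is
depressed by the saturating curve and would leak confined tracks into the
stationary class, while the first lag is unaffected by confinement.
`segment_states()` classifies a rolling 10-frame window and merges
same-class runs to segment switching tracks; change points sit at the
class switches.

```{r spt}
trk <- simulate_trajectory(
  motion_model("confined", D = 0.1, R = 0.5, sigma_loc = 0.02),
  frame_interval = 0.2, n_frames = 150, seed = 2)
analyze_trajectory(trk)
```

## qPCR quantification

`qpcr_analysis()` computes, per sample and target primer,
`dCt = mean(Ct_target) - mean(Ct_housekeeping)` with replicate error
`e = sqrt(sd_t^2 + sd_hk^2)`, relative expression `2^-dCt`, and fold
changes over a reference sample. Two error conventions are provided:
the verbatim published `i = e * 2^-dCt / dCt` (`error_mode = "paper"`,
singular at `dCt = 0`, where the function refuses with an explicit error)
and the first-order propagation `i = ln(2) * e * 2^-dCt`
(`"corrected"`, the default). `primer_efficiency()` converts the
standard-curve slope to `E% = (10^(-1/slope) - 1) * 100`; a slope of
`-3.3219` is perfect doubling.

```{r qpcr}
ct <- simulate_ct_table(
  expression = list(wt = c(telo = 1), mut = c(telo = 4)),
  noise_sd = 0, seed = 1)
qpcr_analysis(ct, reference = "wt")
```

## Determinism

Every generator and every stochastic analysis takes an explicit seed, and
the command-line interface (`terrafoci_main()`; installed script under
`inst/exec/`) reproduces byte-identical CSV/JSON outputs for identical
arguments and seeds.
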