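---
title: "Quantifying the orthogonal/rotated collagen architecture of the corneal stroma from SHG stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the orthogonal/rotated collagen architecture of the corneal stroma from SHG stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shgstroma)
```

## The measurement problem

Second harmonic generation (SHG) microscopy images fibrillar collagen without
labels, so an en-face z-stack through a chick corneal stroma shows, plane by
plane, the texture of whichever collagen lamella the focal plane intersects.
The stroma has a distinctive architecture: sheets of parallel fibers
(lamellae) whose in-plane axis alternates roughly 90 degrees between adjacent
sheets, with a second, much slower rotation superimposed on both alternating
families over part of the depth.  Three numbers summarise a specimen:

* **lamellar orthogonality** — the mean axial angle between the fiber axes of
  adjacent lamellae (ideally 90 degrees);
* **angular displacement** — the total rotation a lamellar family accumulates
  from the epithelial to the endothelial side, once the 0/90 alternation is
  removed;
* **rotated stroma fraction** — the share of total stromal thickness over
  which that rotation occurs.

In cross-sections, the same rotation is visible as depth-localised bright
*bands*: SHG is strong only where fibers lie within the sectioning plane, so
each time the rotating axis sweeps past the section plane a band appears, and
band count increases with total rotation (two bands once the sweep reaches
180 degrees).

No imaging data accompany the published stage values, so this package is
validated end to end by *parameter recovery*: a synthetic-stroma generator
renders stacks whose ground truth is set to the published values, and the
analysis pipeline must recover them.

## Orientation from the 2D power spectrum

All angles in the package are **axial**: a fiber axis at 10 degrees equals one
at 190, comparisons use the minimal angle in \[0, 90\]
(`axial_difference()`), and angles are measured in degrees counterclockwise
from the image row axis.  `angular_power_spectrum()`:

1. removes the plane mean and applies a 2D Hann window (suppressing the
   axis-aligned cross artifact of the periodic-boundary FFT);
2. computes the 2D power spectrum and masks DC and all frequencies outside a
   radial band — by default 1/20 um^-1 to 1/(4 x pixel) um^-1, excluding
   illumination gradients and pixel noise;
3. bins power by spectral angle (1-degree bins), dividing by the per-bin
   frequency-sample count so the square grid's angular anisotropy does not
   masquerade as signal;
4. rotates by 90 degrees, once, so the reported angle is the real-space fiber
   axis (spectral energy lies perpendicular to the fibers), and normalises to
   unit sum.

Two anisotropy indices summarise each spectrum: `AI2` and `AI4`, the
normalised order-2 and order-4 circular moments.  Both are needed because an
orthogonal biaxial plane nulls AI2 exactly while AI4 stays high; the isotropy
decision therefore uses `max(AI2, AI4) < 0.15`.

`detect_axes()` smooths the spectrum with a 5-degree circular moving average,
scans for local maxima with prominence at least 20% of the smoothed range, and
classifies the plane as isotropic, uniaxial, or biaxial (a second peak at
least 0.3 of the first, 90 +/- 15 degrees away).  For uniaxial planes the
reported axis is the order-2 circular mean of the *whole* spectrum rather
than a local peak average: the isotropic noise floor cancels in the vector
sum, which measurably lowers the estimator variance (about 1.5x at 128-px
planes in our tests); the peak scan still decides the class, and biaxial axes
use a local power-weighted mean within 10 degrees of each peak.  Equal peaks
(within 1e-9) break towards the smaller angle.

```{r orientation-demo}
img <- make_fiber_plane(37, texture_params(seed = 1))
detect_axes(angular_power_spectrum(img, pixel_um = 0.44))[c("class", "axis1_deg")]
```

## From the depth profile to the stage metrics

`analyze_stack()` produces one classified row per plane.  `stroma_metrics()`
then:

* **segments lamellae** (`segment_lamellae()`): greedy runs over the
  non-isotropic planes; a new lamella starts when a plane's axis departs more
  than 30 degrees (axially) from the current run's circular median.  Since
  adjacent lamellae sit near 90 degrees apart and the within-lamella estimator
  noise is about 1-2 degrees, the threshold sits far from both failure modes.
  Isotropic planes are excluded from runs but kept in the thickness
  denominator — wound planes are still stroma.  For biaxial planes the axis
  nearer the current run's median continues the run; the orthogonal axis
  belongs to the other family, whose own lamellae carry it.
* **assigns families and unwraps** (`assign_families_and_unwrap()`): lamella 1
  founds family A; each later lamella joins the axially nearer of the two
  running tracks (B is seeded at A + 90) and continues it by the nearest
  180-congruent value.  This separates the orthogonal alternation from the
  slow rotation: after unwrapping, each family's track is a continuous real
  sequence.  Exact ties alternate the previous family.
* **orthogonality** is the mean adjacent-pair axial angle — the quantity
  itself, not its deviation from 90, matching the ~85-88 degree scale of the
  published stage values.
* **angular displacement** is `|last - first|` of each family's unwrapped
  track, averaged over the families with at least two lamellae.  Measuring
  per family and averaging halves the estimator variance; the rotation is
  reported unsigned with the chirality kept as separate metadata.  End-minus-
  start (rather than summing per-pair rotations) is the package's definition;
  it is insensitive to zero-mean estimation noise in the interior lamellae.
* **rotated zone** (`rotated_zone()`): each lamella's within-family step is
  smoothed over 3 lamellae and thresholded at 3 degrees/lamella (above the
  ~2 degree noise floor of the step estimate).  The reported zone starts one
  lamella before the first qualifying step, because a step measured at
  lamella *i* accrued between *i* and its same-family predecessor, i.e.
  across the intervening lamella.  With that convention a drift spanning the
  whole depth scores exactly 100% and the late-stage synthetic recovery is
  centred on its generator truth.

```{r metrics-demo}
gen <- make_stack(preset_schedule("late_wound"), texture_params(seed = 1))
m <- stroma_metrics(analyze_stack(gen$stack))
unlist(m[c("orthogonality_deg", "angular_displacement_deg", "rotated_fraction_pct")])
```

## The synthetic stroma generator

`make_fiber_plane()` renders a lamellar texture as oriented band-pass
filtered Gaussian noise: a radial Gaussian annulus at `1/fiber_wavelength_um`
(relative width 1/4) crossed with a Gaussian angular window about the axis
perpendicular to the fiber axis, plus white noise set by `snr` (a variance
ratio).  Filtered noise was chosen over explicit line drawing because the
analysis consumes only spectra and the dispersion is then continuously
controllable.  Defaults — 3 um fiber wavelength, 8 degrees angular
dispersion, snr 3 — are free parameters of the study conditions: the
published work reports no fiber spacing or image SNR, so values were chosen
once to look like moderately noisy embryonic SHG planes, and validation rests
on parameter recovery, not image realism.  Geometry defaults mirror the
acquisition scale at desk cost: 100 planes of 256 x 256 px, 2 um z-step,
0.44 um/pixel (198 um total thickness), 50 lamellae of 2 planes (4 um) each.
Per-plane seeds derive from the master seed as `seed * 131 + plane_index`
(wound fills add a constant offset), so stacks are reproducible plane-wise.

`drift_schedule()` builds the canonical architecture: two alternating
families separated by a configurable base orthogonality, with a total
within-family rotation distributed uniformly over a contiguous lamella range.
The stored ground truth (family tracks, displacement, orthogonality pairs,
rotated span) is computed from the constructed angles, so it is self-
consistent by construction and recomputable by brute-force unwrapping.
`preset_schedule()` parameterises it with the published stage values:

| preset | displacement (deg) | orthogonality (deg) | rotated fraction (%) |
|---|---|---|---|
| `mid_wound` | 39.41 | 85.13 | 53.48 |
| `late_wound` | 103.16 | 88.13 | 71.798 |
| `E19` | 193.4 | 90 | as late phase |
| `alternating_only` | 0 | 90 | 0 |

The rotated span is realised on the lamellar grid (whole lamellae), so the
recorded truth fraction is the nearest achievable value — 72.7% for the
late-phase preset against the nominal 71.8%, within one lamella.

Wound states (`make_wound_stack()`) replace an axis-aligned lateral box over
a depth range with an isotropic, uniaxial, or biaxial fill — the three
orientation regimes seen in healing wounds (loose irregular network, fibers
bridging the cleft, orthogonal small bundles).  Region-of-interest analysis
(`config$orientation$roi`) recovers them per plane.

What the generator deliberately does **not** emulate: 3D fiber continuity
across planes, keratocytes and other cellular structure, depth-dependent
attenuation, polarisation effects, and corneal curvature.  Passing recovery
tests therefore demonstrate that the estimator chain is unbiased and
well-calibrated under controlled oriented textures — not that segmentation
thresholds are optimal for every real acquisition.

## Cross-section bands

`render_cross_section()` models row intensity as
`b + A |cos(theta(z) - alpha)|^p` with sharpness `p = 4` and noise `A/10`
(visually band-like, countable crossings), where `theta(z)` is the continuous
track of the lamellar family aligned with the cut at the epithelial side —
the orthogonal family stays out of plane and contributes only baseline.
`alignment_crossings()` counts analytically how often `theta(z)` meets the
section axis (mod 180); that count is the expected number of bands.

`depth_intensity_profile()` uses the lateral mean (robust to cellular
clusters), subtracts a rolling lower-quartile baseline over a 50 um window,
and smooths the residual over 5 um.  A lower quartile, rather than a rolling
median, is used deliberately: a median cancels any band occupying more than
half its window and exactly cancels bands touching the image border, where a
rotation that starts aligned with the section always places one.
`count_bands()` keeps peaks whose prominence exceeds 3x the median absolute
deviation of the unsmoothed residual (gain-invariant) and at least 10 um
apart.  One limitation is inherent: a *constant* profile carries no
gain-invariant evidence distinguishing uniformly-aligned (all bright) from
never-aligned (all dark), so a full-depth aligned section reports 0 peaks;
`alignment_crossings()` still reports its single alignment region.  The
inverse inference is deliberately qualitative: two or more bands set
`high_rotation_flag` (rotation likely reaching 180 degrees), never a degree
estimate, because the band-count-to-rotation mapping is many-to-one.

```{r bands-demo}
sched <- drift_schedule(displacement_deg = 190, zone_lamellae = c(4L, 16L))
cs <- render_cross_section(sched, 0, texture_params(seed = 1))
count_bands(depth_intensity_profile(cs))[c("n_bands", "high_rotation_flag")]
```

## Numerical choices and degenerate inputs

* Constant images yield a flagged degenerate (uniform) spectrum and an
  isotropic class; all-isotropic stacks give an empty lamella list with a
  warning; stacks with one plane are accepted by IO but rejected by the
  pipeline ("insufficient depth").
* A biaxial call requires the axial separation within 15 degrees of 90;
  anything else stays uniaxial with the secondary structure ignored.
* The angular dispersion of the texture window is floored at 0.75 degrees so
  a zero-dispersion request still covers discrete frequency-grid angles.
* Calibration always comes from the caller/CLI, never from TIFF tags;
  intensities are arbitrary units (no photometric calibration) and the whole
  analysis is invariant to gain and offset.
* Problem sizes used in the recovery studies — 20 stacks per stage preset,
  100 planes of 256 x 256 px — were chosen as the smallest study at which the
  seed-to-seed spread of the stage metrics is far below the published
  between-specimen spread.

## Known limitations

* Lamella segmentation assumes the ~90 degree alternation; a specimen whose
  adjacent lamellae differ by less than the 30 degree threshold would merge
  into one run (the threshold is exposed in the configuration).
* The rotated-zone rule reacts to rotation *rate* (3 degrees/lamella by
  default); a stage whose per-lamella step sits near that threshold — the
  mid-healing preset's 3.2 degrees/lamella is an example — is detected
  conservatively, fragmenting the zone, although its displacement estimate is
  unaffected.
* Orthogonality is computed between adjacent lamellae; whether published
  values used adjacent or alternating lamellae is not stated, and the
  adjacent-pair definition is this package's choice.
* The band count reads one lamellar family; real sections in which both
  families come into plane at different depths would need the qualitative
  flag interpreted per family.
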