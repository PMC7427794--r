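# shgstroma

Depth-resolved collagen-orientation analysis for second harmonic generation
(SHG) image stacks of the corneal stroma.

## The problem

The chick corneal stroma is built from collagen lamellae whose in-plane fiber
axis alternates ~90° between adjacent sheets, with a slow additional rotation
of both lamellar families progressing from the epithelium towards the
endothelium over part of the depth.  During embryonic wound healing this
orthogonal/rotated architecture is re-established, and its maturity is
summarised by three numbers per specimen:

- **lamellar orthogonality** — mean axial angle θ⊥ between adjacent lamellae,
  `mean_i d(φ_i, φ_{i+1})` with the axial metric
  `d(a,b) = min(|a−b| mod 180, 180 − |a−b| mod 180) ∈ [0°, 90°]`;
- **angular displacement** — total within-family rotation
  `Δφ = |φ̃(z_end) − φ̃(z_start)|` of the unwrapped family track φ̃(z), i.e.
  the rotation left after removing the 0/90 alternation;
- **rotated stroma fraction** — `100 × (rotated-zone depth) / (total stromal
  thickness)`.

The package computes these from grayscale multi-page TIFF z-stacks: per-plane
fiber orientation is read from the angular distribution of the windowed 2D
power spectrum `P(φ)` (spectral energy lies perpendicular to the fibers),
each plane is classified isotropic / uniaxial / biaxial using the circular
moments `AI_k = |Σ P(φ) e^{ikφ}| / Σ P(φ)` (k = 2, 4), the depth profile is
segmented into lamellae, and the two orthogonal family tracks are unwrapped.
Cross-section images are summarised by a depth intensity profile and an SHG
*band count* — bands appear where the rotating lamellar axis lies in the
sectioning plane, and the count increases with total rotation.

Because no imaging data accompany the published stage values, the package
ships a synthetic-stroma generator (oriented band-pass noise textures with
exact ground truth, wound fills, banded cross-sections) so that every stage
of the pipeline is validated by parameter recovery.  Intended users are
microscopists and image analysts quantifying fibrous-tissue organisation.

## Worked example

Simulate a late-healing-stage stroma (published stage values as ground
truth) and analyse it:

```r
library(shgstroma)

gen <- make_stack(preset_schedule("late_wound"), texture_params(seed = 1))
gen$truth$total_displacement_deg
#> [1] 103.16

profile <- analyze_stack(gen$stack)
head(profile[, c("z_um", "class", "axis1_deg")], 3)
#>   z_um    class axis1_deg
#> 1    0 uniaxial 179.68910
#> 2    2 uniaxial 179.34621
#> 3    4 uniaxial  87.50303

m <- stroma_metrics(profile)
round(unlist(m[c("orthogonality_deg", "angular_displacement_deg",
                 "rotated_fraction_pct")]), 2)
#>        orthogonality_deg angular_displacement_deg     rotated_fraction_pct
#>                    87.41                   103.11                    72.73
```

Planes 1-2 read ≈180° ≡ 0° (family A), plane 3 ≈88° (family B): the
alternation is visible immediately.  The recovered displacement (103.1°) and
rotated fraction (72.7%) match the generator truth (103.16°, 72.7% — the
late-stage fraction realised on a 4-µm lamellar grid); orthogonality is 87.4°
against a scheduled 87.4°.  A cross-section of a high-rotation schedule shows the
two-band pattern:

```r
sec <- render_cross_section(preset_schedule("E19"), 0, texture_params(seed = 1))
count_bands(depth_intensity_profile(sec))$n_bands
#> [1] 2
```

A thin CLI with `simulate | analyze | bands | aggregate` subcommands lives at
`inst/cli/shgstroma-cli.R`:

```sh
Rscript inst/cli/shgstroma-cli.R simulate --preset late_wound --seed 7 --out run1
Rscript inst/cli/shgstroma-cli.R analyze --stack run1/stack.tif \
        --z-step 2 --pixel-size 0.44 --out run1 --export-fft
```

`analyze` writes `metrics.json` (all metrics plus the configuration echo and
hash), `planes.csv` (`z_um,class,axis1_deg,axis2_deg,AI2,AI4`) and optionally
`fft_stack.tif`, a log-scaled per-plane FFT power stack for external 3D
rendering.

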