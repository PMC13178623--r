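# comsli

Fiber orientation mapping from computational scattered light imaging
(ComSLI), with polarized light imaging (PLI) fits, cross-stain registration,
collagen masking, and tumor-boundary-relative orientation statistics — built
for studying how peritumoral collagen is arranged around an invasive front
(tangential, TACS-2-like, versus radial, TACS-3-like arrangements).

## The measurement and the method

ComSLI illuminates an unstained tissue section obliquely from many azimuthal
directions φ (here 24 directions, every 15°) and records one camera frame
per direction. Fibrous structures scatter light mainly perpendicular to
their axis, so a fiber oriented at θ produces a pair of antipodal peaks in
the per-pixel azimuthal intensity profile *I*(φ), near θ + 90° and θ + 270°.
The per-pixel analysis is:

1. build the azimuthal profile *I*(φ) and min–max normalize it;
2. find circular local maxima whose topographic prominence reaches a
   threshold (default 0.08 of the normalized range), refining each retained
   peak position to sub-bin resolution with a 3-point parabolic fit;
3. greedily pair peaks lying 180° ± 35° apart (closest to 180° first);
4. one peak → the orientation is the peak position mod 180°; each valid pair
   → the circular midpoint of the pair mod 180°; profiles with 3, 5 or more
   than 6 peaks, or with unpairable peaks, are not evaluated.

Orientations are rendered as hue (red 0°, yellow 30°, green 60°, cyan 90°,
blue 120°, magenta 150°), masked by the average scattering intensity map.

The companion PLI fit recovers, from four frames at polarizer angles
{0°, 45°, 90°, 135°}, the Fourier coefficients of
*I*(ρ) = (I₀/2)[1 + |sin δ| sin(2(ρ − φ))]: retardance |sin δ| from the
modulation amplitude and the fast-axis azimuth φ ∈ [0°, 180°) from the
phase.

For tumor-boundary analysis, the boundary polyline is resampled at constant
arc length, tangents estimated by central differences, and every valid
collagen pixel in a peritumoral band contributes the acute angle
Δ ∈ [0°, 90°] between its fiber orientation and the nearest boundary
tangent. Distributions of Δ (violin/KDE, quartiles, and the fraction with
Δ > 45°) contrast invasion phenotypes: radially aligned collagen — the
arrangement associated with invasion — shows the larger perpendicular
fraction.

A synthetic phantom generator (`make_orientation_field`,
`render_scatter_stack`, `render_pli_stack`, `render_psr_image`) renders
known-truth orientation fields into all measurement modalities, so every
stage of the chain is verifiable without any raw data.

## Worked example

```r
library(comsli)

field <- make_orientation_field("constant", 32, 32, list(theta = 35))
stack <- render_scatter_stack(field, scatter_model(noise_sigma = 0))
omap  <- compute_orientation_map(stack)
omap
#> <orientation_map> 32 x 32; valid: 1024 (100.0%)
unique(round(omap$orientations[, , 1], 2))
#> [1] 34.61

peaks <- detect_prominent_peaks(extract_profile(stack, 16, 16))
round(peaks, 3)
#>   position prominence
#> 1  124.605          1
#> 2  304.605          1
```

The two prominent peaks sit perpendicular to the 35° fiber (near 125° and
305°); their circular midpoint mod 180° recovers the orientation to 0.4° —
well under the 15° angular sampling, thanks to the parabolic peak
refinement.

The full study workflow lives in `analysis/01_simulate_phantoms.R` through
`analysis/05_relative_orientation.R`: simulate phantoms, map orientations,
fit PLI, register stains and mask collagen, then compare tangential
("low WPOI") against radial ("high WPOI") tumor phantoms. Each script
prints what it found and writes tables under `results/`. On the default
seeds the final stage reports a perpendicular fraction of 0.000 for the
tangential phantom versus 1.000 for the radial one (medians 0.6° vs 89.4°),
and recovers a 0.3 radial admixture as 0.297.

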