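---
title: "Methods: scattered-light fiber orientation mapping and boundary-relative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scattered-light fiber orientation mapping and boundary-relative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comsli)
```

## The signal model

Computational scattered light imaging records, per pixel, an azimuthal
intensity profile $I(\varphi)$ sampled at $K$ equally spaced illumination
azimuths covering the full circle (default $K = 24$, 15° steps). A fiber
bundle oriented at $\theta$ (in-plane, mod 180°) scatters obliquely incident
light mainly perpendicular to its axis, so it contributes an antipodal peak
pair near $\theta + 90°$ and $\theta + 270°$; the circular midpoint of the
pair, reduced mod 180°, is the fiber orientation. Two crossing bundles
produce four peaks and two orientations.

The phantom renderer needs a functional form for these peaks; none is
implied by the geometry alone. We use a wrapped Gaussian with unit peak
height,
$$I(\varphi) = b + \sum_{\text{fibers}} a \left[ W(\varphi;\, \theta + 90°,
\sigma) + W(\varphi;\, \theta + 270°, \sigma) \right],$$
because it is smooth, circularly exact (the renderer folds the argument mod
360°, so the 180° symmetry of the profile holds to machine precision), and
has an analytically known argmax, which makes every downstream recovery test
checkable in closed form. Defaults: baseline $b = 0.1$, amplitude $a = 1$,
peak width $\sigma = 20°$, per-exposure noise sd $0.02$ with 4 exposures
averaged per stored frame (applied sd $0.01$). Measured peak widths and
signal-to-noise ratios of real acquisitions are not available to calibrate
against, so these are conventions chosen to resemble the published maps:
peaks wide enough to overlap at 15° sampling but narrow enough that crossing
bundles at 90° separation remain resolvable, and noise an order of magnitude
below the peak amplitude. All are exposed as `scatter_model()` arguments.

## Peak analysis

Profiles are min–max normalized before peak analysis, which makes detection
exactly invariant under positive rescaling of the intensities (exposure
time, gain). Peaks are circular local maxima (strictly above the left
neighbour, at least as high as the right one, so a two-bin plateau counts
once) whose *topographic prominence* — height above the higher of the two
saddles reached while walking away in either direction until meeting a
strictly higher bin, or all the way around — reaches the threshold. The
default threshold of 0.08 of the normalized range follows the convention of
established scattered-light toolboxes; the sources describing the method say
only "prominent". A constant profile has no peaks and marks background.

**Sub-bin refinement.** At 15° sampling, the raw argmax pair limits
orientation accuracy to half a step (7.5°). We refine each retained peak by
the vertex of the parabola through the peak bin and its two circular
neighbours, clamped to half a bin. For wrapped-Gaussian peaks of width
$\sigma = 20°$ this reduces the worst-case single-fiber orientation error
from 7.5° to below 0.5° (the tests sweep $\theta$ over a 5° grid and assert
< 1°). A plain 3-bin intensity-weighted centroid was considered and
rejected: the baseline and the flanking-bin asymmetry bias it by several
degrees (≈ 3.3° for a peak 5° off-grid under the default model), which no
threshold choice repairs. Refinement can be disabled (`refine = FALSE`),
restoring the half-step bound.

**Pairing and validity.** Peaks 180° ± 35° apart are paired greedily —
among all unmatched pairs the one closest to 180° separation is accepted
first, exact ties broken by ascending positions, each peak used once.
Profiles with one peak give the orientation directly (the peak position mod
180°); 2, 4 or 6 fully paired peaks give 1, 2 or 3 pair midpoints; 3, 5 or
more than 6 peaks are not evaluated. Two further cases are undefined in the
method's public descriptions and are decided here: an even peak count with
any unpairable peak is treated as invalid rather than salvaging the pairable
subset (conservative: such profiles are ambiguous), and pixels with several
orientations are displayed in the orientation map by the most prominent
pair, all orientations being kept in the underlying array.

## Polarized light imaging

Four frames at polarizer angles $\{0°, 45°, 90°, 135°\}$ sample the
two-cycle sinusoid $I(\rho) = \tfrac{I_0}{2}\left[1 + |\sin\delta|\,
\sin(2(\rho - \varphi))\right]$ exactly (three parameters, four samples):
$a_0$ is the frame mean, $a = (I_{0°} - I_{90°})/2$,
$b = (I_{45°} - I_{135°})/2$, retardance $= \sqrt{a^2 + b^2}/a_0$, azimuth
$\varphi = \tfrac{1}{2}\,\mathrm{atan2}(-a, b)$ mod 180°. The sign of the
sinusoid is not fixed by the physics description alone; it is pinned by
requiring that rendering a stack and fitting it returns the inputs exactly
(the tests verify identity to $10^{-6}$ over a dense azimuth sweep).
Azimuths are undefined where retardance $< 10^{-3}$ (or $a_0 = 0$): below
that modulation the phase is numerically meaningless at 8–16-bit intensity
quantization.

## Registration and collagen masking

Stains are aligned by a similarity transform (rotation + isotropic scale +
translation, no reflection) estimated from explicit landmark pairs by the
closed-form least-squares (scaled orthogonal Procrustes) solution. The
original workflow aligned layers interactively; landmarks make the step
scriptable and testable, and two distinct points already determine the
transform. Image warping is inverse-mapping bilinear resampling on pixel
centers ((x, y) = (col − 1, row − 1)); nearest-neighbour is available so
warped masks stay binary; polylines are mapped exactly.

Collagen is masked from the picrosirius-red scan by green-channel
thresholding with the band [205, 255]. As printed, selecting that band
would pick the bright background, while collagen (red, hence low green) lies
outside it — so the default polarity selects the band's *complement*
(`select_inside = FALSE`); both polarities are supported since the original
description does not say which side was kept.

## Boundary-relative statistics

The tumor boundary polyline is resampled at constant arc length (default
spacing 2 px in the analysis scripts) and tangents estimated by central
differences over a ±1-vertex window, reported mod 180°; on a circle this is
exact up to discretization (< 1° for spacing ≤ r/20). Each valid,
(optionally) collagen-positive pixel within the peritumoral band takes the
tangent of its nearest resampled vertex (ties to the lower index) and
contributes the acute angle $\Delta = \min(d, 180° - d)$,
$d = |\theta - \tau| \bmod 180°$, to the distribution; pixels with several
orientations contribute one sample per orientation and display the minimum.
The band width is not documented for the published figures; the default is
100 µm when a pixel size is available, else the analysis uses the phantom's
known collagen band (20 px). Distributions are summarized by a Gaussian KDE
with the normal-reference bandwidth $1.06\,\hat\sigma\,n^{-1/5}$ (the
default of MATLAB's `ksdensity`, which produced the original violins),
unbounded by default — a boundary-reflected variant is available — plus
quartiles and the *perpendicular fraction*, the share of samples with
$\Delta > 45°$ (the natural bisector; the original work shows violins
without a summary statistic). The evaluation grid spans [0°, 90°] plus four
bandwidths of tail so the trapezoid integral of the density is 1 within
$10^{-3}$.

## What the phantoms do and do not emulate

The generator reproduces the *geometry* of the measurement: antipodal peak
pairs, crossing regions, flat background, the four-frame polarization
sinusoid, red-on-white collagen imagery, and circular tumors with
tangential, radial, or mixed peritumoral collagen (the mixed fraction drawn
i.i.d. per band pixel from a seeded RNG). It does not simulate physical
light transport (no diffraction or Mie scattering), out-of-plane fiber
inclination, staining chemistry, scanner shading, or the irregular,
pathologist-annotated boundaries of real tumors. Passing recovery tests
therefore demonstrates the correctness of the analysis chain under its own
signal model — peak shape mis-specification, strong background texture, or
boundary annotation variability in real data are outside what these tests
can certify.

## Numerical choices and problem sizes

Angles are degrees everywhere, orientations half-open in [0°, 180°), images
are matrices with row 1 on top, coordinates (x, y) 0-based along
columns/rows, and orientations measured anti-clockwise on the displayed
image. Identical profiles are analysed once and broadcast (a pure
optimization; noiseless piecewise-constant phantoms collapse to a handful of
unique profiles). Float maps are interchanged as 32-bit IEEE TIFF with NaN
for absent values — written by a small built-in writer because the R `tiff`
package reads but does not write float sample formats — with JSON sidecars
carrying angles and pixel size; loads refuse mismatched sidecars.

The test and analysis problem sizes — 64×64 recovery sweeps, 160×160 tumor
phantoms (≈ 6 900 band samples, comfortably above the 5 000 used for the
mixed-fraction check), 1 000-profile oracle comparisons, 720-point PLI
sweeps — were chosen so the whole suite exercises every claim at
desk scale while remaining quick to run end to end.

## Known limitations

Orientation accuracy degrades for crossing bundles separated by much less
than the peak width; no attempt is made to resolve out-of-plane inclination
or more than three orientations per pixel; Otsu masking is meaningless on
phantoms without true background (it then splits the foreground); and the
greedy antipodal pairing, while adequate for up to six peaks, is not a
globally optimal matching (with ≤ 3 pairs the difference never materialized
in testing).
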