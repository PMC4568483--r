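---
title: "Quantifying spheroid contraction as a cytotoxic endpoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid contraction as a cytotoxic endpoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroscreen)
```

## The assay and its readout

Magnetically bioprinted spheroids contract immediately after the printing
magnet is removed: viable cells rearrange and compact the aggregate towards
an equilibrium size. Toxicants slow this compaction in a dose-dependent way,
so the change in a spheroid's projected area over time is a label-free
viability readout that needs no reagent and no microscope — the
nanoparticle-darkened spheroids are imaged plate-wide against a bright
light pad. `spheroscreen` turns a directory of such plate images into
per-compound IC50s and screen-quality statistics.

The pipeline is: locate well regions (calibration-driven geometry), segment
the dark spheroid in each region per frame, convert pixel counts to mm²,
fit the initial-window contraction rate, normalize to vehicle controls, fit
dose–response curves, and gate IC50 reporting on ANOVA significance.

## Coordinate, time and unit conventions

* Pixels are indexed 0-based `(row, col)` with the origin at the top-left;
  well labels are the usual 1-based letter/number pairs (`"A1"`). The
  calibration object pins the grid: A1's center in pixels, the center-to-
  center pitch, the analysis radius per well, and the physical scale in
  mm/pixel. Calibration is always an explicit input: a fixed camera over a
  fixed plate has a fixed grid, and estimating it from image content would
  add a failure mode with no benefit.
* `t = 0` is the first captured frame, taken as the moment of magnet
  removal and compound addition; all times are minutes. Frames are ordered
  by their manifest times, never by filename, and missing frames are
  tolerated everywhere downstream (the rate fit only needs three in-window
  points).
* Areas are reported both as raw pixel counts and as mm²
  (`area_px2 * mm_per_px^2`).

## Segmentation choices

Within each well's analysis disk the background level is estimated as the
median of the outer 20% annulus. This *local* estimate, rather than a
global flat-field correction, is what makes the measurement robust to the
smooth radial vignetting of a light pad: across one 80-pixel region the
illumination gradient is negligible even when it is large across the plate.
Candidate spheroid pixels are those darker than Otsu's threshold computed
on the region's own pixels; the split is accepted only if the background
minus the candidate mean exceeds a contrast floor (default 0.05 intensity
units), which keeps empty or dried-out wells from producing phantom
objects (they are flagged `low_contrast` instead). A radius-1 morphological
opening removes speckle, holes are filled, and the largest 8-connected
component is the spheroid. Ties on component size are broken by darker mean
intensity, then by centroid position, so the output is a deterministic
function of the input.

Circularity is `4πA/P²` with the perimeter estimated from boundary pixels:
weight 1 for pixels with one exposed 4-neighbour side, √2 for staircase
pixels with two or more — a chain-length approximation under which a
rasterized disk of radius ≥ 10 px scores ≥ 0.9. Degenerate regions never
raise errors; they produce area 0 with a QC flag, and the kinetics stage
excludes flagged points (by default `no_object` and `low_contrast`) before
fitting.

## The endpoint

The cytotoxic endpoint is the rate of contraction over the first 150
minutes: the ordinary least-squares slope of area against time on all
points with `time ≤ 150` (inclusive — with 4-minute sampling a frame falls
at exactly 150 min, so inclusivity is declared rather than left to chance),
negated so that contraction is positive. The slope is the exact closed form
`Σ(t−t̄)(A−Ā) / Σ(t−t̄)²`; no smoothing or pre-normalization of the series
is applied, because the endpoint is defined as a plain linear least-squares
fit on raw areas. (A per-series division by `A(0)` would only rescale each
well's rate; since rates are subsequently normalized across wells, the
default fits raw mm²/min.)

Rates are normalized per *solvent group*: wells whose compound is dissolved
in DMSO are divided by the mean rate of DMSO vehicle wells, PBS-dissolved
compounds by PBS vehicles, mirroring how vehicle controls are analyzed
separately per solvent in practice. The vehicle wells of each group then
average exactly 1 by construction. A vehicle mean ≤ 0 (no contraction in
controls) aborts the analysis: the assay itself has failed.

## Dose–response model

Normalized rates are fitted against `x = log10(concentration)` with the
Boltzmann sigmoidal

$$f(x) = A_2 + \frac{A_1 - A_2}{1 + e^{(x - x_0)/dx}},$$

the standard four-parameter form in which `A1` is the uninhibited plateau,
`A2` the fully inhibited plateau, and `IC50 = 10^{x_0}` the transition
midpoint (a `half_response` mode returning the absolute `A1/2` crossing is
available). Vehicle points cannot sit at `log10(0)`; they are anchored one
decade below the lowest tested dose, where a sigmoid of typical width is
flat — this keeps the information the controls carry about `A1` without
measurably biasing `x0`.

Fitting is deterministic multi-start Levenberg–Marquardt (`minpack.lm`):
five `x0` starts across the observed dose range, asymptote starts from the
extreme-dose means, `dx` from a quarter of the span, `dx` bounded below at
10⁻⁶, convergence tolerances of 10⁻¹² on the relative sum-of-squares
decrease; the converged start with the lowest residual sum of squares is
returned. At least four distinct positive concentrations are required, and
flat data are a fit error rather than a spurious estimate.

An IC50 is *reported* only when the compound's one-way ANOVA across its
concentration groups (vehicle included) is significant at `alpha` and the
fit converged; otherwise the compound is labelled `n.s.`. Tukey HSD
(studentized-range p-values via `stats::ptukey`, Tukey–Kramer form for
unequal group sizes) provides the per-dose versus vehicle comparisons, and
the Z′-factor between vehicle and positive-control wells summarises the
screening window. Z′ is computed on normalized rates; being scale- and
shift-invariant, the choice of raw versus normalized rates does not change
it when every well shares one vehicle group, and normalized rates are what
the screen's decisions are made on.

## The synthetic generator

The generator exists so that every stage has an oracle. It emulates the
study conditions: a 96-well plate holding seven compounds — six with
nominal IC50s of 4.7 to 281.8 μM, one flat negative control — at four
half-log doses in triplicate, solvent-matched vehicle wells (six PBS, three
DMSO), three positive-control wells at 625 μM SDS, and one frame every
4 minutes for 10 hours (151 frames of 1200 × 800 px at 0.05 mm/px).

Per-well areas follow a mono-exponential decay
`A(t) = A_inf + (A0 − A_inf) e^{−k(c) t}` with a logistic dose→rate link
`k(c) = k_bot + (k_top − k_bot)/(1 + e^{(\log_{10} c - \log_{10} IC50)/s})`.
This is a modelling convenience, not a mechanistic claim: it is the
simplest form that reproduces the qualitative kinetics (immediate
contraction, dose-dependent slowing, saturation) while admitting an
analytic ground truth for the secant rate and the IC50. Defaults:
`A0 = 2` mm² (initial diameter about one third of the well pitch),
`A_inf = 0.8` mm², `k_top = 0.003`/min, `k_bot = 0`, width `s = 0.25`
decades.

`k_top` deserves a note. The measured endpoint is a *rate over a fixed
window*, which is linear in `k` only for `k·T ≪ 1`. Choosing
`k_top = 0.003`/min puts `k·T = 0.45` at zero dose: untreated spheroids
complete ~83% of their contraction over the 10 h acquisition (so the movie
looks like a finished experiment) while the window-rate endpoint stays
near-linear in `k`, bounding the systematic offset between the fitted
dose–response midpoint and the generator's `IC50` parameter at roughly
0.05–0.1 decades — visible in the recovered IC50s, which run slightly high,
and comfortably inside the 0.15-decade recovery band the end-to-end checks
use. A much faster `k_top` would saturate the endpoint and shift the
apparent midpoint right by more than that.

Rendering: bright background (0.85) with a radial quadratic vignette
(default 15% corner falloff), spheroids as filled disks at intensity 0.25
of radius `sqrt(A/π)/mm_per_px`, per-well center jitter up to 5% of the
pitch (fixed across frames — a printed spheroid sits still), optional
darker well rims, additive Gaussian noise (default sd 0.02, the low-noise
regime of a lit plate), clipped to [0, 1] and written as 8-bit PNG. All
randomness derives from one master seed through fixed substreams (jitter;
one noise seed per frame), so a seed reproduces the dataset byte for byte,
including under dropped-frame schedules.

What the generator does *not* emulate: irregular or fragmenting spheroids
(real high-dose wells can lose circularity), texture inside the spheroid,
optical blur, condensation artifacts, or meniscus shading at well rims
beyond the optional annulus. Passing the synthetic end-to-end checks
therefore demonstrates the correctness of the measurement and inference
chain under the stated imaging model, not robustness to every real-world
artifact; the QC flags and the per-region background estimation are the
designed safety margins for such effects.

## Numerical and testing choices

* The OLS endpoint is validated against a direct-summation oracle to
  10⁻¹² on a thousand random series; the Boltzmann fitter against exact
  synthetic curves (10⁻⁶ relative) and, under noise, against a dense
  grid-search oracle that exploits the model's conditional linearity in
  `(A1, A2)`.
* ANOVA F-statistics are cross-checked against brute-force sums of squares;
  two-group Tukey decisions against the pooled t-test (an exact
  equivalence); the Z′ implementation against hand-computed values and its
  affine invariance.
* The full-scale checks use the study's own sizes — 96 wells × 151 frames
  at 1200 × 800 px — and complete in about a minute for the measurement
  stage; smaller plates (a 2 × 6 mini layout) back the fast unit tests.
* Degenerate inputs are resolved explicitly rather than left to floating
  point: identical ANOVA groups give `F = 0, p = 1`; zero within-group
  variance with distinct means gives `F = ∞, p = 0`; constant area series
  give rate 0 with R² reported as 0; equal control means make Z′ a
  distinct "undefined separation" condition rather than an `Inf`.

## Known limitations

* One spheroid per well is assumed; with multiple objects the largest wins
  and the well is flagged, but debris larger than the spheroid would be
  measured in its place.
* The calibration grid is trusted as given; a mis-specified grid that still
  fits inside the frame will silently measure the wrong regions (the
  `touches_roi_boundary` and `low_contrast` flags are the practical
  tripwires).
* The Boltzmann fit needs four distinct positive doses; sparser designs
  report ANOVA significance only.
* IC50s from windowed rates inherit the mild window-nonlinearity bias
  discussed above whenever the true kinetics are exponential rather than
  linear; on real data this is part of the endpoint's definition rather
  than an error, but comparisons across assays with different windows
  should keep it in mind.
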