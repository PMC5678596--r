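---
title: "Methods: diel rosette phenotyping with dielpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel rosette phenotyping with dielpheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielpheno)
```

## The problem

Arabidopsis rosettes grow around the clock, but a top-view camera sees them
under two very different regimes: RGB (VIS) images while the lights are on,
and near-infrared (NIR) grayscale images in the dark, where colour-based
segmentation is impossible. `dielpheno` extracts a single continuous trait —
projected rosette area (PRA, mm²) — per plant at every frame of a multi-day
time-lapse, and derives relative expansion rates (RER) from it, so that diel
growth dynamics (including the transient PRA dip caused by epinastic leaf
movement at dawn) are observable for every plant on a tray.

The package processes a session in three layers:

1. **Light periods.** Every VIS frame is segmented independently by
   per-channel range thresholding in a chosen colour space (RGB, HSV or CIE
   Lab) or by grayscale Otsu. Thresholding is stateless and cheap, so no
   information is carried between VIS frames.
2. **Dark periods.** NIR frames are segmented by a two-region Chan–Vese
   active contour seeded from the adjacent VIS mask and propagated frame to
   frame — chronologically with an expansion bias, and anti-chronologically
   (seeded from the *following* morning's mask) with a contraction bias; the
   per-plant PRA from the two passes is averaged. Because frames are 20 min
   apart, inter-frame change is small and each converged mask is a good
   initialisation for the next frame.
3. **Traits.** Per-plant PRA series feed two RER estimators: a *daily* RER
   from the first and last VIS frames of each light period, and a *diel* RER
   from consecutive points of a 10-frame sliding-median-smoothed series.

## The Chan–Vese energy and its minimisation

For a grayscale image $I$ normalised to $[0,1]$ and a foreground region
$\Omega$, the package minimises

$$E(\Omega) = \mu\,|\partial\Omega| +
\lambda_{in}\!\!\sum_{p \in \Omega}\!(I_p - c_{in})^2 +
\lambda_{out}\!\!\sum_{p \notin \Omega}\!(I_p - c_{out})^2,$$

where $c_{in}$, $c_{out}$ are the arithmetic mean intensities of the two
regions and $|\partial\Omega|$ counts 4-adjacent pixel pairs with different
labels. Instead of a level-set discretisation, `chan_vese()` uses narrow-band
pixel flips: each iteration recomputes $c_{in}$/$c_{out}$, then visits
boundary-adjacent pixels one checkerboard parity at a time and flips every
pixel whose flip lowers $E$ at the current means. Same-parity pixels are
never 4-adjacent, so simultaneous flips are independent and each half-sweep
can only lower the energy; updating the means afterwards lowers it further.
The energy trace is therefore non-increasing by construction (and asserted
in the tests). The contour moves at most one pixel per half-sweep, which is
exactly the behaviour wanted for frame-to-frame propagation.

Two details are worth noting:

* **Directional bias.** "Expand" multiplies $\lambda_{out}$ by 2 (default),
  making it costly to leave bright plant pixels outside; "contract" is the
  mirror image. The forward night pass expands (plants grow), the reverse
  pass contracts.
* **Fixed points.** With $\mu = 0$ the exact two-region partition of a
  piecewise-constant image is a strict fixed point (asserted exactly in the
  tests). With $\mu > 0$ the minimiser additionally smooths single-pixel
  rasterisation jaggies, so a rasterised disk converges to Dice ≈ 0.998
  rather than exactly 1 — the length penalty trading a few boundary pixels
  for smoothness, as it should.

Defaults: $\mu = 0.2$ (normalised intensities), $\lambda = 1$, bias 2,
tolerance $10^{-4}$ on the changed-pixel fraction, 200 iterations cap. Each
plant evolves independently inside its bounding box dilated by 25% (at least
6 px), which prevents label leakage between neighbouring plants and bounds
the cost per frame.

## Illumination correction

NIR rigs vignet: background intensity falls off radially. The correction
estimates a smooth illumination field and subtracts its deviation from the
global mean. The field estimate has two parts, computed on the
mean-flattened image (`flatten_toward_mean()`, strength 0.5, which halves
the leverage of bright plant pixels): a robust quadratic trend surface
(iteratively reweighted least squares, residuals beyond 2 SD excluded) and a
Gaussian-smoothed residual map (`intensity_map()`, $\sigma$ = width/8) with
one outlier-rejection pass. The correction is rescaled by
$1/(1-\text{strength})$ so the full field is removed.

The split into trend + smoothed residual is deliberate: a convolution
estimator alone underfits the boundary slope of any smooth field (reflective
padding implies a zero gradient at the raster edge), which leaves a corner
residual of a few grey levels and makes the operator visibly non-idempotent.
The quadratic trend captures linear gradients and radial (quadratic)
vignetting exactly, corners included; the blurred residual picks up whatever
non-polynomial shading remains. Measured on generator scenes, re-applying
the correction moves pixels by under 1 grey level, the global mean is
preserved, a uniform image passes through unchanged, and background SD on
flat-plus-gradient scenes drops by ~87%.

## RER estimation

`rer(pra1, pra2, t1, t2)` returns $(\ln \text{PRA}_2 - \ln
\text{PRA}_1)/(t_2 - t_1)$ in day⁻¹ — the log-area slope, positive for
growth, invariant to area units and time origin. Daily RER uses the
endpoints of each light period; multi-day summaries are arithmetic means of
daily values. Diel RER smooths the PRA series with a centred 10-frame
sliding median (~3 h at 20-min sampling) *before* differencing consecutive
points; smoothing first suppresses segmentation spikes before the
noise-amplifying difference step. On uniformly sampled exponential growth
both estimators recover the generating rate exactly (the even-window median
of an exponential is the mid-point value times a constant factor, which
cancels in the log difference) — asserted to $10^{-9}$ in the tests.

Missing observations in gaps of ≤ 2 frames are linearly interpolated for
smoothing only; longer gaps split the series and each segment is processed
separately.

A note on precision: a daily RER computed from two single frames half a day
apart amplifies observation noise by $\sqrt{2}/\Delta t \approx 2.9$
day⁻¹ per unit log-noise. At the sub-percent PRA error this pipeline
delivers on synthetic scenes the 3-day mean daily RER lands within a few
percent of the true rate; at a hypothetical 2% per-frame observation noise
the same statistic has an SD of ~0.034 day⁻¹ and per-plant recovery within
±10% of r = 0.15 can no longer be guaranteed — the tests document both
regimes.

## Dawn-dip detection

Epinastic leaf movement shows up as a transient PRA drop just after
lights-on. `detect_dawn_dip()` smooths the series with a *5-frame* median
(a 2-h dip survives it at near-full depth; the 10-frame RER window would
halve it), takes the end of the preceding dark period as the baseline (the
lights-on frame itself is already inside the dip after smoothing), and flags
a dip when the smoothed minimum within 2 h of lights-on is interior, at
least 4% below baseline, and followed by recovery. The 4% depth sits between
the smoothed noise floor of a few-percent-noise series and the ~10%
amplitude typical of wild-type dips. The first dawn of a session has no
pre-dawn baseline and is often undetectable — which is why the validation
asks for two of three dawns rather than all three.

## The synthetic scene generator

Real multi-week plant imagery is too large to ship and has no pixel-exact
ground truth, so every quantitative claim in this package is validated on
synthetic scenes (`scene_spec()`, `generate_session()`). Each plant is a
smoothed star polygon (8 lobes, 15% lobe depth, random fixed rotation)
rasterised so its pixel count is within 1% of the analytic target
$A(t) = A_0 e^{rt}(1 - \text{dip}(t))$, where dip(t) is a half-sine of 10%
amplitude over the 2 h after lights-on (wild-type-like preset) or absent
(mutant-like preset, r = 0.08 day⁻¹ vs 0.20 day⁻¹). VIS frames colour the
stamps in HSV (hue 120° ± 6°) over brown soil with per-pixel texture noise;
NIR frames use reflectances 200 (plant) vs 80 (soil), multiplied by a radial
falloff field (strength 0.3) plus Gaussian noise (SD 5). Defaults emulate an
18-plant 6×3 tray at 0.25 mm/px on a 520×280 raster; the validation runs use
a 6-plant 3×2 tray at 280×170 with the same per-pixel statistics, and
3-day sessions (216 frames) for the end-to-end checks — sizes chosen so the
full suite runs in minutes while every per-pixel property is unchanged.

What the generator deliberately does **not** emulate: antialiased leaf
boundaries (edges are hard so that ground truth is exact at pixel
resolution; real images have mixed boundary pixels, so real-data Dice will
be slightly lower), leaf-level 3-D pose (the dawn dip is modelled directly
as the area modulation it produces in top view), overlapping rosettes, soil
with reflective particles, and slow drifts in illumination colour. Passing
tests therefore demonstrate the correctness of the algorithms under
controlled conditions, not performance bounds on arbitrary real imagery.

## Numerical and design choices

* Period boundaries are half-open `[lights_on, lights_off)`: a frame at
  exactly lights-off is the first dark frame. Deterministic, and consistent
  with 35- or 36-frame periods depending on acquisition phase — the
  partition never forces a count.
* Otsu ties break to the smallest maximising threshold; foreground is
  strictly above the threshold; a constant image is a reported error, not a
  silent all-background mask.
* Hue ranges wrap (low > high means through 0°), since hue is circular and
  reddish genotypes straddle it; in non-circular channels low > high is an
  empty range.
* Connected components use 8-connectivity throughout — rosette leaves often
  join only through diagonal petiole pixels.
* Automatic numbering is by ascending centroid x, ties by ascending y; a
  grid layout can be numbered row-major by seeding instead. Labels lock at
  the first frame and propagate by nearest-centroid matching; fragments of a
  split plant merge back into its label.
* A vanished plant mask is recorded as missing with a warning and the last
  non-empty mask re-seeds the next frame — one bad frame must not abort a
  16-day batch. `average_passes()` falls back to the surviving pass where
  one pass lost a plant.
* All generator randomness flows through one seed recorded in the ground
  truth; identical seeds give bit-identical scenes.

## Known limitations

Chan-Vese assumes a roughly bimodal local intensity model; soil with bright
reflective particles under NIR will inflate PRA slightly. The propagation
carries no shape prior, so a plant that genuinely disappears (e.g. severe
wilting) degrades to the carried-mask fallback. PRA is a 2-D proxy: leaf
movement and overlap convolve with true expansion in older rosettes, which
is precisely why the dawn dip is visible in it.
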