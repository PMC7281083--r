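---
title: "Measuring material-transition distances in SNMM bioprinted filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring material-transition distances in SNMM bioprinted filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inktransition)
```

## The measurement model

Single-nozzle multi-material (SNMM) printheads switch between bioinks
inside one flow path, so each switch produces a filament segment over which
the extruded material blends gradually from the outgoing ink to the
incoming one. `inktransition` operationalizes the length of that segment as
the **90–10 transition distance**: after reducing the filament photograph
to an along-filament red-channel profile and normalizing it to its own
extremes, the transition distance is the axial span between the points
where the normalized signal crosses 0.9 and 0.1 while switching from the
red ink to the blue ink. For a Gaussian-CDF mixing profile with spread
$\sigma$ the statistic has the closed form
$(z_{0.9} - z_{0.1})\,\sigma = 2\,z_{0.9}\,\sigma \approx 2.5631\,\sigma$;
for a linear ramp of length $L$ it is $0.8\,L$.

The chain assumes a roughly straight, axis-aligned filament in the analyzed
crop, dark inks on a light background (or vice versa), and a known pixel
scale (mm/px). Curved paths are handled by cropping straight segments
before analysis, not by path following.

### Pipeline stages and their interpretation choices

Several steps of the published procedure admit more than one reading; the
package fixes each of them as follows and exposes the alternatives as
parameters.

* **Binarization.** "Black and white conversion" is implemented as Otsu's
  threshold on Rec. 601 luminance (`to_binary()`, `method = "fixed"`
  available). The foreground is taken as the minority class, which makes
  the step invariant to swapping foreground/background brightness.
* **Canny threshold.** The published single number (0.3) is interpreted as
  the *high* hysteresis threshold on the normalized gradient magnitude,
  with the low threshold at 0.4 × high — the common dual-threshold
  convention; both are arguments of `detect_edges()`. Edge detection runs
  on the binarized image by default; `measure_filament(binarize = "none")`
  runs it on the grayscale image instead, since the published order is
  ambiguous.
* **"Pixels within the detected edges."** Per image column, the filament
  interior is the set of rows strictly between the outermost (first and
  last) edge pixels; columns with fewer than two edge pixels are excluded.
  The per-column reading matches the per-position averaging that an
  along-filament transition plot implies.
* **Moving average.** The 20-pixel moving average is *centered*, because a
  trailing window would bias both crossing locations by half the window.
  For even windows the symmetric $(w+1)$-point kernel with half-weighted
  end points is used; a plain $w$-point window cannot be centered and would
  shift the profile by half a pixel. With this kernel an ideal step becomes
  an exact linear descent whose 90–10 span is $0.8\,w$ (16 px at $w = 20$),
  and a linear profile is reproduced exactly at every interior position.
  Near the profile ends the window is truncated *symmetrically*, which
  preserves linear profiles (and hence profile means) there too.
* **Normalization.** "Maximum red value" is read as the profile's own
  post-smoothing maximum (and the minimum as its own minimum), making the
  statistic invariant to affine rescaling of the red channel — exposure and
  white-balance changes drop out. The alternative reading (channel maximum
  255) would make the statistic depend on illumination.
* **Crossings.** Scanning in print direction, the transition end is the
  *first* position at or below 0.1 and the start is the *last* position
  before it at or above 0.9 (the outermost bracket). Under noise this rule
  is insensitive to brief re-crossings inside the transition zone.
  Crossings are refined by linear interpolation between the bracketing
  samples (`subpixel = FALSE` reproduces integer-sample behavior); reported
  distances are therefore finer than one pixel, consistent with
  0.01-mm-resolution reporting.
* **Uncertainty.** Reported as the larger of the 0.02 mm floor and one
  pixel at the image scale; after diffusion correction the slope's standard
  error is propagated as
  $\sqrt{u_{\mathrm{meas}}^2 + (t\,\mathrm{se}_k)^2}$.

### Diffusion correction

Dye keeps spreading within the deposited filament, so the apparent
transition distance grows with the time $t$ between deposition and imaging.
The growth is modelled as a through-origin line $D(t) = k\,t$ — the
empirical form of the published trendline, fitted by least squares
(`fit_diffusion_model()`, closed form $k = \sum t_i d_i / \sum t_i^2$, via
`stats::lm` so a standard error is available). The "real" transition
distance is the measured distance minus $k\,t$ (`correct_transition()`).
Design choices here:

* **No intercept.** The empirical law has none; an intercept fit is
  available for diagnostics (`intercept = TRUE`) but refused for
  correction, where it would double-count the intrinsic transition width.
* **Negative corrected values** are kept and flagged
  (`negative_after_correction`) rather than clamped, so condition means
  stay unbiased.
* **Missing elapsed time is an error** — $t = 0$ is never assumed silently.
* **One global model.** The published characterization fits the law on one
  filament and applies it everywhere; the API permits per-condition models
  but does not default to them.
* The timing reference (deposition of the analyzed segment to image
  capture) is supplied by the user per image; the package cannot infer it.

### Condition summaries

`summarize_conditions()` aggregates measurements per print condition
(pressure in psi, nozzle inner diameter in µm, coated vs regular),
reporting n, mean, sd (0 for n = 1), min and max, in deterministic
(pressure, nozzle, coated) order; since no replicate counts or error-bar
definition is standardized for this experiment, all of sd/min/max are
emitted and interpretation is left to the user. Flagged measurements
(clipped at a profile boundary, negative after correction) are excluded by
default. `trend_report()` renders the qualitative pressure and nozzle
effects as descriptive least-squares slopes per factor cell — no hypothesis
tests, as none are part of the characterization.

## The synthetic-data generator

Laboratory filament photographs are not distributable, so validation rests
on `generate_filament_image()`: a straight horizontal band of two inks
blended along the axis by a mixing fraction $g(x)$ (step, clamped linear
ramp, or complementary Gaussian CDF), on a uniform background, with
optional soft band edges, i.i.d. per-channel Gaussian pixel noise, and a
closed-form ground-truth 90–10 width.

Defaults emulate a close-up photograph of a printed filament: a 60-px band
in a 200 × 600 image at 0.05 mm/px (a ~3 mm-wide filament viewed at
20 px/mm), saturated red/blue inks on a near-white background, Gaussian
mixing with $\sigma = 10$ px, noise sd 0.01. The post-print widening uses
the linear law at 0.03060 mm/s — the empirically fitted diffusion rate —
although physical 1-D diffusion would give $\sqrt{t}$ growth; both laws are
available (`growth_law`), with the linear one as default to match the
correction model, and the mechanism treated as purely empirical. Growth is
applied as *additive widening of the 90–10 width* for every profile kind,
which keeps the ground truth closed-form; a step that must widen is
rendered as the linear ramp with exactly that 90–10 width.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real photographs: filament curvature (serpentine
prints must be cropped), perspective and lens distortion, specular
highlights, illumination gradients, ink opacity variations, and
non-Gaussian sensor noise. Results on real imagery depend on those factors;
the generator establishes correctness of the measurement chain, not
robustness to photography.

## Numerical choices and degenerate inputs

* Axial positions are 1-based column indices of the analyzed crop
  (top-left origin, row-major), and distances are differences of positions,
  so the base index never enters a reported width.
* Canny: Sobel gradients use replicate padding (zero padding fabricates
  border edges); gradient magnitude is normalized by its maximum so
  thresholds are fractions; non-maximum-suppression ties — which always
  occur on the symmetric gradient of a binarized boundary — are broken
  toward the foreground pixel, so edges land on the filament's own
  boundary rows.
* Blank images (single-class binarization), empty edge maps, filaments
  covering fewer columns than required, flat red profiles, signals that
  never reach a crossing bound, all-zero time designs and length mismatches
  raise classed conditions (`inktransition_no_filament`,
  `inktransition_filament_too_short`, `inktransition_no_transition`,
  `inktransition_degenerate_design`, ...), never silent fallbacks.
* A constant-color profile leaves the print direction `undetermined`; the
  measurement proceeds left-to-right and flags the result rather than
  failing, but a truly flat profile is a `no_transition` error.

## Validation scale

The test suite and `scripts/acceptance.R` run on images of roughly
100–240 rows × 300–700 columns — wide enough that Gaussian profiles up to
$\sigma = 40$ px reach both plateaus, and that 300 s of widening at
0.03060 mm/s fits inside the frame at 0.05 mm/px. Noise-robustness checks
use 20 seeds per spread at noise sd 0.03; slope-recovery checks use 100
seeds of 50 points. These sizes give sub-pixel recovery margins while
keeping a full run in tens of seconds on one CPU.

```{r example}
spec <- filament_spec(profile_kind = "gaussian_cdf", profile_param = 10,
                      noise_sigma = 0, growth_law = "none",
                      image_width_px = 360, transition_center_px = 180)
gen <- generate_filament_image(spec)
gen$truth
measure_filament(gen$image, window_px = 1)
```

## Known limitations

* The 90–10 rule is the only transition metric; `hi`/`lo` are exposed but
  hue-angle or per-channel-fit metrics are out of scope.
* No skeletonization or curvilinear path following: curved filaments must
  be cropped to straight segments (a rotation flag is provided).
* One filament per analyzed crop; multi-filament scenes are not parsed.
* No illumination correction; strongly uneven lighting will bias the
  self-normalized red profile.
* The diffusion law is empirical and fitted at one condition; whether the
  rate varies with nozzle, pressure or coating is not addressed by the
  default global model.
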