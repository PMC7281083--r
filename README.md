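# inktransition

Quantification of the material-transition distance in single-nozzle
multi-material (SNMM) extrusion bioprinting.

## The problem

SNMM printheads dispense several bioinks sequentially through one nozzle.
Switching inks is not instantaneous: residual ink mixes with the incoming
one, so a stretch of extruded filament carries a blend of both materials.
The length of that stretch — the **transition distance** — is the key
quality metric of an SNMM printhead, and it depends on extrusion pressure,
nozzle inner diameter, and whether the printhead's inner channels carry a
hydrophobic silicone coating.

`inktransition` measures the transition distance from photographs of
printed two-ink (red → blue) filaments:

1. **Segmentation** — the image is converted to luminance and binarized
   (Otsu by default); Canny edge detection (high threshold 0.3, low = 0.4 ×
   high) delimits the filament's boundaries; per image column, the filament
   interior is the set of rows strictly between the outermost edge pixels.
2. **Color profile** — the RGB values inside the filament are averaged per
   column and smoothed with a centered 20-pixel moving average.
3. **Transition statistic** — the red channel is normalized to its own
   extremes, and the transition distance is the axial span from the 90%
   crossing to the 10% crossing of the normalized red signal
   (sub-pixel interpolated), converted to millimetres via the pixel scale,
   with an uncertainty floor of 0.02 mm. For a Gaussian-CDF mixing profile
   of spread σ the 90–10 width is (z₀.₉ − z₀.₁)·σ ≈ 2.5631 σ.
4. **Diffusion correction** — after deposition the dye keeps spreading, so
   the apparent width grows with elapsed time t. A through-origin linear
   model D(t) = k·t is fitted to widths measured over time
   (slope = Σtᵢdᵢ / Σtᵢ²) and its prediction is subtracted:
   corrected = measured − k·t.
5. **Condition summaries** — measurements are aggregated per print
   condition (pressure, nozzle diameter, coated/regular) with descriptive
   trend slopes and a pressure-vs-distance panel plot.

Because printed filaments are not distributable, the package ships a
synthetic filament-image generator whose mixing profiles (step, linear
ramp, Gaussian CDF) have closed-form 90–10 widths, with a growth law that
widens them over elapsed time; every pipeline stage is validated against
this analytic ground truth.

## Worked example

```r
library(inktransition)

# A synthetic filament photographed 100 s after printing. The Gaussian
# mixing profile has sigma = 10 px; dye diffusion (0.03060 mm/s, linear)
# has widened the 90-10 transition from 1.28 mm to 4.34 mm.
spec <- filament_spec(profile_kind = "gaussian_cdf", profile_param = 10,
                      growth_law = "linear", growth_coeff = 0.03060,
                      elapsed_s = 100, noise_sigma = 0.01, seed = 7)
gen <- generate_filament_image(spec)
gen$truth
#> <filament_truth> 90-10 width 86.831 px = 4.3416 mm, center 300 px (a_to_b)

res <- measure_filament(gen$image)
res
#> <transition_result> 'synthetic-seed7': 88.44 px = 4.422 +/- 0.050 mm (a_to_b)

# Diffusion model fitted to widths measured over time after printing
model <- fit_diffusion_model(times_s = c(30, 60, 120, 180, 240, 300),
                             distances_mm = c(0.92, 1.87, 3.62, 5.55, 7.31, 9.24))
model
#> <diffusion_model> D(t) = 0.03067 mm/s * t  (n = 6, R^2 = 0.9999, residual sd = 0.0436 mm)

correct_transition(res, model)
#> <transition_result> 'synthetic-seed7': 88.44 px = 4.422 +/- 0.051 mm (a_to_b)
#>   diffusion-corrected: 1.355 mm (elapsed 100 s)
```

The measured width (88.44 px = 4.42 mm) recovers the analytic ground truth
(86.83 px) to within the smoothing bias of the 20-px moving average;
subtracting the fitted diffusion contribution at t = 100 s returns the
deposition-time transition distance (1.36 mm vs the 1.28 mm fresh-filament
truth).

Real photographs enter through `read_filament_image()` (PNG/TIFF, with
pixel scale, elapsed time, optional crop/rotation), and condition-level
reporting through `summarize_conditions()`, `trend_report()` and
`plot_condition_summaries()`. Thin command-line wrappers (`simulate`,
`measure`, `fit-diffusion`, `summarize`) live in
`inst/scripts/inktransition-cli.R`.

## See also

The methods vignette (`vignettes/transition-distance.Rmd`) documents the
model, the interpretation choices behind each pipeline stage, the
generator's assumptions, and known limitations.
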