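# ctiq — task-based CT image quality analysis

`ctiq` is an R package for medical physicists and QA engineers who
characterise CT scanners with Catphan-style phantoms. It implements the
full task-based analysis chain recommended by AAPM TG-233 for modern
(iteratively reconstructed, photon-counting-class) scanners, where classic
linear-system metrics alone are not sufficient:

* **Uniformity**: uniformity index
  `UI = 100 (HU̅_periphery − HU̅_center)/(HU̅_center + 1000)` (positive →
  cupping, negative → capping) and integral non-uniformity
  `IN = (HU̅_max − HU̅_min)/(HU̅_max + HU̅_min + 2000)` over the standard
  centre + four-periphery ROI layout (55 mm ring, 20 mm ROIs, 13 slices).
* **Contrast**: Michelson contrast `c = (A − B)/(A + B)`, `CNR = c/σ_bkg`,
  `SNR = A/σ_bkg`; histogram statistics (median, IQR, skewness, excess
  kurtosis) of a pixel ROI; insert CT numbers from 8-pixel circular ROIs.
* **Noise power spectrum**:
  `NPS2D = (Δx Δy / Nx Ny) · ⟨|FFT2D[ROI − second-order polynomial fit]|²⟩`
  with exact discrete Parseval bookkeeping, radial NPS1D, `f_peak`,
  `f_average`, and the noise magnitude `√(∬NPS2D)`.
* **Spatial resolution**: slice thickness from 23°-tilted wire ramps
  (FWHM × tan 23°), and the target transfer function from circular inserts
  via radial ESF → LSF → DC-normalised Fourier transform, with `f50`/`f10`.
* **Detectability**: the non-prewhitening index
  `d′² = [∬W²TTF²]² / ∬W²TTF²·NPS` for a circular task (analytic disc
  transform `W(ρ) = C r J₁(2πρr)/ρ`, default 5 mm), plus protocol
  comparison arithmetic (`compare_dprime`) and a bundled published
  reference d′ table.
* **HU linearity**: OLS regression of measured insert HU on user-supplied
  linear attenuation coefficients, with R².
* **A synthetic phantom simulator** (sensitometry, uniformity,
  low-contrast modules, tilted ramps) with exact analytic ground truth —
  Gaussian PSF rendered via closed-form blurred primitives, stationary
  correlated noise with known `NPS = σ²ΔxΔy|H|²/⟨|H|²⟩`, quadratic radial
  cupping/capping field — so every estimator is validated by parameter
  recovery.

## Worked example

```r
library(ctiq)
g  <- catphan_geometry()

# a "scanner": 0.3 mm Gaussian blur, 8 HU band-pass noise, mild cupping
tr  <- ground_truth(blur_sigma_mm = 0.3, noise_sigma_hu = 8,
                    noise_kernel = nps_kernel_ramp(0.45), seed = 11)
tru <- ground_truth(radial_poly = c(0, 12 / 55^2), noise_sigma_hu = 8,
                    noise_kernel = nps_kernel_ramp(0.45), seed = 11)

uni <- render_module(g, "ctp486", tru, n_slices = 13)
ua  <- uniformity_analysis(uni, g)
np  <- nps_2d(extract_noise_rois(uni))
s   <- nps_summary(np)

sens <- render_module(g, "ctp404", tr)
tt   <- ttf_from_insert(sens, g$inserts[[7]])        # Teflon
dp   <- detectability_index(tt, np, task_function(5, 30, np$fx, np$fy))

rmp <- render_ramp_stack(g, ground_truth(slice_fwhm_mm = 0.8))
st  <- slice_thickness(rmp, geometry = g, nominal_mm = 0.8)
```

which prints, with the formatting of the example script:

```
UI = 1.101 (cupping), IN = 0.00550
f_peak = 0.32 /mm, f_average = 0.36 /mm, noise magnitude = 8.0 HU
Teflon TTF: f50 = 0.61 /mm, f10 = 1.11 /mm
d-prime (5 mm disc, 30 HU contrast) = 25.8
slice thickness = 0.77 mm (nominal 0.8, within tolerance: TRUE)
HU linearity: slope = 5258 HU cm, R^2 = 1.00000
```

Reading: the injected +12 HU periphery-vs-centre field shows up as a
positive (cupping) UI of the expected plug-in magnitude; the band-pass
noise kernel peaks near 0.32 mm⁻¹ and integrates back to the 8 HU that
was put in; the measured f50 = 0.61 mm⁻¹ sits on the Gaussian closed form
`√(ln 2 / 2π²σ²)` = 0.625 mm⁻¹ for σ = 0.3 mm; the 0.8 mm slice profile is
recovered within the pixel-quantisation bound and the ±0.5 mm tolerance
applied to sub-millimetre collimations; and the insert HUs are collinear
with their attenuation coefficients (R² = 1 for a linear synthetic
scanner).

## Command line

A subcommand CLI (simulate / uniformity / nps / ttf / dprime / linearity /
report), driven by a single JSON config, ships in
`inst/scripts/ctiq-cli.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "ctiq-cli.R", package = "ctiq"))')
Rscript "$CLI" simulate   --config cfg.json --out sim
Rscript "$CLI" uniformity --config cfg.json --out results
Rscript "$CLI" nps        --config cfg.json --out results
```

Series are plain-text slice files (one JSON header line + pixel matrix;
rescale slope/intercept applied at read time, slices sorted by z); the
simulator writes the same format plus a ground-truth sidecar. See the
vignette (`vignettes/task-based-ct-image-quality.Rmd`) for the model
definitions, conventions (population SD, pixel-centre ROI membership,
NPS normalisation), simulator assumptions and known limitations.
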