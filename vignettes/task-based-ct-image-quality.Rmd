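---
title: "Task-based CT image quality with ctiq: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based CT image quality with ctiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
```

## What this package measures

`ctiq` implements the task-based image-quality analysis routinely applied to
axial CT acquisitions of a Catphan-style QA phantom, in the spirit of AAPM
TG-233: classical uniformity and contrast metrics, the in-plane noise power
spectrum (NPS), the target transfer function (TTF) measured on circular
material inserts, and the non-prewhitening (NPW) detectability index d'
that combines the two for a specified detection task. Because real
scanner series are rarely redistributable, the package ships a synthetic
phantom simulator with fully known ground truth (true HU values, Gaussian
blur, analytic noise power spectrum, radial cupping/capping field, slice
sensitivity profile), so every estimator can be validated by parameter
recovery rather than by comparison to proprietary data.

## Metric definitions

**Uniformity.** With $\overline{HU}_{periphery}$ the average of four
20 mm ROI means placed top/right/bottom/left at 55 mm from the phantom
centre (each averaged over 13 slices of the uniformity module) and
$\overline{HU}_{center}$ the matching central ROI mean,

$$UI = 100\,\frac{\overline{HU}_{periphery}-\overline{HU}_{center}}
{\overline{HU}_{center}+1000},\qquad
IN = \frac{\overline{HU}_{max}-\overline{HU}_{min}}
{\overline{HU}_{max}+\overline{HU}_{min}+2000},$$

where IN runs over the five ROI means. Positive UI means underestimated
attenuation at the centre (cupping), negative means capping; the
classification in `uniformity_analysis()` follows that sign. The choice to
average the four periphery ROI means (rather than pool their pixels) is an
interpretation; with equal-sized ROIs the two differ only in pathological
cases.

**Contrast.** Michelson contrast
$c = (\overline{HU}_{ins}-\overline{HU}_{bkg})/(\overline{HU}_{ins}+\overline{HU}_{bkg})$,
$CNR = c/\sigma_{bkg}$ and $SNR = \overline{HU}_{ins}/\sigma_{bkg}$, with
$\sigma_{bkg}$ the background ROI standard deviation. Note the Michelson
denominator is *not* offset by 1000, so it can legitimately vanish (air
against a ~+1000 HU material); the package raises an explicit error there
rather than returning an unstable number.

**NPS.** For $N_{ROI}$ square pixel blocks $ROI_i$ of size
$N_x \times N_y$ taken from the homogeneous module (default eight 25 mm
ROIs per slice on a 50 mm ring),

$$NPS_{2D}(f_x,f_y)=\frac{\Delta x\,\Delta y}{N_x N_y}
\cdot\frac{1}{N_{ROI}}\sum_i \left|\mathrm{FFT}_{2D}
\left[ROI_i-FIT_i\right]\right|^2,$$

with $FIT_i$ the least-squares fit of the full bivariate polynomial of
total degree two. The ROI-dimension normalisation uses the *pixel counts*
$N_x N_y$, which gives units HU^2 mm^2 and makes the discrete Parseval
identity exact: the Riemann integral of $NPS_{2D}$ over the Nyquist square
equals the mean detrended pixel variance (asserted to 1e-10 in the tests).
No window function is applied; detrending is the only leakage control.
The radial profile averages over annuli one DFT bin wide; the DC cell is
excluded (detrending forces it to ~0, and numerical residue would bias the
summaries). `f_peak` is the radial maximum (ties to the lower frequency),
`f_average` the NPS-weighted mean frequency over the full annuli inside
the inscribed Nyquist circle — the NPS-weighted reading of "average
frequency" is an interpretation, chosen because it sits close to `f_peak`
for peaked spectra, as published summary tables show. The noise magnitude
is $\sqrt{\iint NPS_{2D}}$ over the *whole* Nyquist square, not just the
inscribed circle.

**Slice thickness.** Each 23-degree tilted wire ramp is projected onto an
along-ramp profile (max across a narrow strip, bilinear sampling at a
tenth of a pixel), a background from two flanking strips is subtracted,
and the FWHM is read off by linear interpolation of the half-maximum
crossings; thickness = FWHM x tan(tilt), averaged over the four ramps.

**TTF.** The edge spread function of a circular insert is built by binning
pixel values by radial distance from the (centroid-refined) insert centre,
bin width 0.1 pixel; the LSF is its finite-difference derivative; the TTF
is the modulus of the Fourier transform of the LSF normalised to its DC
component, so TTF(0) = 1 exactly. `f50`/`f10` are the first downward
crossings of 0.5/0.1, flagged `">Nyquist"` when no crossing exists. The
radial ESF is used without curvature correction, valid when the insert
radius is large against the blur (the bundled inserts have 6.1 mm radius;
the closed-form recovery tests pass within 3 percent for blur sigma up to
0.5 mm). An optional cosine taper (default 20 percent of the LSF support)
suppresses noise leakage; it is disabled in all oracle tests.

**Detectability.** For a circular task of diameter $d$ (default 5 mm) and
contrast $C$, the task function is the analytic disc transform
$W(\rho)=C\,r\,J_1(2\pi\rho r)/\rho$, $W(0)=C\pi r^2$ — not a rasterised
DFT, which would alias; the rasterised version exists only as a test
oracle. The NPW index is

$$d'^2=\frac{\left[\iint W^2\,TTF^2\,du\,dv\right]^2}
{\iint W^2\,TTF^2\,NPS\,du\,dv}$$

evaluated as Riemann sums on the NPS grid, with the radial TTF
interpolated onto the grid and extrapolated as zero beyond its last
computed frequency (conservative). With TTF = 1 and white NPS $N_0$ this
reduces to $d'=C\sqrt{\pi r^2/N_0}$, the closed form used in the
acceptance tests. `compare_dprime(a, b)` reports $a-b$ and $100(a-b)/a$
with the first argument (standard / larger-collimation protocol) as the
reference — the convention under which the bundled reference table
reproduces its published percent differences.

**HU linearity.** Ordinary least squares of measured insert HU on
user-supplied linear attenuation coefficients (1/cm), reporting slope,
intercept and $R^2$. Spectrum modelling and attenuation lookup are
deliberately out of scope: the mu table is an input.

## The simulator as a stated world

`render_module()` composes (ideal HU map convolved with an isotropic
Gaussian PSF) + radial field + stationary correlated noise:

* **Edges.** Sharp scenes are rendered with 4x supersampling and box
  averaging. Blurred scenes use the *exact* analytic profiles instead:
  a Gaussian-blurred disc is the noncentral-$\chi^2_2$ CDF
  $P(\chi^2_2(r^2/\sigma^2)\le R^2/\sigma^2)$ point-sampled at pixel
  centres (with a plain erf profile once $R/\sigma > 100$, where the
  curvature term is below 0.5 percent), so the realised edge has exactly
  the Gaussian MTF $\exp(-2\pi^2\sigma^2 f^2)$ and TTF recovery is a true
  closed-form oracle rather than a discretisation-limited approximation.
* **Noise.** Per-slice frequency-domain filtering of white Gaussian noise
  by a radial kernel $H(\rho)$, scaled so the pixel standard deviation is
  $\sigma$; the analytic spectrum is
  $NPS = \sigma^2\Delta x\Delta y\,|H|^2/\langle|H|^2\rangle$
  (`true_nps()`). Slices are independent — the analysis is 2D in-plane and
  no 3D correlation is claimed. Seeds derive from one master seed through
  a fixed per-slice counter, so renders are bit-reproducible.
* **Cupping/capping.** A quadratic radial field $a_1 r + a_2 r^2$. For a
  pure $r^2$ field the expectation of $r^2$ over a disc ROI at centre
  distance $c$ is $c^2 + R_{ROI}^2/2$, which makes the plug-in UI value
  exact and testable to three standard errors under noise.
* **Ramps.** A wire crossing the slice plane at tilt $\theta$ appears
  in-plane as a segment of extent FWHM$/\tan\theta$; the slice sensitivity
  profile is modelled rectangular, so the in-plane profile is a top-hat
  whose FWHM survives symmetric blur unchanged.

Defaults are the conditions the analysis is meant for: 0.42 mm pixels
(the clinical axial pixel size of the scanner class this emulates),
phantom radius 100 mm, insert diameter 12.2 mm on a 58.4 mm ring,
background +90 HU, periphery ROIs at 55 mm, 20 mm diameter, 13 slices,
eight 25 mm noise ROIs per slice. Noise sigmas of 5-10 HU are used in the
recovery tests, matching the mid-range of published noise magnitudes for
abdomen-class protocols.

What the simulator does **not** emulate: photon-counting physics (pile-up,
charge sharing, spectral response), nonlinear iterative reconstruction,
helical geometry, 3D noise correlation, or nonstationary noise. A green
recovery test therefore establishes estimator correctness on a stationary
linear-system phantom, not scanner realism; published per-protocol tables
measured on real scanners are *not* reproduction targets, and the package
treats them only as inputs to the comparison arithmetic.

## Numerical choices worth knowing

* Standard deviations are population (divide by N) everywhere, so
  CNR/SNR/NPS normalisations agree with each other.
* ROI membership is pixel-centre-inside-shape; mm sizes convert with the
  slice's own spacing, pixel sizes (the 8 px insert ROI, the 128 px
  histogram ROI) are used verbatim.
* Quantiles (median, IQR) use linear interpolation between order
  statistics; kurtosis is reported as *excess* kurtosis. Constant input
  flags the shape moments as undefined instead of dividing by zero.
* Detrending biases the lowest NPS frequency bins low (it removes six
  degrees of freedom concentrated near DC). Because the task weighting
  $W^2$ also peaks near DC, d' computed from a *measured* NPS is biased
  high on coarse frequency grids: about +8 percent with 64 px ROIs at
  0.42 mm spacing in the end-to-end test, falling to ~3 percent with
  128 px ROIs. The end-to-end d' recovery test therefore uses 128 px noise
  ROIs; users comparing d' across protocols (same grid both sides) are
  insensitive to this common-mode bias.
* The tilted-ramp FWHM is quantisation-limited by the in-plane pixel:
  recovery is asserted within max(5 percent, one pixel times tan 23).
* f50/f10 crossings and the ramp half-maximum crossings are linearly
  interpolated; `f_peak` ties break toward the lower frequency.

## Design decisions that were genuinely open

* **DICOM input.** The analysis environment provides no DICOM reader, and
  a hand-rolled parser for a standard format would be worse than none.
  Series I/O therefore uses a plain-text slice format (one JSON header
  line with pixel spacing, z, rescale slope/intercept and protocol
  metadata, followed by the stored pixel matrix) that preserves the full
  series contract: rescale applied at read time, slices sorted by z,
  inconsistent spacing rejected. The simulator writes the same format.
* **Geometry is config, not detection.** Phantom alignment on real scans
  is laser-guided; the package takes explicit geometry (built-in
  `catphan_geometry()` or a JSON file) and offers `locate_center()` only
  as an optional refinement.
* **Visibility scoring is out of scope.** CNR/SNR are computed for any
  caller-specified insert; no human-observer visibility threshold is
  emulated, and low-contrast disc contrast is a free simulator parameter.
* **Eye filters.** The observer is plain NPW; no eye filter or internal
  noise is applied.

## Known limitations

The ESF binning assumes an isotropic pixel grid (circular ROIs use the
mean spacing); strongly anisotropic reconstructions are not supported.
The NPS is 2D and stationary; local NPS maps and 3D spectra are
non-goals. TTF beyond the binning Nyquist is not recovered, and an ideal
step edge is reported as `">Nyquist"` rather than a number. The d'
integrals truncate at the grid Nyquist; grids should extend past the
first zero of the task function (a warning fires otherwise).
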