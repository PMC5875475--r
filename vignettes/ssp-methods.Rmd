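---
title: "Measuring CT slice sensitivity profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CT slice sensitivity profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctssp)
```

## The measurement problem

Helical CT reconstructs axial slices by interpolating projection data
acquired along a helix. Projection data from outside the reconstruction
plane blur the system's axial response, so the *effective* slice thickness
exceeds the nominal one. The slice sensitivity profile (SSP) is the
system's axial response to an impulse-like object — a sub-millimetre
high-attenuation bead or a thin disc positioned at isocenter — and its
full width at half maximum (FWHM) is the standard figure of merit for
effective slice thickness during acceptance testing and periodic QA.

Because the object's signal is spread over several contiguous slices, the
SSP cannot be read from one image. Instead the scan is reconstructed into
overlapping slices at an interval well below the slice thickness
(canonically T/10 over ±5 slice widths, giving 101 images), a fixed ROI is
propagated through the stack, and the per-slice ROI statistic plotted
against slice location *is* the sampled SSP.

## Pipeline

For a series of slices at positions $z_1 < \dots < z_n$:

1. **HU conversion** — stored pixel values are mapped to Hounsfield units
   with the rescale slope and intercept from each file header.
2. **ROI statistic** — per slice, the mean or the maximum HU over the
   fixed ROI, giving a vector $s_i$.
3. **Background correction** — $s_i \leftarrow s_i - (s_1 + s_n)/2$: the
   outermost slices are assumed to contain only background. A warning is
   raised when the corrected end values exceed 10% of the peak or the
   profile is still changing rapidly at the ends (more than 5% of the
   peak per step), both signs that the scan range did not cover the
   profile tails. Each statistic's vector uses its own outermost values.
4. **Normalization** — division by the maximum, so $\max_i v_i = 1$.
5. **FWHM estimation** by one of four methods (below).

The order (correct, then normalize) matters: normalizing first would make
the half level depend on the background.

### Mean vs maximum ROI statistic

The maximum-ROI SSP tracks the object's peak signal and is insensitive to
ROI geometry as long as the hottest pixel stays inside the ROI. The
mean-ROI SSP dilutes the peak over all ROI pixels; if the in-plane blur of
the object grows with distance from the focal slice, the ROI mean decays
more slowly than the peak and the mean-ROI SSP is systematically broader.
This package therefore defaults to the maximum statistic and treats the
mean statistic as a comparison arm.

## FWHM methods

Let $j$ be the index of the (unique, interior) peak. The half level on
side $s$ is $h_s = m_s + (v_j - m_s)/2$ where $m_s$ is that side's
minimum — after background correction the minima sit near zero, so
$h_s \approx v_j / 2$.

* **left / right** — the one side's level is applied to *both*
  crossings. (An alternative reading — mirror the single crossing about
  the peak — is available via `reflect = TRUE` in `fwhm_interp()`; the
  default contract was chosen because it degrades gracefully on
  asymmetric curves.)
* **two_sided** — each side's own level locates its own crossing.
* **gaussian** — a bounded least-squares fit of
  $A \exp(-(z-\mu)^2/(2\sigma^2)) + b$, reporting
  $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,\sigma$.

Crossings are located by linear interpolation between the two bracketing
samples, scanning **outward from the peak** and taking the first bracket
on each side — deterministic and robust to noise wiggles in the far
tails. A sample exactly at the half level is taken as the crossing
without interpolation.

### Numerical choices in the Gaussian fit

The fit minimizes the residual sum of squares with `optim`'s L-BFGS-B
(analytic gradient, at most 500 iterations, relative function tolerance
about $10^{-12}$). Initialization: $\mu$ at the peak sample, $A$ the peak
value, $\sigma$ from the two-sided interpolated FWHM, $b = 0$. The
baseline is fitted by default — mean-ROI curves need not rest at zero —
but is constrained to $|b| \le 0.2\,A_0$ because curves arrive
background-corrected; `fit_baseline = FALSE` pins it at zero. A fitted
$\sigma$ below half the sampling interval triggers an "under-resolved"
warning. A bounded quasi-Newton minimizer was chosen over `nls` with
`algorithm = "port"` after the latter produced spurious convergence
failures on exact noise-free fits, where the baseline parameter is
redundant.

On noise-free symmetric curves all four methods agree to within one
sampling step. Under noise the Gaussian fit pools all samples instead of
two crossings, which is why it is the most precise method and the package
default for reporting.

## Accuracy and precision statistics

Measured FWHMs are compared to the manufacturer-specified effective
widths per nominal thickness (defaults 0.625 → 0.98 mm, 1.25 → 1.38 mm,
2.5 → 2.88 mm, 5.0 → 6.00 mm):

* **percent error** $= 100\,|m - S|/S$, reported to one decimal in CSV,
  full precision internally;
* **one-sample z-test** $z = (\bar m - S)/(s/\sqrt n)$, two-sided normal
  p-value, for repeats against the specification;
* **two-sample (Welch) z-test** for comparing FWHM sets, e.g. mean-ROI vs
  max-ROI.

The reference material never states which z-test variant was used for
which comparison; the contract here is one-sample against the
specification for accuracy tables and Welch two-sample for method
comparisons, both two-sided, no multiple-testing correction. Groups of
identical repeats (sd = 0) report `NA` for z and p rather than erroring,
since a zero-spread group is a legitimate aggregation input.

## The synthetic generator: what it emulates and what it does not

`generate_series()` models the *reconstructed image stack* directly:

$$I(x, y, z) = B + A\,w(z - z_0)\,
  \exp\!\left(-\frac{(x-x_0)^2 + (y-y_0)^2}{2\sigma_{xy}(z-z_0)^2}\right)
  + \mathcal N(0, \sigma_n)$$

with axial weight $w$ either Gaussian
($\sigma_z = \mathrm{FWHM}/2.3548$) or triangular, both with *exact*
ground-truth FWHM, and in-plane blur
$\sigma_{xy}(dz) = \sigma_0 (1 + c\,|dz|/\mathrm{FWHM})$.

Defaults, with rationale:

| parameter | default | why |
|---|---|---|
| grid | interval T/10 over ±5 T (101 slices) | the canonical overlapping-reconstruction protocol; divisors 5 and 2.5 give the 51- and 26-image variants |
| `peak_hu` | 1000 HU | high-attenuation bead over background, typical bead-phantom contrast |
| `background_hu` | 0 HU | water-equivalent surround |
| `inplane_sigma0` | 0.4 mm | bead-scale in-plane blur |
| `inplane_spread_coeff` c | 0 | accuracy studies need a z-independent in-plane shape so mean- and max-ROI agree; c = 1 for mean-vs-max comparisons |
| `noise_sd` | 0 (tests use 5 HU) | 5 HU is a realistic head-protocol noise level against a 1000 HU object |
| `image_size`, `pixel_spacing` | 64 px, 0.5 mm | enough margin for the largest ROI preset; Monte-Carlo tests run at 32 px purely for compute budget — the profile along z is unaffected |
| storage | integer HU, slope 1, intercept −1024 | common CT convention; one HU quantum round-trip error |

The generator's default object position sits on a pixel centre so the 2-D
blur peaks at exactly 1 and the max-ROI curve equals the axial weight
exactly.

What it does **not** model: helical projection/interpolation physics
(pitch, collimation, bowtie/FOV effects are carried as inert metadata and
representable only through the chosen FWHM and noise level), Poisson or
streak noise, the finite physical size of the bead, or disc-vs-bead
geometry. A green end-to-end test therefore establishes that the
*analysis* recovers a known axial profile through the full DICOM
round-trip — it says nothing about scanner physics. The physical
mechanism that broadens mean-ROI profiles is *interpreted* here as
off-focus in-plane spreading (the `c` knob); real scanners show the
broadening, but its mechanism is not modelled from first principles.

## DICOM subset and other interface decisions

No DICOM library exists in the supported environment, so the package
carries a minimal reader/writer: uncompressed Explicit VR Little Endian
written, Explicit and Implicit VR Little Endian read, single-frame CT
only. Axial position prefers the z component of Image Position (Patient)
and falls back to Slice Location (the source used is recorded on the
returned series); spacing may deviate from the median interval by at most
1% before a spacing error is raised — resampling is never done silently.
Series UIDs are derived deterministically from content so identical
simulations yield identical files.

CLI configs are JSON rather than YAML (no YAML parser in the supported
environment). The published reconstruction tables print rounded intervals
(0.06, 0.12, 0.24, 0.48 mm); the implementation uses the exact T/10
division, which is the only reading consistent with the 101-image count.

## Known limitations

* Asymmetric profile models (e.g. exponentially modified Gaussians) are
  out of scope; strongly asymmetric mean-ROI curves are fitted by a
  symmetric Gaussian, which is exactly the regime where the interpolation
  methods and the fit legitimately disagree.
* Sub-pixel ROI geometry and per-slice ROI re-centering are not
  supported; the ROI is fixed in pixel coordinates.
* Symmetric truncation of the scan range (both tails equally unresolved)
  is fundamentally undetectable from the profile vector alone; the
  warning heuristics catch asymmetric truncation and still-decaying
  tails.
* The z-test treats the five-repeat sample standard deviation as known
  variance; at n = 5 the normal reference is approximate (the test suite
  checks null-uniformity of p-values at larger n).
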