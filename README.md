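# ctssp — slice sensitivity profiles for helical CT quality assurance

`ctssp` measures the **slice sensitivity profile (SSP)** of a helical CT
scanner — the system's axial response to a point object — and estimates
the **effective slice thickness** as its full width at half maximum
(FWHM). It is written for clinical medical physicists doing acceptance
testing or periodic QA with a point-response phantom (a sub-millimetre
bead or thin tungsten disc), and for anyone validating SSP analysis code.

The measurement model: a phantom scan is reconstructed into overlapping
slices at interval T/10 over ±5 slice widths (101 images). A fixed ROI is
propagated through the stack; the per-slice ROI statistic (mean or
maximum HU), background-corrected by the average of the two outermost
slices and normalized to unit peak, plotted against slice location, is
the sampled SSP. Its FWHM is estimated four ways:

* **left / right** — a single half level h = m + (peak − m)/2 from one
  side's minimum m, applied to both crossings (linear interpolation
  between bracketing samples);
* **two_sided** — each side's own level locates its own crossing;
* **gaussian** — bounded least-squares fit of
  A·exp(−(z−μ)²/(2σ²)) + b, with FWHM = 2√(2 ln 2)·σ ≈ 2.3548 σ.

Results are compared against manufacturer-specified effective widths
(0.625 → 0.98 mm, 1.25 → 1.38 mm, 2.5 → 2.88 mm, 5.0 → 6.00 mm by
default) with percent error and one-/two-sample z-tests. A synthetic
phantom-series generator with exact ground-truth FWHM, plus a minimal
single-frame CT DICOM reader/writer, make the entire pipeline testable
without scanner time.

## Worked example

Simulate a noisy 2.5 mm-slice scan whose true FWHM equals the 2.88 mm
specification, build the max-ROI SSP, and run all four FWHM methods:

```r
library(ctssp)

cfg <- sim_config(true_fwhm = 2.88, thickness = 2.5, noise_sd = 5, seed = 17)
series <- generate_series(cfg)
series
#> CT image series: 101 slices of 64x64 px, z in [-12.500, 12.500] mm, interval 0.2500 mm, thickness 2.500 mm

ssp <- build_ssp(series, auto_place_roi(series), "max")
ssp
#> SSP curve (max-ROI): 101 points, z in [-12.500, 12.500] mm, background 10.86 HU, norm 983.61 HU

res <- fwhm_all(ssp)
for (r in res) print(r)
#> FWHM [left]: 2.8747 mm (crossings -1.4314 / 1.4434 mm)
#> FWHM [right]: 2.8702 mm (crossings -1.4290 / 1.4412 mm)
#> FWHM [two_sided]: 2.8726 mm (crossings -1.4314 / 1.4412 mm)
#> FWHM [gaussian]: 2.8486 mm (crossings -1.4213 / 1.4273 mm)
#>   fit: A=1.0076 mu=0.0030 sigma=1.2097 b=-0.0013 (residual norm 0.0385)

percent_error(res$gaussian$fwhm, 2.88)
#> 1.1 (percent)
```

All four methods land within ~0.1 mm of each other and within ~1% of the
2.88 mm specification — the behaviour expected of a max-ROI SSP on a
well-sampled grid. The `background` line shows the HU offset removed from
the outermost slices; `norm` is the peak HU the curve was divided by.

## Command line

```sh
ssp simulate -c config.json -o series_dir     # DICOM series + truth.json sidecar
ssp analyze series_dir --statistic max --method gaussian --roi roi1 -o out.csv
ssp report rep1.csv rep2.csv rep3.csv rep4.csv rep5.csv -o table.csv
```

(`ssp` is `inst/exec/ssp`; equivalently call `cmd_simulate()`,
`cmd_analyze()`, `cmd_report()` from R.) Configs are JSON with at least
`true_fwhm` and `thickness`; the report aggregates repeats into
mean/sd/error/percent-error/z/p rows per statistic and method. Exit
codes: 0 success, 2 input error, 3 computation error, 4 usage.

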