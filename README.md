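# chromaPK

Computational companion to HPLC-UV plasma assays of co-administered
cardiovascular drugs — the kind used to quantify clopidogrel (CLP), its
inactive carboxylic acid metabolite (CCA) and atorvastatin (ATV) in patient
plasma with ibuprofen as internal standard (IS). The package is for
bioanalytical and pharmacokinetic scientists who want the *numerical* side
of such a study — system suitability, calibration, validation arithmetic,
compartmental fitting — as tested, reproducible code that runs end to end
on simulated data with known ground truth.

## What it computes

**Chromatography.** Simulated detector traces are sums of Gaussian or
exponentially modified Gaussian (EMG) peaks plus seeded baseline noise.
`detect_peaks()` measures retention time, baseline-corrected height, area
and widths; the system-suitability metrics follow the pharmacopeial
conventions

- plate count `N = 5.54 (tR / w0.5)^2` (half-height method),
- tailing factor `T = w0.05 / (2 f0.05)` (USP 5%-height method),
- resolution `Rs = 2 (tR2 − tR1) / (Wb1 + Wb2)` with `Wb ≈ 1.699 w0.5`,
- `S/N = 2h / Npp` with `Npp` the detrended peak-to-peak blank excursion,

checked against the limits `Rs > 2.0`, `T ≤ 2.0`, `N > 2000`.

**Calibration.** Ordinary least squares of the analyte/IS area ratio on
concentration (`fit_calibration()`, optional 1/x² weighting),
back-calculation with out-of-range flagging, and S/N-based sensitivity
limits: LOD at S/N = 3, LLOQ at S/N = 10.

**Validation.** Accuracy as recovery `100·mean/nominal`, precision as RSD
`100·sd/mean` (sample SD), the ±15 % acceptance rule with inclusive
boundaries, stability and robustness summaries, and forced-degradation
recovery arithmetic.

**Pharmacokinetics.** One-compartment oral kinetics
`Cp(t) = A (e^{−Ke t} − e^{−Ka t})` fitted the classical way: the terminal
log10-linear slope gives `Ke = −ln(10)·slope` (the "−Ke/2.303" relation),
the method of residuals (feathering) gives `Ka`, `t½ = ln2/Ke`,
`tmax = ln(Ka/Ke)/(Ka − Ke)`, linear trapezoidal `AUC(0–t)` over
quantifiable (above-LLOQ) points, and `AUC(0–∞) = AUC(0–t) + Clast/Ke`.

A seeded pipeline (`run_pipeline()`, or `Rscript scripts/run_pipeline.R`)
chains simulation → SST → calibration → validation → PK and writes every
input and report as delimited text plus a JSON run manifest.

## Worked example

Analyse one simulated metabolite profile (dosing schedule 0–12 h, 5 %
assay noise, LLOQ 0.01 µg/mL):

```r
library(chromaPK)
p <- generate_profile(A = 5.1, ka = 3.2, ke = 0.15, lloq = 0.01,
                      noise_cv = 0.05, seed = 42,
                      analyte_id = "CCA", subject_id = "patient1", dose_mg = 75)
analyze_profile(p, rule = "best_r2")
#> PK result [patient1 / CCA]
#>   Ke 0.1498 1/h   t1/2 4.628 h   Ka 3.644 1/h
#>   tmax (model/obs) 0.9135 / 1 h   Cmax (model/obs) 4.345 / 4.311 ug/mL
#>   AUC0-t 27.11   AUC0-inf 32.71 ug.h/mL  (terminal n=4, r^2=0.9957)
```

The fitted elimination rate (0.1498 h⁻¹) recovers the generating value
(0.15) to 0.2 %; the absorption rate from the residual method (3.64 h⁻¹ vs
3.2) carries the noise of the three absorption-phase points; observed Cmax
and tmax are read directly from the sampled curve.

System suitability on the simulated four-peak chromatogram:

```r
ch <- generate_chromatogram(baseline_noise_sd = 0.2, seed = 7)
pk <- detect_peaks(ch, min_height = 1,
                   expected = list(CCA = c(9.4, 9.9), ATV = c(10.7, 11.3),
                                   IS = c(11.5, 12.1), CLP = c(12.4, 13.0)))
sst_evaluate(pk)
#>   analyte_id retention_time plate_count tailing_factor resolution ... pass
#> 1        CCA          9.667       14883         0.9744         NA ... TRUE
#> 2        ATV         11.017       13350         1.0022      3.867 ... TRUE
#> 3         IS         11.803       17442         0.9921      2.129 ... TRUE
#> 4        CLP         12.690       22413         1.4140      2.545 ... TRUE
```

All four analytes clear the limits; the CLP peak's exponential tail shows
up as a tailing factor of 1.41.

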