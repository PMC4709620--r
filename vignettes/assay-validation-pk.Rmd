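---
title: "Methods: chromatographic validation metrics and one-compartment pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatographic validation metrics and one-compartment pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaPK)
```

chromaPK reimplements, as reusable and tested code, the computational
content of an HPLC-UV bioanalytical workflow for clopidogrel (CLP), its
carboxylic acid metabolite (CCA) and atorvastatin (ATV) in plasma with an
ibuprofen internal standard (IS): chromatographic system suitability,
internal-standard calibration, ICH-style accuracy/precision/stability
arithmetic, and one-compartment oral pharmacokinetics. This vignette is
the package's methods reference: the models, every convention we had to
choose, the defaults and their provenance, and what the simulations do and
do not demonstrate.

## The chromatographic simulation

A detector trace is a sum of peak shapes on a uniform time grid (default
20 min at 5 Hz) plus additive Gaussian baseline noise. Each peak is a
Gaussian of width `sigma` (minutes), optionally convolved with an
exponential decay of time constant `tau` (an exponentially modified
Gaussian, EMG). The EMG was chosen because a pure Gaussian can never fail
a tailing-factor limit: `tau` is the single knob that moves the USP
tailing factor away from 1, which the suitability code must be able to
observe. The EMG density is evaluated in the numerically stable scaled
form `f = erfcx(u) exp(-(t-mu)^2/(2 sigma^2)) / (2 tau)`, with an
asymptotic series for `erfcx` beyond `u = 20` and the direct form in the
far right tail, so no parameter combination overflows. Because the EMG
mode sits to the right of its Gaussian centre, the generator shifts the
centre so that the *observed apex* lands at the specified retention time —
retention times in, retention times out.

Peak areas are expressed in detector-response × minutes, consistently
between the generator (unit-area densities scaled by the requested area)
and the integrator (trapezoid over minutes). The response scale is
arbitrary: only area ratios, widths and heights matter downstream.

The default four-peak system places CCA, ATV, IS and CLP at 9.663, 10.998,
11.802 and 12.682 min — the elution order and retention times of the assay
the package accompanies — with widths giving plate counts in the 10^4
range typical of a well-packed 250 mm column, a mild tail on ATV
(`tau = 0.062`, T ≈ 1.1) and a pronounced one on CLP (`tau = 0.100`,
T ≈ 1.5).

## Peak measurement conventions

The assay's reference values state limits, not formulas, so each metric
follows the standard pharmacopeial convention, kept as a single documented
constant:

* **Detection.** Local maxima of a 5-point running mean; a candidate is a
  peak when its baseline-corrected apex height exceeds `min_height`.
  Working on the smoothed trace keeps baseline noise from fragmenting
  peaks; all *measurements* are taken on the raw signal.
* **Bounds and baseline.** From each apex the code walks outward tracking
  the running minimum of the smoothed trace and stops when the trace rises
  a noise-scaled tolerance (3 × a robust `mad`-based noise estimate) above
  it — the nearest true valley, immune to spurious upticks. The local
  baseline is the straight line between the two valley anchors, which
  makes every measurement invariant to a uniform signal offset.
* **Apex.** 3-point parabolic interpolation through the highest corrected
  sample (retention time and height).
* **Integration.** Trapezoidal area of the corrected signal between the
  points where it falls to 1 % of apex height (or the valley, whichever
  comes first) — late enough that EMG tails are not truncated; a pure
  Gaussian loses only ~0.24 % of its mass.
* **Widths.** Linear interpolation between the bracketing samples at 50 %
  and 5 % of corrected height.
* **Metrics.** `N = 5.54 (tR/w0.5)^2` (half-height plate count),
  `T = w0.05/(2 f0.05)` (USP tailing), `Rs = 2 Δt/(Wb1+Wb2)` with
  `Wb = 1.699 w0.5` (the Gaussian 4σ/2.3548σ relation), and
  `S/N = 2h/Npp` with `Npp` the peak-to-peak excursion of a linearly
  detrended, analyte-free blank window (≥ 20 samples required; a blank
  with zero excursion is an error, not an infinite S/N).
* **Limits.** `Rs > 2.0` and `N > 2000` are strict inequalities, `T ≤ 2.0`
  inclusive — exactly as the limit statements read. A plate count of
  exactly 2000 fails; a tailing factor of exactly 2.0 passes.

The reported plate counts of the reference assay (≈ 14 800 – 18 300)
cannot be recomputed without its raw traces; the simulated system is
tuned to the same magnitudes, and the tests verify the conventions
against Gaussian closed forms (N within 1 %, T = 1 ± 0.01, Rs of two
σ = 0.1 peaks 1 min apart = 2.5 ± 2 %) rather than the instrument values.

## Calibration and sensitivity limits

Quantification uses the analyte/IS peak-area ratio against concentration,
fitted by unweighted ordinary least squares (`1/x²` weighting is exposed
but off by default, since the reference assay reports no weighting).
`back_calculate()` inverts the line and *flags* rather than rejects
out-of-range results — the LLOQ censoring downstream decides their fate.
The bundled default configuration carries the reference calibration
designs (e.g. CLP at 0.008–2 µg/mL over 9 levels) and regression lines
(e.g. ratio = 0.3789·conc + 0.0004 for CLP). The CCA design spans
0.015–4 µg/mL although the stated working range begins at 0.01 (and ATV
runs to 2.56 vs a stated 2.5); the package takes levels as given and does
not reconcile that discrepancy.

LOD and LLOQ derive from the signal-to-noise definition: with a *height*
response slope `s` (height per µg/mL) and blank excursion `Npp`,
`LOD = 3 Npp/(2s)` and `LLOQ = 10 Npp/(2s)`, so `LLOQ/LOD = 10/3`
identically. The height slope, not the area slope, is used because S/N is
a height quantity.

## Validation arithmetic

Accuracy is recovery `100·mean/nominal`; precision is RSD `100·sd/mean`
with the *sample* SD (n−1) — the convention is unstated in the reference
tables, but recomputing their printed mean ± SD pairs is
convention-independent. The ±15 % rule is applied with inclusive
boundaries (a mean exactly 15 % off passes), the common reading of the
bioanalytical guidelines. No separate 20 % LLOQ tier is implemented
because the reference applies a single ±15 % rule. Display rounding
follows the printed reports — recovery to whole percent, RSD to two
decimals — using half-away-from-zero rounding (96.5 → 97), with full
precision retained internally. Stability and robustness summaries reuse
the same arithmetic; storage-condition labels are treated as opaque
strings (the reference tables themselves label one condition
inconsistently). Degradation recovery is simply
`100·stressed/reference` peak area.

## One-compartment pharmacokinetics

The model is the single first-order absorption / first-order elimination
(Bateman) solution `Cp(t) = A (e^{−Ke t} − e^{−Ka t})` with
`A = F·D·Ka/(V·(Ka−Ke))`. The degenerate case `Ka = Ke`, where the
solution changes functional form, is a refused input everywhere (its
`tmax` limit `1/Ke` is documented, never silently substituted).

Estimation follows the classical graphical procedure, in code:

1. **Terminal slope.** OLS of `log10 Cp` on `t` over the terminal points;
   `Ke = −ln(10)·slope` (the textbook "−Ke/2.303", with the exact log
   factor so that noiseless log-linear data reproduce `Ke` to machine
   precision). The default terminal set is every quantifiable point
   strictly after the observed Cmax — deterministic and assumption-free.
   An optional `best_r2` rule searches suffixes of length ≥ 3 for the
   best adjusted r², which on the 12 h schedule reliably drops early
   terminal points still carrying absorption. A non-negative slope is a
   no-elimination-phase error.
2. **Method of residuals.** The terminal line is back-extrapolated; at
   quantifiable points at or before the observed Cmax the residuals
   `r(t) = 10^{a + b t} − Cp(t)` must be positive and decay log-linearly;
   `Ka = −ln(10)·slope(log10 r ~ t)`. Non-positive residuals (no distinct
   absorption phase) and fewer than two absorption points are errors.
3. **Derived quantities.** `t½ = ln2/Ke` (an exact identity in every
   result object), model `tmax = ln(Ka/Ke)/(Ka−Ke)` and the model Cmax
   from the back-extrapolated `A`; observed Cmax/tmax are also reported,
   read directly from the data.
4. **AUC.** Linear trapezoid over quantifiable points to the last
   quantifiable time, then `AUC(0–∞) = AUC(0–t) + Clast/Ke`. A
   log-linear-down trapezoid was considered and left out: the reference
   procedure states the plain trapezoidal rule.

Below-LLOQ (censored) points are retained in the data but excluded from
every fit and from the trapezoid — mirroring the reference situation where
parent clopidogrel falls below quantification beyond 3 h. If the fitted
absorption rate comes out below the elimination rate, the curve alone
cannot say which is which (flip-flop kinetics); the larger rate is
reported as Ka and the result flagged.

## The synthetic-data generator as study design

The generator's defaults *are* the study conditions every test and the
acceptance script run under:

* sampling at 0, 0.25, 0.5, 1, 3, 6, 9, 12 h — the clinical schedule of
  the accompanying study;
* multiplicative lognormal assay noise (concentrations stay positive),
  default CV 5 %, a typical validated-assay imprecision; additive
  Gaussian noise for chromatogram baselines;
* simulated patients with elimination rates at the reported per-analyte
  magnitudes (CLP ≈ 0.6–1.0 h⁻¹ with LLOQ censoring beyond ~3 h,
  CCA ≈ 0.13–0.23 h⁻¹, ATV ≈ 0.07–0.08 h⁻¹) and pre-exponential
  coefficients giving the reported Cmax scales;
* for the parameter-recovery study: 200 noiseless profiles with
  `Ke ~ U(0.13, 0.23)` — the reported CCA range, the analyte whose
  profile is fully quantifiable over 12 h — `Ka/Ke ~ U(3, 20)` and
  `A ~ U(4, 7)` µg/mL. Under these conditions the median relative error
  is well under 1 % for Ke, under 5 % for Ka, and under 3 % for
  AUC(0–∞) against the analytic `A(1/Ke − 1/Ka)`. Near the lower end of
  the `Ka/Ke` range absorption still contaminates the 6–12 h window, so
  *individual* profiles can err by a few percent — a real limitation of
  the terminal-slope method on sparse schedules, reported as medians for
  that reason.

Every stochastic call takes one explicit integer seed and restores the
RNG state afterwards; the same seed is bit-reproducible and different
seeds give different realisations. What the simulations do **not**
emulate: matrix effects, carryover, heteroscedastic (concentration-
dependent) assay error, retention drift within a run, gradient effects on
peak shape, or multi-compartment disposition. Passing tests therefore
demonstrate the correctness of the *computations* under the stated model,
not the behaviour of the method on real extracts.

## Numerical choices and problem sizes

Tolerances in the tests reflect the numerics, not wishful precision:
machine-level (1e-10…1e-14) for closed-form identities and OLS against
normal-equation oracles; 0.1–1 % for quantities limited by the 5 Hz
sampling grid (areas, widths, plate counts); stated Monte-Carlo
tolerances for sampling checks. The default problem sizes — 6 001-point
chromatograms, 8-point profiles, 200-profile recovery studies, 3-patient
× 3-analyte pipeline runs — keep the full suite and the acceptance script
in the tens of seconds while leaving every estimate's error far from its
tolerance.

## Known limitations

* Overlapping peaks are not deconvolved; when a broad peak swallows a
  neighbour the valley baseline distorts both measurements (the SST
  report still fails such systems, which is the point).
* The terminal/absorption split is driven by the observed Cmax; schedules
  with no samples after absorption is complete will bias Ke upward and
  the default rule offers no remedy beyond `best_r2`.
* The ±15 % rule is the only acceptance tier; incurred-sample reanalysis
  and LLOQ-tier rules are out of scope.
* Reported instrument-derived values of the accompanying assay (plate
  counts, real-extract r², stress-degradation recoveries) are used as
  simulation targets and format references only — they are not
  recomputable without raw traces, and the package does not pretend to.
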