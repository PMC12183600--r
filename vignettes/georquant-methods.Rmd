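---
title: "Quantifying glycerol electrooxidation products from HPLC-DAD chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glycerol electrooxidation products from HPLC-DAD chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analytical problem

Electrochemical oxidation of glycerol (GEOR) produces a panel of closely
related C1-C3 oxygenates: oxalic (OA), tartronic (TA), glyceric (GA),
glycolic (GCA) and formic (FA) acids, glyceraldehyde (GlyAld),
dihydroxyacetone (DHA), plus the unconverted glycerol. On a proton
ligand-exchange column with diode-array detection the panel separates into a
stable retention-time map (OA 12.37, TA 13.64, GA 17.13, GCA 18.31, DHA
20.76, glycerol 22.46 min) with one unavoidable co-elution: formic acid and
glyceraldehyde share the 19.46 min slot. Because glyceraldehyde is the only
panel member with usable absorbance at 300 nm, the pair can be split
spectrally: quantify GlyAld at 300 nm, predict its 205 nm area from its
205 nm calibration line, subtract that from the merged 205 nm area, and
convert the remainder to a formic acid concentration.

`georquant` implements this workflow end to end — simulation, peak
processing, calibration and validation statistics, the indirect split, and
electrochemical reporting — so that every stage is testable against known
ground truth.

## The synthetic chromatogram generator

No instrument data ships with the package; a seeded generator
(`simulate_injection()`) stands in for the detector. It emulates:

* **Peak shape.** Pure Gaussians by default, with an exponentially modified
  Gaussian available behind the `shape` option. The Gaussian default was
  chosen because it gives closed-form areas, so every integration step can
  be checked against an exact oracle; real ion-exclusion peaks show mild
  tailing that the EMG option can reproduce when needed.
* **Response.** The area of each analyte's peak at wavelength `w` is
  `slope[w] * concentration`, with the validated 205 nm slopes
  (167894, 34133, 9994, 7441, 6309, 17903, 12566 and 30.6 area units per mM
  for OA, TA, GA, GCA, FA, DHA, GlyAld and glycerol). The GlyAld 300 nm
  slope is not published at full precision, so the library carries a
  configurable synthetic default (4000 area/mM); likewise lactic acid
  (8000) and the alkaline-matrix salt peak (5000). All three are
  configuration, never constants, and every algorithm reads them from the
  `default_library()` object.
* **Peak width.** `peak_sigma = 0.12` min for all analytes. This single
  width reproduces the method's qualitative separation structure: every
  validated adjacent pair is baseline-resolved (resolution
  `Rs = 2*dt/(w1+w2)` with `w = 4*sigma` above 1.5; the closest, GA/GCA at
  1.18 min, gives `Rs = 2.46`), while the optional lactic acid (17.88 min)
  and glycolic acid pair stays partially overlapped (`Rs = 0.90`), which is
  exactly the case the two-Gaussian deconvolution
  (`fit_overlapped_pair()`) exists for.
* **Noise.** Two sources: a multiplicative lognormal injection-amount
  factor (mean 1, CV `area_cv = 0.005` by default), drawn once per analyte
  per injection and shared across wavelengths because the physical source is
  the injected volume; and additive white baseline noise
  (`baseline_sd = 0.02` absorbance units) with optional linear drift. The
  CV default puts simulated repeatability RSDs in the 0.1-1.6% band a
  validated 205 nm method achieves.
* **Time grid.** 0-30 min at `dt = 0.01` min, matching a 30 min run; the
  simulator warns when `dt` exceeds `peak_sigma / 5`.
* **Seeding.** One root seed; each injection of a series draws from its own
  stream derived by a stable string hash of (analyte, level, replicate), so
  a series is reproducible as a whole, per injection, and independent of
  evaluation order.
* **Matrix effects.** Alkaline electrolysis samples are acid-quenched
  before injection (1000 uL + 250 uL, dilution factor 1.25) and show a
  salt peak at 11.38 min. The salt peak sits 0.99 min from the nearest
  analyte, so with the 0.15 min assignment tolerance it is detected but
  never assigned to the panel.

What the generator deliberately does **not** emulate: retention-time drift
across runs, detector saturation, tailing from column overload, carryover,
and real matrix absorbance structure. Passing tests therefore demonstrate
the correctness of the computational pipeline under the stated noise model,
not the ruggedness of an instrument method.

## Peak processing

The baseline is a morphological opening (rolling minimum then rolling
maximum over a 2 min window, then a short mean smooth, recentred on the
residual median). The opening reproduces flat and linearly drifting
baselines exactly in the interior and removes any feature narrower than the
window; the median recentring keeps the baseline on the centre of the noise
band rather than its floor. Detection takes local maxima of the
baseline-subtracted signal above `min_height` (default 0.1, five times the
default baseline sd) with prominence above `min_prominence` (0.06). Bounds
fall at the valley toward a neighbouring peak or where the flank decays to
the 5-sigma-equivalent level, so the trapezoidal area of an isolated
noise-free peak captures the analytic area to better than `1e-6` relative.

Assignment uses a +/-0.15 min window: generous against the 1.18 min closest
approach of distinct validated analytes, tight enough to keep the salt peak
unassigned. When several library entries share a slot (FA/GlyAld) the peak
carries the full co-elution group and is integrated **once** — the indirect
method consumes the combined area, never a split of it.

Deconvolution of the lactic/glycolic overlap is explicit, not automatic:
`fit_overlapped_pair()` is called only when both species are declared
present, because silent overlap-hunting on every chromatogram would invite
false positives on shoulder noise.

## Calibration and validation statistics

Calibration lines are ordinary least squares through the origin by default,
because the validated method reports all its regressions in the
intercept-free `y = (m +/- sd) x` form; the intercept mode remains
available. `r_squared` is computed against the centred total sum of squares
in both modes, which is the convention calibration reports use.

Detection limits follow `LOD = 3.3 sigma / S` and `LOQ = 10 sigma / S`.
The phrase "standard deviation of the response" is ambiguous: the slope
standard error and the residual standard deviation are both defensible
readings, and published limit tables are not always self-consistent between
the two. Both are implemented (`sigma_mode`), the default is `slope_sd`
(the only sigma-like quantity an intercept-free report prints), and every
reported limit carries its `sigma_mode` tag so no convention is silently
canonised.

Repeatability is the sample-sd RSD of replicate concentrations
(`100 * sd / mean`); recovery is `100 * mean(measured) / theoretical`.
Below-LOQ quantifications are reported with a flag and excluded from
selectivity accounting by default; negative back-calculated concentrations
clip to zero with a flag. The indirect formic acid subtraction can
likewise produce small negative areas at trace levels under noise — these
clip and flag rather than raise, because a batch run must survive its blank
injections, and the unclipped area is retained so the additivity identity
`A_mix = A_GlyAld,205 + A_FA,205` is exactly checkable on every result.

## Electrochemical reporting

Quantified injected concentrations are corrected back to cell
concentrations by the quench dilution factor (1.25). Selectivity is the
percentage share of each product; the default **mole** basis
(`100 * C_i / sum(C_j)`) matches how per-product distribution percentages
are usually quoted, with carbon-weighted and electron-weighted bases
available for comparison since the accounting convention differs between
groups. Faradaic efficiency is charge bookkeeping,
`FE = 100 * F * sum(z_i C_i V) / Q`, with electrons-per-mole derived from
oxidation-state differences against glycerol (mean carbon oxidation state
-2/3): GlyAld and DHA 2, GA 4, GCA 10/3, FA 8/3, TA 8, OA 22/3. The table
is configurable. Gaseous CO2/O2 are invisible to the detector, so an FE
short of 100% is reported as-is — that shortfall is physically meaningful
at high anodic potentials.

The electrolyte volume is an input, never a constant: the analysis scripts
use a 10 mL single-compartment cell, a realistic bench scale under which a
50 C charge corresponds to ~52% of the two-electron full conversion of
50 mM glycerol.

## Numerical choices and problem sizes

* Trapezoidal integration with endpoint interpolation: second-order in the
  grid step; at the default `dt = 0.01` min the isolated-peak error is
  below `1e-6` relative.
* The two-Gaussian fit runs Levenberg-Marquardt with positivity bounds on
  areas and widths; non-convergence returns best-so-far parameters with an
  honest `converged = FALSE`.
* Assignment ties break by retention-time distance, then alphabetically.
* The test-suite and acceptance studies use the method's own design sizes
  (five levels, triplicate injections), which keeps each simulated study at
  15 injections and a full validation pass under a minute.

## Worked example

```{r, eval = FALSE}
library(georquant)
lib <- default_library()

# calibration from simulated triplicate standards, full pipeline
cal <- calibrate_simulated("OA", 205, library = lib,
                           noise = noise_model(seed = 7))
cal$curve

# indirect formic acid on one equimolar mixture
curves <- list(
  glyald_300 = calibrate_simulated("GlyAld", 300, library = lib,
                                   noise = noise_model(seed = 11))$curve,
  glyald_205 = calibrate_simulated("GlyAld", 205, library = lib,
                                   noise = noise_model(seed = 11))$curve,
  fa_205     = calibrate_simulated("FA", 205, library = lib,
                                   noise = noise_model(seed = 13))$curve)
study <- indirect_fa_study(curves, library = lib, noise = noise_model(seed = 3))
max(study$error_pct)
```

## Known limitations

* Single-run retention times: no alignment across batches.
* Two-component deconvolution only; three-way overlaps are out of scope.
* The GlyAld 300 nm, lactic and salt response slopes are synthetic
  placeholders until instrument values are supplied through
  `default_library()` overrides.
* Selectivity conventions differ across the literature; the mole basis is a
  package default, not a claim that it is the only defensible accounting.
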