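---
title: "Electrothermal phenotyping of ex vivo breast biopsy tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrothermal phenotyping of ex vivo breast biopsy tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrotherm)
```

## The measurement problem

Tumor progression remodels the extracellular matrix of breast tissue —
collagen fibers fragment, stiffness rises, water content shifts — and these
changes are visible in the tissue's effective electrical and thermal
transport. A microchip with a platinum microheater, concentric circular
interdigitated electrodes (IDEs) and three resistance temperature detectors
(RTDs), pressed against a cubical biopsy block from two opposite faces,
measures three scalar markers per sample and temperature:

* **bulk resistivity** $\rho_B = R_B A / l$ (reported in $\Omega\,$cm), where
  $R_B$ is the DC resistance measured through the tissue thickness $l$ and
  $A$ is the electrode cross-sectional area. DC transport is dominated by
  the extracellular matrix because the cell membrane capacitance blocks
  direct current;
* **surface (sheet) resistivity** $\rho_S = \dfrac{2\pi}{\ln(D_2/D_1)} R_s$
  (in $\Omega/\square$), the geometry-corrected resistance of one tissue
  face contacting the concentric IDE pair with diameters $D_1 = 130\,\mu$m
  and $D_2 = 140\,\mu$m, so the multiplier is $84.8$ to three significant
  figures;
* **thermal conductivity** $k = \dfrac{Q\,l}{A_c\,\Delta T}$
  (W m$^{-1}$ K$^{-1}$): ex vivo there is no blood perfusion or metabolic
  heating, so the tissue bioheat equation reduces to steady conduction, and
  a one-dimensional balance across the block (heater power $Q = VI$, contact
  area $A_c$, steady temperature drop $\Delta T$ between the heated face and
  the sink face) yields $k$ directly.

Tissue temperature is ramped from 25 to 37 °C in 3 °C steps (collagen is
thermally unstable above 37 °C). Tumor tissue shows a markedly larger rise
in $\rho_B$ and $\rho_S$ over that ramp than adjacent normal tissue, and a
lower $k$ at both endpoints; the package's statistics quantify how well the
three markers — singly and in combination — delineate tumor from normal.

RTD readings follow the first-order linear law
$R(T) = R_0\,(1 + \alpha (T - T_0))$ with a single temperature coefficient
$\alpha = 2.2\times10^{-3}\,$°C$^{-1}$, the value measured for the
fabricated platinum film. A single printed coefficient warrants a linear
law; no quadratic (Callendar–Van Dusen) term is fitted. The sink temperature
is the unweighted mean of the three RTD temperatures: no RTD coordinates are
available that would justify a position-weighted triangulation.

All internal computation is in SI units; $\Omega\,$cm and $\Omega/\square$
appear only at the I/O boundary, matching the conventional reporting units.

## What the synthetic cohort emulates

No raw per-sample measurements are published for the reference study, so the
package generates cohorts with its statistical structure: 8 patients, half
deparaffinized FFPE and half formalin-fixed, a paired tumor and
adjacent-normal block per patient, and 3 technical repeats per block — 48
samples, each measured at 5 setpoints (240 records). The generator's
defaults reproduce the published group table exactly
(`default_group_parameters()`), including every mean, spread and 37 °C/25 °C
fold ratio.

Design choices, made once:

* **Lognormal inter-sample variability, moment-matched.** Resistivities and
  conductivities are positive, right-skewed quantities; each group cell is
  matched in mean and standard deviation by a lognormal.
* **Published "±" values are standard errors.** They are converted to
  per-sample SDs with $\sqrt{n}$, $n = 12$ (4 patients × 3 repeats). This
  reading — rather than taking "±" as an SD — is the one consistent with the
  published paired t tests: with SEM-scaled spreads a fold change of ~3 in
  the normal groups is borderline at $n = 12$, as reported, whereas SD-scaled
  spreads would make every contrast overwhelmingly significant. The source
  does not state the convention; this is a declared assumption.
* **Correlated endpoints.** A sample's values at 25 and 37 °C are drawn as a
  bivariate lognormal with log-scale correlation 0.8 (both endpoints are
  measured on the same physical block); the per-sample fold factor is the
  ratio of the two draws, so group-mean folds match the published ratios in
  expectation.
* **Hierarchical technical repeats.** Repeats cut from one specimen share a
  block-level draw and scatter around it with a within-block CV of 0.15
  (typical bench repeatability); the group-level marginal moments are
  preserved exactly. Without this structure "technical repeats" would be as
  variable as unrelated patients.
* **Interpolation between endpoints.** Only the two endpoint distributions
  are published. Resistivities interpolate geometrically,
  $\rho(T) = \rho(25)\cdot F^{(T-25)/12}$, making the fold ratio $F$ the
  single shape parameter; $k$ interpolates linearly (its folds are near 1).
* **Noise model.** Independent multiplicative Gaussian noise with CV 0.02 is
  applied to each raw electrical observable (bulk resistance, both surface
  resistances, heater voltage and current) and to each RTD *temperature
  reading*. No instrument noise figure is published; 2% is an
  instrument-style proportional error. Noise is deliberately not applied to
  the raw RTD resistance: because $\alpha R_0 \approx 0.22\,\Omega/$°C, a 2%
  resistance error would correspond to a ~9 °C temperature error, which no
  working RTD readout exhibits; scaling the temperature reading keeps the
  noise physically commensurate across channels.
* **Thermal boundary.** The sink face is held at a 20 °C ambient, below the
  lowest setpoint, so a positive steady gradient — and hence a measurable
  $k$ — exists at every setpoint including 25 °C. The heater drive voltage
  follows a precalibrated map $V \propto \sqrt{T - T_\mathrm{amb}}$ (Joule
  power scales as $V^2$ and required power scales with the temperature
  lift), with the current set so $VI$ equals the steady-state power.
* **Single seed.** Every draw flows from `study_config(seed = )` in a fixed
  order; a fixed seed makes all downstream CSV/JSON output byte-identical.

With `noise_cv = 0` the inverse pipeline recovers the generating truth to
better than $10^{-9}$ relative error at every setpoint — the central
self-consistency contract between the forward model and the estimators.

## The delineation statistics

For each preparation arm, `delineation_table()` computes four contrasts per
parameter: within-group temperature contrasts (37 vs 25 °C) by paired
two-tailed t test, pairing at the technical-repeat level, and between-group
contrasts (tumor vs normal at fixed temperature) by Welch's unequal-variance
t test. Every subset of the three parameters is then combined per contrast
with Fisher's method, $\chi^2 = -2\sum_i \ln p_i$ on $2m$ degrees of
freedom, giving a 7-set × 4-contrast grid per preparation. Combined cells
are always derived from the table's own single-parameter cells, never
recomputed from raw data. Significance labels use the standard bands with
strict upper bounds (`***` < 0.001 ≤ `**` < 0.01 ≤ `*` < 0.05 ≤ `ns`);
boundary values fall in the less significant band since the source's
footnote uses strict inequalities on both ends. No multiple-testing
correction is applied — the reference analysis reports raw p-values and
Fisher combinations only.

Two honest caveats about what the synthetic cohort can and cannot show:

* **Summary-input mode is the reproduction path for the published combined
  probabilities.** `combine_pvalue_table(published_single_parameter_pvalues())`
  regenerates all sixteen published combined cells to within rounding of the
  printed inputs. The published *single-parameter* p-values themselves are
  not reproducible without the unpublished raw data.
* **Repeat-level pairing on clustered repeats is anticonservative.** Because
  generated repeats are correlated within a block, treating the 12 repeats
  of a group as independent pairs overstates within-group significance
  (pseudo-replication) — so on synthetic cohorts the normal-group
  temperature contrasts often reach nominal significance where the published
  table shows `ns`. The generator reproduces the *ordering* (tumor
  temperature contrasts far more significant than normal ones, between-group
  contrasts strongest), which is what the property tests assert. The type-I
  calibration of the tests themselves is verified separately on a null
  cohort with independent repeats.

Pairwise linear regressions between the three markers (R² of ordinary least
squares) quantify their mutual independence; low R² values justify combining
them. The package computes the R² grid per group with both preparations
pooled (the reference scatter analysis does not separate them).

## The classification rule

`classify_sample()` implements the bimodal rule that needs no paired normal
tissue: a specimen is called a tumor when the 25→37 °C increase in **both**
$\rho_B$ and $\rho_S$ across its technical repeats is significant (paired t,
$\alpha = 0.05$) **and** both fold changes exceed a threshold, default 3.8 —
the midpoint between the published tumor fold range (about 4.1–4.8) and the
normal range (about 2.9–3.5), chosen from those printed group ratios alone
and not fitted to data. Both $\alpha$ and the threshold are arguments.

Under the generator's study conditions the per-specimen fold distributions
are wide (the SEM-scaled spreads imply block-level fold SDs of roughly
0.5–0.8 on the log scale) and genuinely overlap the threshold, so the rule
has moderate sensitivity with high specificity; the Monte-Carlo in the test
suite quantifies this at the default settings. A rule with >90% sensitivity
at this threshold would require the fold distributions to be far tighter
than the published spreads allow.

## The trench conduction study

`chip_cross_section()` and `solve_steady()` reproduce, at desk scale, the
qualitative effect of the chip's thermal isolation trench: a 2-D vertical
cross-section of the 500 µm silicon substrate (4 mm wide at 20 µm node
spacing, ~5,200 nodes), capped by a one-node layer for the thin oxide film
(1.3 W m$^{-1}$ K$^{-1}$), with a central surface heater and air-filled
trenches of the fabricated 350 µm depth flanking it. Trench width (100 µm)
and offset (600 µm) are not published and are configurable; a deep-etched
isolation trench of order 100 µm width is typical. The chip underside and
far edges are Dirichlet boundaries at ambient; convective boundaries are
omitted (no coefficients are published). The discretisation uses
harmonic-mean interface conductances on a uniform 5-point stencil, and the
system is solved directly (sparse Cholesky), so the residual is at rounding
level and the discrete energy balance closes to well under 0.1%.
`power_for_target()` brackets and bisects the injected power until the mean
heater-node temperature reaches the target (the problem is linear in the
source, so the iteration is cheap and monotone).

The solver is verified against a 1-D analytic slab, a dense independently
assembled linear system, the discrete maximum principle, linearity in the
source, and flux conservation. Both published directions reproduce on the
default geometry: the trench lowers the power needed to reach a given heater
temperature and lowers the temperature SD over the surface region inside
the trench ring. No quantitative match to the original finite-element study
is attempted — its mesh, material stack and boundary data are unpublished.

## Numerical and interface choices

* Degenerate statistics are explicit: zero-variance paired differences give
  $p = 1$ when all differences are zero and $p = 0$ (unbounded statistic)
  when they are constant but nonzero; Fisher's method rejects $p \le 0$ or
  $p > 1$; a single p-value combines to itself.
* Estimators raise typed errors on nonpositive resistances, powers or
  gradients ("no gradient" when $\Delta T \le 0$); profile construction
  flags a missing observable as `NA` at that setpoint and still computes the
  remaining parameters; with fewer than three valid RTDs the sink
  temperature falls back to the mean of the valid ones with a warning.
* Measurement tables are strict-schema CSV (exact header, '.' decimals) with
  `#` provenance comments (package version, seed, config hash); malformed
  rows are rejected by file line number, valid rows survive. YAML run
  configurations reject unknown keys.
* Problem sizes in the test suite are chosen for desk-scale runtimes: type-I
  calibration uses $10^4$ null replicates per test, the Fisher null
  uniformity check $10^5$ combinations, recovery checks 100 noiseless and 24
  noisy samples, and classification operating characteristics 480 simulated
  specimens.

## Known limitations

* The generator emulates group-level structure, not tissue physics: no
  contact-resistance, anisotropy, transient thermal response, or
  frequency-dependent impedance. Passing recovery tests show the estimators
  invert the stated forward model, not that the forward model captures every
  systematic error of a real instrument.
* Between-endpoint correlation (0.8) and within-block repeat CV (0.15) are
  assumptions stated here, not published values; delineation significance on
  synthetic cohorts shifts with both.
* The published single-parameter p-values cannot be checked directly
  (no raw data); only their Fisher combinations are reproduced, from the
  printed values.
* The trench model is 2-D and qualitative; absolute powers depend on the
  assumed out-of-plane thickness.

## A worked run

```{r, eval = FALSE}
cfg <- study_config(seed = 1)
out <- run_pipeline(cfg, out_dir = "results")
print(out$delineation)
classify_sample(out$profiles[out$profiles$patient_id == "FF1" &
                               out$profiles$group == "tumor", ])
```
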