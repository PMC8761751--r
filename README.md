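# electrotherm

Simulation and analysis pipeline for **microchip-based electrothermal
phenotyping of ex vivo breast biopsy tissue** — a label-free route to
delineating tumor from adjacent normal tissue for pathology labs and
surgical-margin workflows, where frozen-section histology costs 30 minutes
to 2 hours per sample.

A silicon microchip carrying a platinum microheater, concentric
interdigitated electrodes (IDEs) and resistance temperature detectors
(RTDs) is pressed against both faces of a cubical biopsy block
(5 × 5 × 3 mm) while the tissue is heated from 25 to 37 °C in 3 °C steps.
Three scalar markers are inverted from the raw electrical record at each
temperature:

| marker | estimator | units |
|---|---|---|
| bulk resistivity | ρ_B = R_B · A / l | Ω·cm |
| surface (sheet) resistivity | ρ_S = 2π/ln(D₂/D₁) · R_s = 84.8 · R_s | Ω/□ |
| thermal conductivity | k = Q · l / (A_c · ΔT) | W·m⁻¹·K⁻¹ |

where `R_B` and `R_s` are the measured bulk and surface resistances, `l`
the tissue thickness, `A` the electrode area, `D₁ = 130 µm` and
`D₂ = 140 µm` the concentric IDE diameters, `Q = V·I` the heater power and
`ΔT` the steady temperature drop from the heated face to the RTD-triangulated
sink face (ex vivo, the tissue bioheat equation reduces to steady
conduction, which makes the one-dimensional balance exact). Tumor tissue
shows a much larger temperature-driven rise in ρ_B and ρ_S than normal
tissue (fold changes ≈ 4.1–4.8 vs ≈ 2.9–3.5) and a lower k; combining all
three markers with Fisher's probability combination gives the sharpest
delineation.

The package provides, as separately testable modules:

* **chip model** — chip geometry, the IDE geometric factor, the linear RTD
  calibration (TCR 2.2 × 10⁻³ °C⁻¹) and heater power;
* **synthetic cohort generator** — reproduces the reference study design
  (8 patients, deparaffinized and formalin-fixed arms, paired tumor/normal
  blocks, 3 technical repeats, 48 samples × 5 setpoints) with hierarchical
  lognormal variability moment-matched to the published group table, and
  forward-simulates every raw observable with configurable noise;
* **inference** — inverts raw records to per-sample profiles of ρ_B(T),
  ρ_S(T), k(T); a noiseless round trip recovers ground truth to < 10⁻⁹;
* **delineation statistics** — paired and Welch t tests, fold changes,
  Fisher combination over all parameter subsets, significance labelling,
  pairwise regression R², and a bimodal tumor/normal classification rule;
* **trench solver** — a 2-D finite-difference steady conduction model of
  the chip cross-section showing the effect of the 350 µm thermal isolation
  trench;
* **pipeline and I/O** — strict-schema CSV with provenance headers, YAML
  run configuration, and `run_pipeline()` tying simulate → infer →
  delineate → report together deterministically.

## Worked example

```r
library(electrotherm)

cfg <- study_config(seed = 1)        # default: the full 48-sample design
out <- run_pipeline(cfg, out_dir = "results")

cells <- out$delineation$cells
cells[cells$parameter_set == "rho_b+rho_s+k", ]
```

```
     preparation parameter_set   contrast  p_value label
1 deparaffinized rho_b+rho_s+k N37_vs_N25 1.54e-05   ***
2 deparaffinized rho_b+rho_s+k T25_vs_N25 1.33e-10   ***
3 deparaffinized rho_b+rho_s+k T37_vs_N37 3.63e-15   ***
4 deparaffinized rho_b+rho_s+k T37_vs_T25 1.11e-14   ***
5 formalin_fixed rho_b+rho_s+k N37_vs_N25 1.29e-05   ***
6 formalin_fixed rho_b+rho_s+k T25_vs_N25 1.28e-07   ***
7 formalin_fixed rho_b+rho_s+k T37_vs_N37 2.05e-16   ***
8 formalin_fixed rho_b+rho_s+k T37_vs_T25 3.75e-16   ***
```

Each row is the Fisher combination of the three single-marker p-values for
one contrast (`T`/`N` = tumor/normal, subscript = temperature): tumor versus
normal at 37 °C is the strongest contrast in both preparation arms, and the
tumor temperature contrast dominates the normal one by many orders of
magnitude — the delineation signal the method is built on.

Classifying one simulated formalin-fixed tumor specimen from its three
technical repeats, without using its paired normal tissue:

```r
ff3 <- out$profiles[out$profiles$patient_id == "FF3" &
                      out$profiles$group == "tumor", ]
classify_sample(ff3)
```

```
$call
[1] "tumor"

$evidence
  parameter p_value  fold
1     rho_b 0.00450  6.84
2     rho_s 0.00457 25.80
```

Both resistivities rose significantly from 25 to 37 °C with fold changes
above the 3.8 threshold, so the specimen is called a tumor.

The published combined probabilities are reproduced directly from the
published single-parameter p-values (no raw data needed):

```r
pub <- combine_pvalue_table(published_single_parameter_pvalues())
pub[pub$parameter_set == "rho_b+rho_s+k" & pub$contrast == "T37_vs_N37", ]
```

```
  preparation    parameter_set contrast   p_value  label
1 deparaffinized rho_b+rho_s+k T37_vs_N37 6.76e-06 ***
2 formalin_fixed rho_b+rho_s+k T37_vs_N37 1.95e-07 ***
```

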