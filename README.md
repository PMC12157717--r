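# suprafit

Quantitative thermodynamics of ion-pair binding by heteroditopic hosts in
nonaqueous solvents.

Receptors that bind a cation and an anion simultaneously (for example
ureido-amide calix[4]arenes binding NaCl, NaHSO4 or NaH2PO4 in
acetonitrile) pose a coupled-equilibria problem: the stability constant of
the ternary complex CHA can only be determined if the side processes —
cation binding (H + C⁺ ⇌ CH⁺), binary anion binding (H + A⁻ ⇌ HA⁻),
free-ion pairing (C⁺ + A⁻ ⇌ CA), anion dimerization (2 A⁻ ⇌ A₂²⁻) and salt
precipitation (CA(s) ⇌ C⁺ + A⁻, governed by the solubility product
K_s = [C⁺][A⁻]) — are characterized and included in the model.  `suprafit`
implements that entire workflow for users of potentiometric (Na-ISE),
conductometric, calorimetric (ITC), UV spectrophotometric and
fast-exchange ¹H NMR titrations:

* a general **speciation solver** (damped Newton in log-concentration
  space, active-set handling of solid phases with saturation
  complementarity), plus an independent brute-force verifier for
  one-unknown models;
* **closed-form salt models** for saturated solutions: the
  pure-solution relation `s = √Ks + Ks·K_IP`, the common-ion expression
  `s(c) = ½(2·Ks·K_IP − c + √(c² + 4Ks))`, the two-regime free-cation
  expressions before/after the precipitation onset, and the cubic/sextic
  forms for dimerizing anions — with least-squares fitters for the four
  experimental protocols built on them (common-ion solubility series and
  two-regime pNa titrations, with or without anion dimerization);
* **forward models and fitters per technique**, with unknown spectra,
  chemical shifts or reaction enthalpies profiled out linearly at each
  iterate (variable projection) and known parameters frozen;
* a three-level **binding-model ladder** (M1 "inseparable titrand",
  M2 explicit cation binding, M3 full model) with cooperativity factors
  α = K(CHA|succ)/K(HA⁻) and bias reports across levels;
* **synthetic-data generators** for every experiment type with known
  ground truth and seeded noise, so the whole pipeline is testable end to
  end;
* **coordination analysis of labelled 3-D structure frames**: discrete
  Na/Cl/hydrogen-bond coordination matrices, solvent-inclusion classes,
  signature-based clustering with populations, and PCA-based
  representative-structure selection; multi-frame XYZ/PDB input with a
  YAML role map.

## Worked example

Simulate a noise-free two-regime potentiometric titration of NaClO4 with
TEACl for an NaCl-like salt (log Ks = −8.7, K_IP = 7.7e3) and refit it:

```r
library(suprafit)
p  <- scenario_preset("NaCl", quiet = TRUE)
ds <- generate("potentiometric", p)
fit <- fit_method_B(potentiometric_fit_data(ds))
fit$params
#> $Ks    2e-09
#> $s     6.012136e-05
#> $K_IP  7700
```

The fitter recovers the generating solubility product
(Ks = 2.0e-9 mol² dm⁻⁶, i.e. log Ks = −8.7), the total solubility
(6.0e-5 mol dm⁻³) and the ion-pairing constant (7.7e3 mol⁻¹ dm³) from the
pNa curve alone, identifying the precipitation onset automatically.

Fit a full-model UV titration of the cation-preloaded host under the
three model levels and quantify cooperativity:

```r
ds_uv <- generate("uv", "NaCl")
model_ladder_report(ds_uv)
#>    level     logK        K pct_vs_M3
#> M1    M1 3.285499 1929.741  3.633204
#> M2    M2 3.285841 1931.260  3.714810
#> M3    M3 3.270000 1862.087  0.000000
cooperativity(3.27, ds_uv$truth$logK_HA)
#> $alpha 10   $classification "positive"
```

The full model (M3) recovers the generating successive constant
log K = 3.27 exactly; the simplified levels over-estimate it slightly
(the inseparable-titrand treatment inflates K for this weakly pairing
system), and the tenfold ratio of the ternary to the binary anion-binding
constant classifies the cation effect as positive cooperativity.

Classify structure frames into coordination clusters:

```r
frames <- c(generate_frames(list(Cl = c(4, 2, 2)), n_frames = 97),
            generate_frames(list(Cl = c(2, 2, 0)), n_frames = 3))
cluster_frames(frames)[, 1:3]
#>                  signature  n population_pct
#> 1 Cl(4,2,2)|HB(0,0,0)|none 97             97
#> 2 Cl(2,2,0)|HB(0,0,0)|none  3              3
```

A thin command-line front end over the same functions is installed at
`inst/scripts/suprafit.R` (subcommands `speciate`, `simulate`, `fit`,
`ladder`, `mdcoord`).

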