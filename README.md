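# cocrysol

Thermodynamic prediction of pharmaceutical cocrystal solubility in
solvent/anti-solvent mixtures.

Cocrystals — crystalline solids combining an active pharmaceutical
ingredient (API) with a coformer (CF) in fixed stoichiometry — are
usually produced by crystallization from solution, often by adding an
anti-solvent. Whether that works for a given solvent pair depends on the
ternary phase diagram: the solubility lines of the API solid, the CF
solid and the cocrystal, and the eutectic points where they meet. This
package computes those diagrams for the nicotinamide (NA) / succinic
acid (SA) 2:1 cocrystal in ethanol/water, ethanol/acetonitrile and
ethanol/ethyl acetate mixtures, entirely from a thermodynamic model:

* **PC-SAFT** (perturbed-chain statistical associating fluid theory)
  supplies activity coefficients `γᵢ` from hard-chain, dispersion and
  Wertheim association contributions to the residual Helmholtz energy,
  with Berthelot–Lorentz/Wolbach–Sandler combining rules and
  temperature-linear binary corrections `kᵢⱼ(T) = kᵢⱼ,slope·T + kᵢⱼ,int`.
* **Solid–liquid equilibrium** of each single solute:
  `xᵢγᵢ = exp[−Δh₀ᵢ/(RT)(1−T/T₀ᵢ) − Δc_P,₀ᵢ/R(T₀ᵢ/T−1−ln(T₀ᵢ/T))]`.
* **The cocrystal solubility product**
  `K_s = (x_API γ_API)^ν_API (x_CF γ_CF)^ν_CF`, solvent- and
  concentration-independent, fixed by one aqueous saturation point
  (`3.70·10⁻⁷` at 298.15 K) and scaled in temperature by
  Gibbs–Helmholtz with `Δh_s^ref = 64.75 kJ/mol`.

A typed parameter database (melting properties, PC-SAFT pure-component
and binary parameters, cocrystal definition) ships with the package;
fitting routines estimate `kᵢⱼ(T)` and `K_s` from saturation data, the
`ard()` metric scores correlations, and a seeded synthetic-data
generator emulates saturation experiments with multiplicative lognormal
noise so the whole pipeline is testable without laboratory data.

## Worked example

```r
library(cocrysol)
db <- load_parameter_db()          # packaged NA/SA/solvent parameters

# saturation of nicotinamide in a 0.5/0.5 (w/w) ethanol/water mixture
solve_solubility("NA", c(ethanol = 0.5, water = 0.5), 298.15, db)
#> <solubility_point> NA in ethanol:0.5,water:0.5 at 298.15 K
#>   x = 0.0394672  gamma = 0.881748  (ideal 0.0348001)  [converged]

# the mixture dissolves more NA (x = 0.0395) than the ideal law
# predicts (0.0348) because gamma < 1: the mixed solvent stabilizes NA

# solubility product scaled from 298.15 K to 310.15 K
cc <- db$cocrystals[[1]]
ks_at_temperature(cc, 310.15)
#> [1] 1.016541e-06

# fully predictive cocrystal solubility line in the same mixture
line <- cc_solubility_line(cc, c(ethanol = 0.5, water = 0.5), 298.15,
                           db, ratio_grid = c(1, 2, 4))
as.data.frame(line)
#>     x_api     x_cf gamma_api gamma_cf ratio
#> 1 0.01726 0.017260    0.9416  0.08117     1
#> 2 0.02264 0.011322    0.9278  0.07404     2
#> 3 0.02954 0.007386    0.9080  0.06961     4
```

Each row is a liquid composition in equilibrium with the cocrystal
solid at the given API/CF mole ratio; every row reproduces
`(x_api·γ_api)²(x_cf·γ_cf) = K_s = 3.70·10⁻⁷`.

`build_phase_diagram()` assembles the full ternary diagram (three
branches clipped at their eutectics); `fit_kij()` / `fit_ks()` estimate
parameters from saturation datasets; `generate_binary_solubility()` /
`generate_cc_dataset()` create seeded synthetic datasets;
`reproduce_tables()` turns any dataset into the assembled
ARD-by-system report.

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

| script | what it computes |
|---|---|
| `01_pure_solvent_solubility.R` | NA and SA saturation in the four pure (anti-)solvents |
| `02_mixture_solubility_lines.R` | solubility vs. solvent ratio; the interior maximum in ethanol/ethyl acetate |
| `03_phase_diagrams.R` | predictive ternary diagrams and eutectics for five solvent systems at two temperatures |
| `04_synthetic_recovery.R` | parameter recovery and the assembled reproduction report on synthetic data |

## Scope

Stoichiometry (2:1) and the identities of the stable solid phases are
inputs, not predictions; there is no vapor–liquid equilibrium, no
solvate/polymorph handling, and no pure-component parameter estimation.
See the methods vignette (`vignettes/cocrystal-solubility-modeling.Rmd`)
for the model details, numerical choices and known limitations.
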