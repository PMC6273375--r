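---
title: "Modeling cocrystal solubility in solvent/anti-solvent mixtures"
author: "cocrysol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cocrystal solubility in solvent/anti-solvent mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pharmaceutical cocrystals — crystalline solids holding an active
ingredient (API) and a coformer (CF) in fixed stoichiometry — dissociate
into their components on dissolution. Designing an anti-solvent
crystallization for a cocrystal therefore requires the full ternary
phase diagram: the solubility lines of the API solid, the CF solid, and
the cocrystal, in every candidate solvent/anti-solvent mixture. Measuring
those diagrams is slow and expensive; this package predicts them from a
thermodynamic model, taking the nicotinamide (NA) / succinic acid (SA)
2:1 cocrystal in ethanol/water, ethanol/acetonitrile and ethanol/ethyl
acetate as the worked system.

## The model

Three pieces combine:

**Solid–liquid equilibrium of a single solute.** A pure crystalline
solid in equilibrium with the liquid satisfies

$$x_i^L = \frac{1}{\gamma_i^L}\exp\!\left[-\frac{\Delta h_{0i}^{SL}}{RT}
\Bigl(1-\frac{T}{T_{0i}^{SL}}\Bigr)
- \frac{\Delta c_{P,0i}^{SL}}{R}\Bigl(\frac{T_{0i}^{SL}}{T}-1
- \ln\frac{T_{0i}^{SL}}{T}\Bigr)\right]$$

with melting temperature $T_{0i}^{SL}$, fusion enthalpy
$\Delta h_{0i}^{SL}$ (treated as temperature-independent, as is
conventional over such narrow ranges) and the heat-capacity difference
$\Delta c_{P,0i}^{SL}$. The right-hand exponential is the *ideal*
solubility — solvent-independent; every solvent effect enters through the
activity coefficient $\gamma_i^L$ (`ideal_solubility()`,
`solve_solubility()`).

**The cocrystal solubility product.** The cocrystal itself never exists
in solution, so its equilibrium is a dissociation constant,

$$K_s = \prod_i a_i^{\nu_i} = (x_{API}\gamma_{API})^{\nu_{API}}
(x_{CF}\gamma_{CF})^{\nu_{CF}},$$

which depends on temperature only — not on the solvent and not on the
concentration. One saturation point in *any* solvent fixes $K_s$; the
packaged value ($3.70\times10^{-7}$ at 298.15 K) derives from an aqueous
reference point. Temperature scaling follows Gibbs–Helmholtz,
$\ln K_s(T) = \ln K_s^{ref} + (\Delta h_s^{ref}/R)(1/T^{ref}-1/T)$ with
$\Delta h_s^{ref} = 64.75$ kJ/mol held constant
(`ks_at_temperature()`). Neglecting the activity coefficients gives the
popular but solvent-specific $K_s^{ideal} = \prod_i x_i^{\nu_i}$
(`ks_ideal_from_point()`), retained only for comparison.

**PC-SAFT activity coefficients.** All $\gamma_i$ come from the
perturbed-chain statistical associating fluid theory, the residual
Helmholtz energy summing hard-chain, dispersion and association
contributions. Pure components carry segment number $m_i$, segment
diameter $\sigma_i$, dispersion energy $u_i/k_B$, and — for hydrogen
bonders — association energy $\varepsilon^{A_iB_i}/k_B$ and volume
$\kappa^{A_iB_i}$. Mixtures use Berthelot–Lorentz combining rules with a
temperature-linear correction $k_{ij}(T) = k_{ij,slope}T + k_{ij,int}$
on the cross dispersion energy, and Wolbach–Sandler rules for
cross-association. Polar but non-self-associating solvents (ethyl
acetate, acetonitrile) follow the induced-association convention:
$\varepsilon^{A_iB_i}=0$, $\kappa^{A_iB_i}=0.01$, so they cross-bond
with true associators but never with themselves (the cross energy, an
arithmetic mean, vanishes only when both partners are induced).

Activity coefficients use the symmetric convention
$\gamma_i = \varphi_i(T,p,x)/\varphi_i^{0L}(T,p)$ with fugacity
coefficients from residual chemical potentials at the liquid density
root. Solid solutes below their melting point use the subcooled-liquid
root of the equation of state as reference, with no extra
stabilization.

## Implementation choices

Where the underlying publications leave the numerics open, the package
makes these choices:

* **Working equations.** The hard-chain, dispersion (universal power
  series and compressibility correction) and Wertheim association terms
  follow the original perturbed-chain SAFT formulation; the association
  strength uses
  $\Delta^{A_iB_j} = \sigma_{ij}^3\, g_{ij}^{hs}\, \kappa^{A_iB_j}
  [\exp(\varepsilon^{A_iB_j}/k_BT)-1]$.
* **Site inventories.** Association scheme "1/1" (water, ethanol) means
  one donor plus one acceptor site; "2/2" (NA, SA) means two of each,
  following the usual donor/acceptor reading of these scheme labels.
  Donor–donor and acceptor–acceptor bonds carry zero strength.
* **Analytic derivatives.** Chemical potentials come from hand-coded
  analytic composition derivatives of the residual Helmholtz energy
  (association handled by the envelope theorem on the Michelsen
  Q-function); the test suite checks them against central finite
  differences to 1e-6 relative.
* **Association fixed point.** Damped successive substitution (damping
  0.5, tolerance 1e-12, at most 500 iterations), warm-started across
  density iterations.
* **Density solver.** Pressure-explicit root find on the packing
  fraction with a liquid-branch Newton shortcut from $\eta_0 = 0.45$
  and a full bracketing scan over $(10^{-10}, 0.7405)$ as fallback;
  converged roots satisfy the pressure to 1e-9 relative, and the liquid
  hint selects the largest mechanically stable root.
* **Pressure.** All liquid-phase work is at 101325 Pa. The original
  study does not state its pressure; liquid activity coefficients are
  insensitive to it, and the choice is asserted nowhere else.
* **Saturation solver.** `solve_solubility()` solves the equilibrium
  condition by bracketed Brent iteration on $\ln x$ rather than damped
  fixed-point substitution: for strongly composition-dependent
  $\gamma$ (NA in water) the fixed point contracts slowly, while the
  bracketed root find needs fewer equation-of-state evaluations and
  cannot diverge. Convergence is to 1e-10 on $\ln x$. A missing root
  below full miscibility is reported as `fully_miscible`, not an error.
* **Cocrystal lines.** Parameterized by the solute mole ratio
  $r = x_{API}/x_{CF}$ on a logarithmic grid; each node solves a scalar
  root problem in $\ln s$ (the common concentration scale) to 1e-10 on
  the log-residual. Stability assignment uses line-crossing logic — the
  eutectic kink — rather than a full Gibbs-energy minimization,
  matching how such diagrams are conventionally presented.
* **Eutectics.** Seeded from the discrete crossing of the two parent
  lines (using their stored activity coefficients, at no extra model
  evaluations) and refined by a damped two-dimensional Newton iteration
  in $(\ln x_{API}, \ln x_{CF})$; both equilibrium residuals close
  below 1e-6. Two lines that do not cross in the sampled region report
  an absent eutectic rather than failing.
* **Fitting.** $k_{ij}$ estimation minimizes squared deviations in
  $\ln x$ — solubilities span orders of magnitude and accuracy is
  judged as relative deviation, so a log loss is the natural choice.
  The smooth two-parameter least squares is solved by
  Levenberg–Marquardt with multiple starts (a derivative-free simplex
  needs an order of magnitude more model evaluations here for no
  robustness gain); standard errors come from the finite-difference
  Jacobian at the optimum. Datasets at a single temperature fit the
  intercept only, with the slope fixed at zero. Cocrystal deviation
  tables are evaluation-only: the solubility product is never refit per
  solvent.
* **Units.** Fusion enthalpies are stored in kJ/mol and converted to
  J/mol at exactly one site (`ideal_solubility()`); temperatures are
  always kelvin; $R = 8.314$ J/(mol K).

## The synthetic-data generator

No raw experimental saturation tables ship with the package, so
validation runs on synthetic datasets that emulate the measurement
design of the original study: saturation points over temperature and
solute-free solvent-ratio grids, replicated, with multiplicative
lognormal noise $x_{obs} = x_{model}e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma_{rel}^2)$. The default
$\sigma_{rel} = 0.02$ mirrors the ~2% precision of triplicate
gravimetric/photometric concentration measurements; the lognormal form
matches the relative-error structure of the ARD metric and keeps
synthetic solubilities positive across their decades-wide range. A
single seed fixes the full stream (temperature-major, then solvent
ratio, then replicate; for cocrystal records the API draw precedes the
CF draw).

What passing these tests shows — and does not show: the generator
samples from the model itself, so zero-noise round trips certify the
*internal* consistency of the solver/fit/report pipeline, and noisy
round trips certify its statistical calibration. They cannot certify
agreement with laboratory data; that comparison needs a transcription
of the original saturation tables, which `reproduce_tables()` accepts
in the same CSV schema whenever one is available. The generator also
makes no attempt to emulate analytical-chemistry artifacts (evaporation
losses, calibration drift).

## Problem sizes and determinism

The shipped tests and the acceptance script use deliberately small
designs — lines of 10–40 nodes, fits over eight temperatures, a few
hundred noise replicates — chosen so the full validation battery
completes in minutes while every assertion retains a comfortable
margin. All stochastic steps are seeded; reruns are bit-identical.

## Known limitations

* The published parameter tables, not spectroscopic or pρT data, are
  the only parameter source; no new pure-component parameters are
  estimated here.
* Constant solvent/solvent $k_{ij}$ values are applied at all
  temperatures although they were regressed at other temperatures
  (343 K and similar) — deliberately mirroring the original usage.
* No vapor–liquid equilibrium, polar/ion terms, solvate or polymorph
  equilibria, or prediction of feasible stoichiometries: the 2:1
  stoichiometry and the identities of the stable solids are inputs.
* PC-SAFT with these parameters is approximate for liquid densities
  (water is reproduced to well under 1%, ethanol to about 1%); the
  tests assert only coarse realism bounds on density, and accuracy
  claims concern saturation compositions.
* Eutectic location assumes the sampled line segments cross at most
  once in the region of interest, which holds for the diagrams treated
  here.
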