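---
title: "Dissecting P450 regioselectivity with modified Arrhenius analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting P450 regioselectivity with modified Arrhenius analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p450thermo)
```

## The problem

Cytochrome P450 enzymes frequently oxidise a single substrate at several
sites of metabolism (SOMs), producing a mixture of regioisomeric
metabolites. What controls the product ratio? Three thermodynamically
distinct factors: the relative binding free energy of the catalytically
active substrate poses (ΔΔG~bind~), the relative activation energy of the
chemical steps (ΔE~a~), and the relative probability of forming the
transition state out of a bound pose — an entropic, "collision-efficiency"
term expressed through the pre-exponential factors A₁/A₂ of the Arrhenius
law.

A classic Arrhenius plot of a single P450 pathway — ln V~max~ against
1/T — is rarely informative. Steps other than the oxidation (reduction by
the redox partner, oxygen binding, protonation) can be rate limiting,
membrane fluidity and thermal denaturation bend the curve, and V~max~
cannot be converted to a k~cat~ per reactive pose because the
concentrations of the individual reactive enzyme–substrate poses are not
measurable. `fit_classic_arrhenius()` is therefore kept only as a
linearity *diagnostic*.

## The modified Arrhenius model

For two parallel pathways of the same enzyme the confounding factors are
shared, so they cancel in the ratio. Writing each pathway's maximal
velocity as V~max,i~ = k~cat,i~·[ES~i~]~max~ with the Arrhenius form
k~cat~ = A·e^−Ea/RT^ and a Boltzmann ratio of reactive pose populations,
[ES₁]~max~/[ES₂]~max~ = e^−ΔΔG~bind~/RT^, the ratio obeys

$$\ln\frac{V_{max,1}}{V_{max,2}} \;=\; \ln\frac{A_1}{A_2} \;-\;
  \frac{\Delta}{RT}, \qquad
  \Delta = \Delta\Delta G_{bind} + \Delta E_a .$$

A plot of ln(V~max,1~/V~max,2~) against 1000/T is therefore expected to be
*linear* even where the individual plots are not. Its slope (in K, per
10³/T unit) gives Δ = −slope × R × 10³, and its intercept is ln(A₁/A₂),
the relative collision efficiency — an entropic measure of how easily the
transition state is reached from the bound pose. The steady-state pose
ratio assumption behind the model requires either fast substrate
binding/unbinding or fast interconversion between reactive poses relative
to product formation; kinetic isotope effect ratios (`kie_ratio()`,
`kie_summary()`) are the package's hook for the experimental check used to
support that assumption (metabolic switching between pathways after
deuteration indicates that poses do interconvert).

Two complementary estimators close the loop:

* **Curtin–Hammett** (`curtin_hammett()`): at a single temperature the
  product ratio measures only the overall transition-state free-energy
  difference, ΔΔG~overall~ = −RT·ln(V~max,1~/V~max,2~).
* **Decomposition** (`decompose_selectivity()`): with an externally
  computed ΔE~a~ (SMARTCyp, DFT — inputs, never computed here),
  ΔΔG~bind~ = Δ − ΔE~a~; and treating the relative activation enthalpy as
  equal to ΔE~a~, the entropic part of the barrier is
  TΔΔS^≠^ = Δ − ΔΔG~overall~. The enthalpy≈energy approximation is carried
  in the output metadata rather than silently assumed.

All pairwise differences are pathway-1-minus-pathway-2, in kJ/mol, with
R = 8.3145 J mol⁻¹ K⁻¹.

## The pipeline

```{r pipeline, eval = FALSE}
params <- read_velocity_table("velocities.csv", temperature_unit = "C") |>
  fit_kinetics()

params |>
  build_ratio_series(c("3'-OH-MF", "4'-OH-MF")) |>
  fit_modified_arrhenius() |>
  glance()
```

Per-temperature Michaelis–Menten fits (`fit_michaelis_menten()`) use
damped (Levenberg–Marquardt) least squares with an analytic Jacobian.
Choices that matter:

* **Initialisation**: V~max,0~ = largest observed velocity, K~M,0~ = the
  concentration whose velocity is nearest half of V~max,0~ — essentially
  never outside the basin of attraction for saturation data.
* **Bounds**: both parameters constrained positive.
* **Convergence**: relative objective change < 1e-10, ≤ 500 iterations;
  non-convergence flags the fit instead of failing, and flagged fits
  should be excluded from ratio series.
* **Standard errors**: asymptotic, from the residual-variance-scaled
  inverse Gauss–Newton Hessian — the convention behind published ±
  values from common curve-fitting software.
* **Replicates are pooled** into one regression rather than averaged
  first, preserving degrees of freedom; the sources the package mirrors
  are silent on this, and pooling is the conservative choice.

The ratio series (`build_ratio_series()`) is always formed from fitted
V~max~ values, never raw velocities. Ordinate uncertainties come from
first-order (delta-method) propagation,
SE_y = √((SE₁/V₁)² + (SE₂/V₂)²); a Monte-Carlo check in the test suite
confirms the linearisation is accurate at the relative-error magnitudes of
the shipped data.

The modified Arrhenius regression is **unweighted OLS by default**:
recomputation shows that unweighted fits reproduce the published
mefenamic acid slopes and intercepts from the packaged parameter table
within their printed uncertainties, and the original analysis gives no
indication of weighting. Weighted fits (1/SE²) remain available via
`weighted = TRUE`. Two-point series are allowed for exploration but
flagged non-inferential, with SEs undefined. Temperatures are used exactly
as given in kelvin; 1000/T is never rounded.

Because OLS is linear in the ordinate and ln is a homomorphism of ratios,
two exact properties hold and are enforced by tests: *antisymmetry* (pair
swap negates slope, intercept and Δ) and *additivity* along metabolite
chains (slope(1,3) = slope(1,2) + slope(2,3) on a shared temperature
grid).

## Pose classification

The geometric near-attack criteria decide, per MD frame and per SOM,
whether the substrate is bound in a catalytically active pose:

| type | distance | angle |
|---|---|---|
| aromatic | C~SOM~–O~ferryl~ < 0.35 nm | C–H–O **not** within 140–220° |
| aliphatic | H~SOM~–O~ferryl~ < 0.35 nm | H–O–Fe within 110–130° |

Numerical conventions, stated because they decide boundary frames:
three-point angles live in [0°, 180°], so the 140–220° exclusion is
applied through the reflection 360° − θ — effectively θ ≥ 140°; distance
comparisons are strict (`<`), angle windows closed (inclusive). The
aromatic exclusion models hydrogen interposition: with the SOM hydrogen
directly between carbon and ferryl oxygen, C–H activation is blocked.
Internal units are nanometres; ångström input is accepted only with an
explicit declaration (×0.1), never inferred, and a frame missing a
required atom aborts the run rather than being skipped (silent skipping
would bias the active fractions). Several SOMs can be evaluated on the
same trajectory, and per-trajectory rows are never pooled silently.

The aromatic criterion involves no Fe-centred angle; none is added here.
Whether equilibration frames should be excluded is a question for the
caller: the classifier scores exactly the frames it is given.

## What the generators emulate — and what they do not

`simulate_kinetics()` runs the ratio model forwards:
V~max,i~(T) = env(T)·A~rel,i~·e^−G~eff,i~/RT^, Michaelis–Menten sampling at
the assay's concentrations, and multiplicative Gaussian noise
(CV-parameterised, truncated at −0.99 so velocities stay positive),
reflecting the roughly proportional standard errors of published kinetic
tables. Defaults are the study conditions the package targets: eight
temperatures from 277.0 to 317.6 K, seven substrate concentrations from
10 to 750 µM, triplicate observations, noise CV 0.05, and two pathways
separated by G~eff~ = 8.1 kJ/mol and ln A ratio = 3.0 — the scale of the
mefenamic acid 3′/4′ comparison. The shared envelope `bell_envelope()`
(peak 600 velocity units at 297 K, width 15 K, chosen to mimic the
observed rise-and-fall of absolute V~max~ across that range) models the
single-pathway nonlinearity *phenomenologically* rather than
mechanistically, because the physical causes are exactly the factors that
cancel in ratios; the test suite asserts that cancellation for constant,
bell and step envelopes. The generator does not emulate substrate
inhibition, enzyme inactivation kinetics, correlated errors between
metabolites measured in the same incubation, or temperature-dependent
K~M~ laws beyond per-pathway constants — so passing tests certify the
estimator under the stated error model, not robustness to those
violations.

`simulate_poses()` places atoms so that each frame satisfies or violates
each criterion with a safety margin (at least 0.03 nm in distance and 8°
in angle, and never less than three times the coordinate jitter) before
Gaussian jitter (default 0.002 nm) is added; each frame then receives a
random rigid rotation and translation. Active counts are exact —
round(n·target/100) frames, in seeded random order — so target fractions
are recovered exactly and classifier/label agreement is an honest oracle.
Real MD frames have no such margin: near-boundary geometries are common,
and the 100% agreement shown on synthetic data does not transfer to any
claim about classification stability on real trajectories. Published
per-simulation active-pose percentages require the original MD
trajectories and are therefore not reproducible from this package alone.

## Reference data and reference temperatures

The packaged mefenamic acid table (`mefenamic_params()`) is an exact
transcription of the published per-temperature kinetic parameters (eight
temperatures × three metabolites for the bacterial mutant BM3 M11, four ×
two for human CYP1A2; entries not applicable are absent, not zero). The ±
values are treated as standard errors of the fit, the reporting convention
of the software named in the source. Curtin–Hammett estimates use the
measured temperature nearest 300 K for the V~max~ pair and T = 300 K in
the formula; with the shipped data (nearest row 298.6 K) both conventions
round to the same published values, and both temperatures are recorded in
the output. Whether the published intercept uncertainties used plain OLS
formulas and whether ratios were formed from full-precision or rounded
V~max~ is unknowable from the source; plain OLS and full precision are
used, and agreement is checked against the printed ± ranges.

## Problem sizes and testing

The test suite regenerates everything it needs: velocity tables from the
generator, pose trajectories of 60–1000 frames, and a 200-replicate
calibration study (noise CV 0.05, triplicates) verifying that the
t-based 95% confidence interval for Δ covers the generating value in at
least 90% of runs — sizes chosen so the whole suite runs in well under a
minute while the Monte-Carlo assertions remain stable. The acceptance
script recomputes the published mefenamic acid regression and
Curtin–Hammett quantities from the packaged table in under a second.

## Limitations

* Only the hyperbolic Michaelis–Menten model is fitted — no substrate
  inhibition or Hill kinetics; enzyme concentration bookkeeping beyond
  normalised velocities is out of scope.
* Δ is a composite; splitting it requires an external ΔE~a~, whose
  accuracy bounds the accuracy of ΔΔG~bind~.
* TΔΔS^≠^ rests on the enthalpy≈energy approximation noted above.
* No segmented/breakpoint Arrhenius fitting: the ratio construction is
  designed to make membrane-transition discontinuities cancel instead.
* Binary MD trajectory formats are not read; convert to XYZ or the
  delimited frame layout first (`read_xyz_frames()` documents the hook).
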