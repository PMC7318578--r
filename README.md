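# p450thermo

Thermodynamic dissection of regio- and stereoselectivity in multi-product
enzyme catalysis, built for cytochrome P450 hydroxylation.

When one P450 isoform oxidises a substrate at several sites of metabolism,
the product ratio is set by three separable quantities: the relative
binding free energy of the catalytically active substrate poses
(ΔΔG<sub>bind</sub>), the relative activation energy of the oxidation
chemistry (ΔE<sub>a</sub>), and the relative collision efficiency
ln(A₁/A₂) — the entropic ease of reaching the transition state from a
bound pose. Classic Arrhenius plots of single pathways cannot separate
these (and for P450s are usually not even linear), but the ratio of two
parallel pathways of the *same* enzyme cancels every shared step:

```
ln(Vmax,1 / Vmax,2) = ln(A1/A2) − Δ/(RT),    Δ = ΔΔG_bind + ΔE_a
```

So the slope of ln(V<sub>max,1</sub>/V<sub>max,2</sub>) versus 1000/T
gives Δ = −slope·R·10³ (kJ/mol) and the intercept gives ln(A₁/A₂).
Combined with the Curtin–Hammett estimate
ΔΔG<sub>overall</sub> = −RT·ln(V<sub>max,1</sub>/V<sub>max,2</sub>) at a
single temperature and an externally computed ΔE<sub>a</sub> (e.g.
SMARTCyp), the package decomposes selectivity into
ΔΔG<sub>bind</sub> = Δ − ΔE<sub>a</sub> and
TΔΔS<sup>≠</sup> = Δ − ΔΔG<sub>overall</sub>.

The package covers the full workflow:

* **Kinetics** — `read_velocity_table()`, `fit_michaelis_menten()`,
  `fit_kinetics()`: per-temperature Michaelis–Menten fits by damped least
  squares with asymptotic standard errors.
* **Modified Arrhenius** — `build_ratio_series()`,
  `fit_modified_arrhenius()`, `fit_classic_arrhenius()` (diagnostic),
  `arrhenius_report()`; `tidy()`, `glance()` and `autoplot()` methods.
* **Thermodynamics** — `curtin_hammett()`, `curtin_hammett_from_params()`,
  `decompose_selectivity()`, `kie_ratio()`/`kie_summary()` for kinetic
  isotope effect checks of the fast-interconversion assumption.
* **Pose classification** — `som_definition()`, `pose_criteria()`,
  `classify_poses()`, `active_fraction()`: geometric near-attack criteria
  (distance < 0.35 nm; C–H–O angle outside 140–220° for aromatic SOMs,
  H–O–Fe within 110–130° for aliphatic) applied to MD-derived frames read
  with `read_pose_frames()` or `read_xyz_frames()`.
* **Synthetic data** — `simulate_kinetics()` and `simulate_poses()`
  generate datasets with known ground truth; `mefenamic_params()` ships a
  published per-temperature kinetic parameter table for mefenamic acid
  hydroxylation by P450 BM3 M11 and CYP1A2.
* **CLI** — `exec/p450thermo` with subcommands `fit-kinetics`,
  `arrhenius`, `curtin-hammett`, `decompose`, `classify-poses`,
  `simulate-kinetics`, `simulate-poses`, `fixtures`.

## Worked example

```r
library(p450thermo)

params <- mefenamic_params("BM3 M11")

fit <- params |>
  build_ratio_series(c("3'-OH-MF", "4'-OH-MF")) |>
  fit_modified_arrhenius()
fit
#> Modified Arrhenius fit: 3'-OH-MF vs 4'-OH-MF (8 points)
#>   slope     =  -0.968 +/- 0.074 K
#>   intercept =   2.937 +/- 0.250   (ln A1/A2)
#>   R^2       =   0.966
#>   Delta     =    8.05 +/- 0.62 kJ/mol

ch <- curtin_hammett_from_params(params, c("3'-OH-MF", "4'-OH-MF"))
decompose_selectivity(fit, ddG_overall = ch$ddG_overall,
                      dEa = -1.8, dEa_source = "SMARTCyp v2/v3")
#> # A tibble: 1 × 10
#>   metabolite_1 metabolite_2 delta ddG_overall   dEa ddG_bind  TddS reference_T
#>   <chr>        <chr>        <dbl>       <dbl> <dbl>    <dbl> <dbl>       <dbl>
#> 1 3'-OH-MF     4'-OH-MF      8.05       0.680  -1.8     9.85  7.37         300
```

Reading: 3′-methyl hydroxylation carries a composite penalty of
Δ ≈ 8.1 kJ/mol relative to 4′ hydroxylation, yet the overall barriers are
nearly equal (ΔΔG<sub>overall</sub> ≈ 0.7 kJ/mol). With
ΔE<sub>a</sub> ≈ −1.8 kJ/mol, the 4′ pose binds ~9.9 kJ/mol more
favourably, and that advantage is almost entirely repaid by the higher
collision efficiency — TΔΔS<sup>≠</sup> ≈ 7.4 kJ/mol, mirrored in the
positive intercept ln(A₁/A₂) ≈ 3 — of transition-state formation from the
3′-methyl pose.

The same analysis from the shell:

```sh
p450thermo arrhenius --fixture --enzyme "BM3 M11" \
  --pairs "3'-OH-MF,4'-OH-MF;3'-OH-MF,5-OH-MF;4'-OH-MF,5-OH-MF" \
  --curtin-hammett --out-dir results/
```

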