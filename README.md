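# alveodyn

3D morphometry of pulmonary gas-exchange units across the tidal cycle.

`alveodyn` is for researchers who image lung parenchyma at two respiratory
states (end-expiration at PEEP, end-inspiration at the inspiratory plateau
pressure) and want to quantify how alveoli and alveolar ducts share the
inhaled volume. It takes instance-labeled voxel volumes (duct lumen plus
per-alveolus lumina, micrometre spacing), or grayscale volumes that it
segments itself, and produces per-structure morphometry, paired-state
dynamics, and the statistical report layer. A synthetic phantom generator
with closed-form ground truth stands in for live-animal tomography and
backs every accuracy claim in the test suite.

## The model

For any closed shape, surface and volume are linked dimensionally by
`S = k V^(2/3)` with a dimensionless shape factor `k = S / V^(2/3)`
(cube: 6; sphere: `6^(2/3) π^(1/3) ≈ 4.8360`, the isoperimetric minimum).
Because `k` is scale-free, the ratio over a tidal cycle

```
q = k_insp / k_exp
```

isolates shape change from size change for a gas-exchange unit
(AAD = alveoli + duct): `q = 1` is balloon-like (geometrically similar)
expansion, `q > 1` alveolus-dominant deepening, `q < 1` duct-dominant
widening. Supporting measures: equivalent diameter `D_A = (6V/π)^(1/3)`;
thinnest septal wall `T_A`; membrane area strain
`ΔS = (S_insp − S_exp)/S_exp` with linear equivalent
`ε = (1 + ΔS)^(1/2) − 1`; entrance-ring strain `ε_ER` from the aperture
perimeter; and the inter-alveolar angle change `Δθ = θ_insp − θ_exp`,
whose sign diagnoses the expansion regime. Inference mirrors standard
practice: one-sample t-tests of `q` against 1 and `Δθ` against 0 (from
raw values or printed mean ± SEM and n), one-way ANOVA across pressure
groups with Welch pairwise post-hocs, mean ± SEM and five-number
summaries.

## A worked example

```r
library(alveodyn)

spec <- phantom_spec(deformation_mode = "alveolus_dominant",
                     duct_radius = 11, alveolar_radius = 9, n_alveoli = 5,
                     duct_volume_fraction = 0.5, noise_sd = 10,
                     placement_seed = 1)
unit <- generate_unit(spec)
res <- run_chain(unit, noise_seed = 1)

length(label_counts(res$labels_exp))
#> [1] 6
round(c(q = res$q, q_true = res$q_true), 4)
#>      q q_true
#> 1.0137 1.0149
round(mean(res$angles$d_theta), 2)
#> [1] -5.61
```

Six instances are the duct plus its five alveoli, recovered from the
noisy rendering by watershed splitting. The measured shape-change
statistic `q = 1.0137` recovers the generator's ground truth `1.0149`
within 0.12%, and `q > 1` with a negative mean angle change `Δθ ≈ −5.6°`
is exactly the alveolus-dominant signature: the alveoli deepen and draw
toward each other while the duct grows less. `summarize_experiment()`
turns dynamics tables from several pressure conditions into the
mean ± SEM summary, the one-sample tests and the ANOVA/post-hoc layer.

A thin command-line front end wraps the same functions
(`inst/scripts/alveodyn.R`, subcommands `phantom`, `segment`, `measure`,
`dynamics`, `report`).

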