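# afsmcr — area of feasible solutions for multivariate curve resolution

Spectroscopic series from titrations or reactions are bilinear: the
measured absorbance matrix `D` (k spectra × n channels) is the product
`D = C Sᵀ` of nonnegative concentration profiles `C` and pure component
spectra `S` (Beer's law). The factorization is found through a truncated
SVD, `D = U Σ Vᵀ`, with every candidate solution written as
`C = U Σ T⁻¹`, `S = V Tᵀ` for a regular transform `T` with all-ones first
column. The catch is *rotational ambiguity*: a continuum of transforms
gives chemically admissible (nonnegative) factor pairs.

`afsmcr` is for spectroscopists and chemometricians who want that
ambiguity made explicit instead of hidden behind a single solution. It

* computes the **area of feasible solutions (AFS)** — the set of all AFS
  points `x` (rows `(1, x)` of `T`) extendable to a fully nonnegative
  factorization — in closed form for two-component systems and by adaptive
  boundary tracing (a polygon-inflation-style algorithm with a compiled
  multi-start inner optimization) for three-component systems, on both the
  spectral and the concentrational side;
* reduces the ambiguity by **duality/complementarity**: a known pure
  spectrum at AFS point `x` confines the complementary components'
  concentration representations to the line `1 + x·y = 0`, and vice versa;
  `complete_factorization()` propagates known spectra/profiles to a unique
  factorization when the fixes suffice — and refuses when they do not;
* expresses remaining ambiguity as **bands of feasible profiles** and fixes
  absolute scales by the **closure** (mass-balance) constraint
  `c₁ + 2c₂ + c₃ = c₀`;
* validates decompositions by **rank annihilation** (two rank-1 downdates
  isolating the intermediate species) and by **kinetic hard-modeling** of
  the consecutive protonation → dimerization → splitting scheme along the
  added-acid axis, with `reldiff()` agreement metrics;
* ships a ground-truthed **synthetic titration generator** (12 × 401,
  200–600 nm, three species under closure) so the entire workflow is
  testable without measured data, plus a CLI (`exec/afsmcr`).

The feasibility test is ε-relaxed: a profile is admissible when its most
negative entry is ≥ −ε times its maximum absolute entry (default
ε = 2×10⁻⁴, acceptance δ = 10⁻⁴, boundary precision ε_b = 10⁻⁴). ε must
exceed the data's relative noise level or the AFS is empty — see the
methods vignette (`vignettes/afs-methods.Rmd`).

## Worked example

```r
library(afsmcr)

sim <- generate_dataset(synthetic_config())   # 12 x 401, noise 1e-4
sv  <- truncated_svd(sim$dataset, s = 3)
sv
#> Truncated SVD: s = 3 components, 12 conditions x 401 channels
#> Leading singular values: 18.061, 10.7045, 2.5129
#> Next singular value: 0.00212708
estimate_rank(sv$all_d)
#> [1] 3                                # three absorbing species

afs_S <- afs_three_component(sv, "spectral", feasibility_params())
afs_S
#> AFS region (spectral side): 3 subset(s)
#>   component_1: 89 vertices, area 0.0001175
#>   component_2: 110 vertices, area 0.02909
#>   component_3: 306 vertices, area 0.0006382
```

Three isolated subsets, one per species; the large one is the dimer, whose
spectrum is genuinely ambiguous, the tiny ones are the terminal species
pinned by the near-pure endpoint spectra. Fixing the endpoint rows of `D`
as pure spectra and the two terminal concentration profiles (the stand-ins
for fluorescence measurements) removes the ambiguity:

```r
D   <- sim$dataset$absorbance
fit <- complete_factorization(
  sv,
  fixed_spectra  = list(D[1, ], D[12, ]),
  fixed_profiles = list(sim$C_true[, 1], sim$C_true[, 3]))
fit
#> Completed factorization: 3 components, 12 conditions x 401 channels
#> Feasibility violation: 1.642e-08

# components return in fixed-input order (dye, protonated monomer, dimer);
# restore titration order so the dimer carries closure weight 2
C_titr <- fit$C[, c(1, 3, 2)]
scaled <- closure_scale(C_titr, closure_spec(c(1, 2, 1), sim$config$c0))
range(scaled$C %*% c(1, 2, 1))
#> [1] 0.00098423624 0.00098429871      # c0 = 9.84269e-4 mol/l recovered

ra <- middle_component_by_annihilation(
  sim$dataset, first_profile = sim$C_true[, 1],
  last_profile = sim$C_true[, 3])
ra
#> Rank annihilation: residual sigma2/sigma1 = 0.0008556
#> Most negative spectrum entry (unit-max scale): -0.0004627

kin <- fit_kinetics(scaled$C, sim$dataset$conditions, sim$config$c0)
kin
#> Kinetic fit: k1/k2 = 4000.55  (k1 = 23490000 , k2 = 16020 )  sse = 1.477e-14
reldiff(kin$C_kin, scaled$C, "max")
#> [1] 5.0e-05 1.27e-04 3.22e-05
```

The rank-annihilation residual is rank 1 up to noise (σ₂/σ₁ ≈ 9×10⁻⁴) and
the kinetic hard-model reproduces the recovered profiles to ~10⁻⁴ relative
error, with the identifiable rate ratio k₁/k₂ recovered to 0.01% (the
individual rates are a gauge choice in the added-acid formulation — see
the vignette).

The same pipeline is scriptable from a shell:

```sh
afsmcr simulate --noise 0 --out-dir run/
afsmcr svd --data run/dataset.csv --out-dir run/
afsmcr afs --data run/dataset.csv --side spectral --out-dir run/
afsmcr annihilate --data run/dataset.csv --c0 9.84269e-4 --out-dir run/
```

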