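---
title: "Resolving titration spectra with the area of feasible solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving titration spectra with the area of feasible solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afsmcr)
```

## The model and the ambiguity it leaves

A series of $k$ absorption spectra measured over $n$ wavelength channels
during a titration is collected in a matrix $D \in \mathbb{R}^{k \times n}$.
Beer's law in matrix form relates it to the $s$ pure components as

$$D = C S^T,$$

with concentration profiles in the columns of $C \in \mathbb{R}^{k\times s}$
and pure spectra in the columns of $S \in \mathbb{R}^{n\times s}$, all
nonnegative. The factors are computed through a truncated singular value
decomposition $D = U \Sigma V^T$: every rank-$s$ factorization can be
written as

$$C = U \Sigma T^{-1}, \qquad S = V T^T$$

for a regular $s \times s$ transform $T$ whose first column can be fixed to
the all-ones vector (each spectrum is scaled by its leading expansion
coefficient). This reduces the unknowns to the last $s-1$ entries of each
row of $T$, and exposes the central difficulty: many regular $T$ give
nonnegative pairs $(C, S)$ that reproduce $D$ equally well — rotational
ambiguity.

The **area of feasible solutions (AFS)** makes the ambiguity explicit. A
row $(1, x)$ of $T$, i.e. a point $x \in \mathbb{R}^{s-1}$, is *feasible*
when $T$ can be completed by some block $W$ so that both factors are
nonnegative. The AFS is the set of all feasible $x$; for a three-component
system it is a subset of the plane and, for well-posed data, splits into
$s$ isolated subsets — one per chemical component.

Measured (or truncated) data are never exactly nonnegative, so feasibility
is relaxed: a profile passes when its most negative entry is no smaller
than $-\varepsilon$ times its maximum absolute entry. The package scores a
transform by `feasibility_violation()`, the sum over the $2s$ profiles of
the squared shortfalls beyond $\varepsilon$, and accepts a point when the
minimized violation falls below $\delta^2$.

### Control parameters

| parameter | meaning | default |
|---|---|---|
| $\varepsilon$ | relative negativity tolerance per profile | $2\times10^{-4}$ |
| $\delta$ | feasibility acceptance: min violation $\le \delta^2$ | $10^{-4}$ |
| $\varepsilon_b$ | boundary precision of traced polygons (AFS units) | $10^{-4}$ |

$\varepsilon$ has a physical reading: it is an upper bound on the relative
magnitude of the negative entries that the factors are allowed to carry,
and therefore must exceed the relative size of the negative entries that
noise forces into the rank-$s$ truncation of $D$. This is a hard
consistency requirement, not a preference — if the truncated data contain
negative entries of, say, $10^{-3}$ relative while $\varepsilon =
2\times10^{-4}$, *no* $\varepsilon$-admissible pair $(C, S)$ can reproduce
them and the AFS is empty. The synthetic generator's default noise
($10^{-4}$ relative) is deliberately below the default $\varepsilon$;
enlarge $\varepsilon$ before analyzing noisier data. Increasing
$\varepsilon$ always (weakly) enlarges the AFS.

The denominator of the relative-negativity test is the maximum absolute
entry of the *same* profile (not of the whole factor). The test is then
invariant under the rescaling freedom of the factorization, which the
test suite asserts on random transforms.

## Computing the AFS

**Two components.** The AFS consists of two disjoint intervals available in
closed form from extreme ratios of singular-vector entries: candidate
spectra $V_{\cdot 1} + x V_{\cdot 2}$ must be nonnegative (outer bounds,
partitioned by the sign of $V_{j2}$), and the complementary concentration
profile, proportional to $(U\Sigma)_{\cdot 2} - x (U\Sigma)_{\cdot 1}$,
must be single-signed (inner bounds from the extreme ratios
$(U\Sigma)_{j2}/(U\Sigma)_{j1}$). For $\varepsilon > 0$ each endpoint is
pushed outward by bisection on the exact relaxed test to $\varepsilon_b$
precision. A brute-force scan over $10^4$ grid points cross-checks the
construction in the test suite.

**Three components.** `afs_three_component()` traces each subset's
boundary as a polygon:

1. *Seeding.* The normalized row coordinates of $U\Sigma$ (the data
   spectra's AFS images) are clustered into three groups; the cluster
   centers are inflated away from their centroid (an enclosing-triangle
   heuristic) and the resulting transform is refined by minimizing the
   total violation over all six free entries. Any transform with violation
   $\le \delta^2$ is a fully feasible factorization, so its three rows are
   interior points of the three subsets.
2. *Tracing.* From each seed, the boundary is located along rays by
   bisection between the feasible seed and an infeasible far point, to
   radial precision $\varepsilon_b$. Angular subdivision is adaptive: an
   arc is split while the midpoint boundary point deviates from the chord
   by more than $\varepsilon_b$ or the chord exceeds a spacing cap.
3. *Inner minimization.* Each feasibility query minimizes the violation
   over the four entries of $W$ by Nelder–Mead from a fixed multi-start
   set ($W = I$, $W = -I$, eight seeded random regular matrices) plus a
   warm start carried along the trace. The query exits early once the
   target $\delta^2$ is reached, and points whose *first* spectrum already
   violates the bound (a $W$-independent lower bound on the violation) are
   rejected without optimization. This inner loop is compiled (C++) —
   boundary tracing and the grid oracle evaluate it tens of thousands of
   times.

The radial trace assumes the subset is star-shaped as seen from its seed;
for strongly crescent-shaped subsets the polygon would be an inner
approximation. The independent cross-check is `afs_grid_oracle()`, which
evaluates the same feasibility test at every cell center of a regular grid
and must agree with the rasterized polygons up to boundary cells.

The concentrational AFS runs the identical machinery with the factor roles
swapped ($U \leftrightarrow V$); the resulting coordinates are converted
to the scaled-basis convention below.

## Duality between the factors

From $T^{-1} T = I_s$, a fixed spectrum at AFS point $x$ forces the
complementary components' concentration representations onto the affine
line

$$\{\, y : 1 + x_1 y_1 + x_2 y_2 = 0 \,\}$$

and symmetrically with the sides swapped. This holds *exactly* when
concentration-side AFS coordinates are defined as expansion coefficients
in the scaled basis $U\Sigma$ (equivalently: normalized columns of
$T^{-1}$), which is therefore the convention used on the concentration
side throughout the package; spectral coordinates are expansions in $V$.
The coordinate choice only rescales the two axes, and the package verifies
the incidence relation numerically (to $10^{-8}$ over seeded random
transforms) rather than trusting the algebra.

`complete_factorization()` turns known pure spectra and/or concentration
profiles into a full factorization: each fixed profile maps to its AFS
point, any two points on one side determine one point on the other side
through the intersection of their dual lines, and the propagation is
iterated to a fixed point. Counting degrees of freedom shows which fixes
suffice: two spectra plus two profiles (the canonical titration workflow:
endpoint spectra from the first and last measured rows, terminal-component
profiles from fluorescence) or three fixes on one side determine $T$; two
spectra plus one profile leave the middle component's spectrum on a line,
and the function refuses to guess. Inconsistent fixes (assembled violation
above $100\,\delta^2$) raise an error carrying the violation.

## Bands, closure, and validation

**Bands of feasible profiles.** The remaining ambiguity of one component
is summarized by reconstructing the profile of every sampled AFS point of
its subset (all boundary vertices plus seeded rejection-sampled interior
points) and taking pointwise envelopes. Profiles are normalized to unit
maximum first, since AFS points determine them only up to scale.

**Closure.** The titration obeys the mass balance
$c_1 + 2 c_2 + c_3 = c_0$ (the dimer binds two dye molecules).
`closure_scale()` finds the positive per-component scale factors that fit
the balance in least squares along the whole acid axis. When the design
matrix is ill-conditioned (condition number above $10^6$) one scale
direction is undetermined by the balance; the function then returns the
minimum-norm solution and raises an `ambiguous_scale` flag instead of
silently committing — the situation the dimer profile of a titration can
genuinely produce.

**Rank annihilation.** With pure endpoint rows, subtracting the two
terminal components as rank-1 terms leaves a residual carrying only the
intermediate. Two variants are implemented. With *known* terminal profiles
(e.g. fluorescence), the downdates are exact and the residual's leading
singular pair recovers both the dimer profile and its spectrum. Without
them, the downdate profiles come from regressing the rows of $D$ onto the
two fixed spectra; the residual is then exactly
$c_2 (s_2 - P s_2)^T$ with $P$ the orthogonal projector onto the fixed
spectra's span, so the *profile* is still exact but the *spectrum* carries
an oblique contamination $-P s_2$ — negative dips where the terminal
spectra absorb, the characteristic nonnegativity defect of rank
annihilation, reported as `min_negative`. The middle spectrum is
structurally unidentifiable from $(D, s_1, s_3)$ alone; the package
documents this rather than papering over it.

**Kinetic hard-modeling.** The consecutive scheme — protonation and
dimerization of the free dye, then acid-driven splitting of the dimer into
two protonated monomers — is formulated in the added-acid coordinate $a$:
each increment of acid is consumed by the two reactions in proportion to
their instantaneous rates,

$$r_1 = \frac{k_1 c_1^2}{k_1 c_1^2 + k_2 c_2 + \eta}, \quad
  r_2 = \frac{k_2 c_2}{k_1 c_1^2 + k_2 c_2 + \eta},$$
$$\frac{dc_1}{da} = -2r_1, \quad \frac{dc_2}{da} = r_1 - r_2, \quad
  \frac{dc_3}{da} = 2r_2,$$

from $(c_0, 0, 0)$, with $\eta = 10^{-30}$ guarding the empty state and
both back reactions set to zero (titration with a superacid). The
added-acid coordinate replaces time because titration grades are a
sequence of equilibria, not a time series; this formulation conserves the
closure identically and reaches full conversion after exactly $c_0$ of
added acid. It is the largest interpretive choice in the package: the
rate-law orders follow the reaction scheme (second order in the free dye
for the dimerization, first order in the dimer for the split), and the
stoichiometric factors are fixed by the closure weights $(1, 2, 1)$.

Because $r_1 + r_2 = 1$ while reactants remain, the trajectory depends on
the rates only through $k_1/k_2$: the individual rate values are a gauge
choice. `fit_kinetics()` (log-scale Nelder–Mead from a fixed $4\times4$
log-grid of starts) therefore reports the identifiable `ratio` alongside
the raw rates, and agreement between a factorization and the kinetic model
is quantified by `reldiff()` — per-component relative errors in the
maximum and Euclidean norms.

Numerical notes: the ODE has a corner where both reactants are exhausted
($c_1 + c_2 \to 0$ at $a = c_0$); the integrator (`deSolve::lsodar`) stops
there through a root function and the fully converted state is used
beyond. Rates are clamped at zero concentration so an exhausted species
cannot drive its reaction; a stiff retry with relaxed tolerances covers
extreme rate ratios.

## What the synthetic generator does and does not emulate

`generate_dataset()` defines the reference scenario all tests run under: 12
spectra over 401 channels on 200–600 nm, added acid in
$[0, 1.264\times10^{-3}]$ mol/l, $c_0 = 9.84269\times10^{-4}$ mol/l,
concentration profiles from the kinetic model above (defaults $k_1 =
4\times10^7$, $k_2 = 10^4$, chosen so the dimer peaks near mid-titration
at about $0.29\,c_0$ and both terminal states are pure), pure spectra as
three-band Gaussian mixtures, and additive Gaussian noise of $10^{-4}$
relative to the maximum absorbance. The dimer's bands sit strictly inside
the union of the terminal components' supports, so the dimer is the
ambiguous component — its AFS subset is visibly larger than the terminal
components' — while each terminal species retains a selective wavelength
region that keeps the three subsets isolated. The band tables are fixture
tuning, not a claim about any real dye.

The generator does not emulate instrument effects (baseline drift, stray
light, wavelength-dependent noise), deviations from Beer's law, or
fluorescence measurement error: the "measured" profiles handed to the
duality and annihilation workflows are the exact ground-truth columns.
Passing tests therefore demonstrate the correctness of the algorithms
under the bilinear model, not robustness to real instrument artifacts.

Problem sizes used by the test suite: the unit tests run a 201-channel
noiseless instance for the tracing-heavy checks, the acceptance tests run
the full 401-channel dataset with the default noise, the polygon/oracle
comparison uses a $200\times200$ grid over the padded bounding box of the
spectral subsets, and the $\varepsilon$-monotonicity property is checked
on three 201-channel instances differing in their kinetic paths.

## Degenerate inputs and tie-breaks

* Singular transforms get an infinite violation sentinel, never an
  exception, so optimizers can penalize them smoothly.
* Singular vectors are oriented so each right singular vector's
  largest-magnitude entry is positive, making AFS coordinates reproducible
  across platforms.
* Profiles with a (near-)zero leading expansion coefficient cannot be
  normalized to an AFS point and are rejected with an explicit error;
  the same applies to data rows when seeding (nonnegative-like data have
  strictly positive leading coefficients).
* Completed components are matched to the fixed inputs by maximal cosine
  similarity, spectra before profiles, ties broken by input order;
  spectra are returned at unit maximum with the concentration columns
  absorbing the reciprocal scale. Absolute concentration scaling is the
  closure step's job.
* `region_member()` takes an explicit tolerance: boundary vertices are
  only $\varepsilon_b$-accurate, and on noisy data a ground-truth point
  can sit within noise distance outside the traced boundary.

## Known limitations

* AFS computation supports $s \in \{2, 3\}$; four-component systems need
  a different representation of the feasible set.
* The radial trace yields inner approximations for non-star-shaped
  subsets.
* Only irreversible kinetics are fit; equilibrium-constant estimation is
  out of scope.
* The grid oracle is a test instrument: it is quadratic in resolution and
  not meant for production AFS computation.

## A worked run

```{r workflow, eval = FALSE}
sim <- generate_dataset(synthetic_config())
sv  <- truncated_svd(sim$dataset, s = 3)
estimate_rank(sv$all_d)                       # 3

pp  <- feasibility_params()                   # eps 2e-4, delta = eps_b = 1e-4
afs_S <- afs_three_component(sv, "spectral", pp)
afs_C <- afs_three_component(sv, "concentrational", pp)

D <- sim$dataset$absorbance
fit <- complete_factorization(
  sv,
  fixed_spectra  = list(D[1, ], D[12, ]),     # pure endpoint rows
  fixed_profiles = list(sim$C_true[, 1], sim$C_true[, 3]))
# components come back in fixed-input order (dye, protonated monomer,
# dimer); restore titration order so the dimer carries closure weight 2
C_titr <- fit$C[, c(1, 3, 2)]
scaled <- closure_scale(C_titr, closure_spec(c(1, 2, 1), sim$config$c0))

ra  <- middle_component_by_annihilation(
  sim$dataset, first_profile = sim$C_true[, 1],
  last_profile = sim$C_true[, 3])
kin <- fit_kinetics(scaled$C, sim$dataset$conditions, sim$config$c0)
reldiff(kin$C_kin, scaled$C, "max")
```

The chunk is not evaluated when building the vignette (the AFS traces take
tens of seconds); `README.md` shows the same pipeline with the numbers it
prints, and `scripts/acceptance.R` recomputes them from scratch.
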