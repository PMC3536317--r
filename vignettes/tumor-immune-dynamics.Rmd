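---
title: "Tumor–immune dynamics with and without estrogen: models, methods, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor–immune dynamics with and without estrogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrodyn)
```

## The models and their assumptions

`estrodyn` implements two coupled ODE systems for breast-tissue cell
populations, treated as normalized dimensionless densities (the healthy
compartment starts at `H = 1`; no carrying-capacity rescaling is
applied).

**Estrogen-free core.** Host cells grow logistically and lose to tumor
competition; tumor cells grow logistically and are killed by immune
predation (`gamma2*I*T`); immune cells enter at a constant source `s`
from the thymus, are stimulated by tumor presence through a saturating
Michaelis–Menten term `rho*I*T/(omega + T)` (so immune proliferation
never runs away), are inactivated by tumor contact (`gamma3*I*T`) and
turn over at rate `mu`. The assumptions to keep in mind: populations
are well mixed (no spatial structure), interactions are mass-action
except the saturating immune response, and there are no delays and no
treatment terms.

**Estrogen extension.** A 17-β-estradiol compartment with constant
exogenous source `pi_src` and first-order clearance `theta` acts three
ways: it damages host DNA (`-sigma1*H*E`), a fraction of damaged cells
re-enter as tumor (`+sigma2*H*E`, with `sigma2 < sigma1` because immune
surveillance destroys part of them), and it suppresses the immune
compartment through a second saturating term `sigma3*I*E/(upsilon+E)`.
Tumor growth uses `alpha3 > alpha2`, folding in autocrine
estrogen-receptor stimulation.

## Parameters

| symbol | meaning | default | unit | provenance |
|---|---|---|---|---|
| alpha1 | host growth rate | 0.70 | day⁻¹ | published |
| beta1  | host self-limitation | 0.30 | day⁻¹ | published |
| delta1 | host loss to tumor competition | 1.0 | day⁻¹ | published |
| alpha2 | tumor growth rate | 0.98 | day⁻¹ | published |
| beta2  | tumor self-limitation | 0.40 | day⁻¹ | published |
| gamma2 | immune kill rate of tumor | 0.9 | day⁻¹ | published |
| gamma3 | immune inactivation by tumor | 0.1 | day⁻¹ | package default |
| s      | immune source | 0.4 | day⁻¹ | published |
| rho    | immune response rate | 0.2 | day⁻¹ | published |
| omega  | immune half-saturation | 0.3 | density | published |
| mu     | immune turnover | 0.29 | day⁻¹ | published |
| alpha3 | tumor growth under estrogen | 1.0 | day⁻¹ | package default |
| sigma1 | host DNA-damage rate | 0.3 | day⁻¹·E⁻¹ | package default |
| sigma2 | damaged-to-tumor transfer | 0.2 | day⁻¹·E⁻¹ | package default |
| sigma3 | immune suppression by estrogen | 0.1 | day⁻¹ | package default |
| upsilon| estrogen half-saturation | 0.5 | E units | package default |
| pi_src | exogenous estrogen source | 0.2 | E·day⁻¹ | package default |
| theta  | estrogen clearance | 0.97 | day⁻¹ | package default |

No published values exist for `gamma3` or for the estrogen block; the
defaults above are the package's own, chosen once to satisfy the
structural constraints (`sigma2 < sigma1`, `alpha3 > alpha2`), to keep
immune predation (`gamma2 = 0.9`) dominant over inactivation
(`gamma3 = 0.1`), and to keep the steady estrogen level
`E = pi_src/theta` below the host-viability threshold `alpha1/sigma1`
across the default dose grid. `validate_params()` enforces all of this
and names the violated constraint on rejection.

Two initial-condition presets are shipped exactly as printed in the
source material: `ic_estrogen_free_paper` uses `T(0) = 1e-5` while
`ic_estrogen_paper` uses `T(0) = 10` — a factor-of-10⁶ discrepancy that
we surface rather than resolve.

## Equilibria: closed forms, root-finding, and a pseudo-equilibrium

Tumor-free and type-2 dead states are closed-form. The coexisting state
(and the estrogen tumor-takeover state) couple the tumor and immune
coordinates mutually; after substituting
`I(T) = s / (mu - rho*T/(omega+T) + gamma3*T [+ sigma3*E/(upsilon+E)])`
(and `H(T)` in the coexisting case) the condition `dT/dt = 0` becomes a
scalar equation in `T`, solved by a sign-scan over a 600-point grid on
`(1e-12, Tmax]` followed by `uniroot` at tolerance `1e-13` and a short
Newton polish — cheap, derivative-light, and robust to the poles of
`I(T)`. Every root found is returned as its own equilibrium, ordered by
tumor density, with the smallest labelled primary. A feasible
equilibrium must have finite nonnegative coordinates, all existence
conditions satisfied, and a scaled residual
`max|f(x*)| / max(1, max|x*|) < 1e-10`.

For the type-1 dead state of the core model, the printed construction
takes the tumor coordinate from the quadratic
`gamma3*T² + (mu + omega*gamma3 - rho)*T + mu*omega = 0` — which is
exactly the numerator of the immune coordinate's denominator, so at
that root the immune coordinate diverges. Both quadratic branches are
computed and feasibility-checked (the `+sqrt` branch is labelled
primary), and the state is reported with its failed conditions; in
practice it is never a finite feasible fixed point, consistent with the
dead states being unreachable except through total immune collapse.

**The estrogen tumor-free pseudo-equilibrium.** With `pi_src > 0` the
printed tumor-free coordinates do not zero the extended vector field:
`dT/dt = sigma2*H*E > 0` at `T = 0`. We report the state with
`feasible = FALSE` and its true (nonzero) residual, while the condition
`E_le_alpha1_over_sigma1` records whether the printed coordinates are
admissible (`pi_src/theta <= alpha1/sigma1`). This keeps the residual
contract exact and makes the model's central message explicit: under a
sustained estrogen source, tumor-free is not a state the system can
occupy at all.

## Stability

Local stability is read off the eigenvalues of the analytic Jacobian
(`eigen`), with a marginality band of `1e-9` on real parts to absorb
double-precision eigensolver noise near bifurcations. The printed
characteristic polynomials of the estrogen model are truncated in the
source text and one coefficient is not derivable from the Jacobian, so
they are never reconstructed symbolically; Routh–Hurwitz sign tables
are instead computed from the exact characteristic polynomial of the
3×3 cell block and reported as diagnostics, alongside the
trace/determinant of the tumor–immune 2×2 sub-block.

The Castillo–Chavez global check splits the state into undamaged
compartments `X` and the damaged compartment `Z = T`, with
`A = D_Z G(X_tf, 0)` and `Gstar(T) = A*T - G(X_tf, T)` evaluated over a
201-point tumor grid on `[0, growth/beta2]`. In the core model
`Gstar = beta2*T² ≥ 0` identically, so the tumor-free state is globally
stable whenever it exists; with `pi_src > 0` the transfer term makes
`Gstar(0⁺) = -sigma2*H*E < 0` and global stability is lost. Because the
printed decomposition writes the `A` coefficient with the estrogen-free
growth rate while the extended field uses `alpha3`, both readings are
exposed via `global_A_growth_rate`, defaulting to the
vector-field-consistent `alpha3`.

One published claim is deliberately treated as *monitored* rather than
asserted: that the estrogen-model tumor-free state is always unstable.
Its printed derivation rests on the non-derivable polynomial
coefficient; over random feasible parameter draws the linearisation is
unstable in roughly half the cases, and the test suite reports the
violation count instead of hiding it.

## Simulation

Integration uses the adaptive Dormand–Prince Runge–Kutta 4(5) scheme
(`deSolve::ode`, method `"ode45"`), default `rtol = 1e-8`,
`atol = 1e-10`, with at least 201 saved points. Default horizons are
200 days (core model) and 100 days (estrogen model), at least ten
multiples of the slowest canonical rate. Negative undershoot beyond
`-1e-8` is an error, never clipped — clipping would mask model or
solver defects; milder undershoot is tolerated and reported in the
solver metadata. The decoupled estrogen compartment has the exact
solution `pi_src/theta + (E0 - pi_src/theta)e^(-theta t)`, kept in the
package (`estrogen_closed_form`) as an independent oracle for the
integrator. Outcome classification matches the terminal state against
the feasible equilibria at relative tolerance `1e-3` with precedence
tumor clearance → host extinction → coexistence → tumor escape
(terminal tumor above every equilibrium and still growing) → undecided,
and uses an absolute clearance threshold of `1e-6`.

## Dose sweep

`sweep_estrogen_source` re-solves equilibria, tumor-free leading
eigenvalue, and a full simulation on a `pi_src` grid (default 11 points
on `[0, 1]`), refining any leading-eigenvalue sign change by bisection
to `1e-8`. Monotonicity flags use terminal values at fixed `t_end`
rather than asymptotic values, since escape trajectories need not
converge. Under the default parameters the terminal host population
falls monotonically with dose, and the tumor rises over most of the
grid — but not all of it: by `t_end = 100` trajectories sit on the
coexisting branch, along which the tumor coordinate peaks near
`pi_src ≈ 0.8` and then declines slightly as host collapse shrinks the
`sigma2*H*E` inflow, and the immune coordinate rises at small doses
because tumor-stimulated recruitment outweighs suppression at
`sigma3 = 0.1`. The sweep records these flags honestly instead of
forcing a monotone reading; the strict three-way monotone dose response
holds only in parameter regimes with stronger immune suppression.

## Synthetic data and parameter recovery

There is no deposited data for these models, so the synthetic module
generates the only inputs the analysis consumes. Random parameter sets
are drawn uniformly from `[0.5, 1.5]` times the defaults (rejection
sampling against the structural constraints, deterministic given a
seed) — wide enough that the resistance coefficient spans both sides of
the stability boundary. Observations are the tight-tolerance
(`rtol 1e-10`) model solution on 41 equally spaced times plus additive
Gaussian noise truncated at zero; this is the simplest observation
model consistent with nonnegative densities, and it is a package
construct, not a published one. Truncation biases the noise only where
the signal is within a couple of standard deviations of zero.

The default recovery scenario uses the core model with `T(0) = 0.25`
rather than the published `1e-5`: at a vanishing tumor load the tumor
equation linearizes to `dT/dt ≈ (alpha2 - gamma2*I)T`, so `alpha2` and
`gamma2` are identifiable only through that combination, while a
visible burden activates the `beta2*T²` and saturating-response terms
and separates them. Fitting is bounded local Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a supplied guess; there is no global
search, and full 11-parameter fits are deliberately out of scope
(sloppy, multi-modal). On noise-free data the `{alpha2, gamma2}` pair
is recovered to ~1e-6 relative error; at noise sd 0.02 the median
relative error on `alpha2` over 20 seeds is below 1%.

## Problem sizes in the test suite

Property tests use 1000-draw parameter ensembles for the stability
equivalences, 500 random states per model for Jacobian
finite-difference agreement, 300 draws for equilibrium-condition
properties, 20 replicate seeds for noisy recovery, and brute-force
grids at step 1e-6 for root oracles — sizes chosen so the whole suite
exercises every claim at meaningful resolution while remaining quick to
run on a laptop.

## Known limitations

- No spatial structure, delays, stochasticity, or treatment terms.
- Equilibrium continuation is re-solve-per-grid-point; no fold/Hopf
  tracking.
- The estrogen-block parameter defaults are package choices; published
  figures for the estrogen model cannot be reproduced point-for-point
  because the underlying parameter values were never printed — only
  qualitative behaviour is checkable.
- Global stability is assessed through the compartment-splitting
  conditions only; no Lyapunov functions are constructed, and marginal
  eigenvalue cases get no center-manifold analysis.
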