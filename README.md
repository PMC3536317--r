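# estrodyn

Deterministic population models of breast-cancer dynamics for
mathematical oncologists and biostatisticians who want a tested,
scriptable implementation of the tumor–immune competition framework and
its estrogen-extended variant: equilibria, stability classification,
trajectory simulation, dose sweeps, and synthetic-data parameter
recovery.

## The models

The core system tracks three normalized cell densities — normal host
cells *H*, tumor cells *T* and immune effector cells (NK / CD8⁺) *I* —
coupled by Lotka–Volterra competition, immune predation and a
saturating immune response:

    dH/dt = H(α₁ − β₁H − δ₁T)
    dT/dt = T(α₂ − β₂T) − γ₂IT
    dI/dt = s + ρIT/(ω + T) − γ₃IT − μI

All rates are per day. The tumor-free state (α₁/β₁, 0, s/μ) is locally
stable exactly when the **immune resistance coefficient** sγ₂/μ exceeds
the tumor growth rate α₂, and it is the unique globally stable state
(Castillo–Chavez compartment splitting).

The extended system adds a 17-β-estradiol compartment *E* with constant
source π and first-order clearance θ. Estrogen damages host DNA
(−σ₁HE), converts part of the damaged cells into tumor (+σ₂HE, with
σ₂ < σ₁), boosts tumor growth through autocrine receptor signalling
(α₃ > α₂ replacing α₂) and suppresses immunity (−σ₃IE/(υ + E)):

    dH/dt = H(α₁ − β₁H − δ₁T) − σ₁HE
    dT/dt = T(α₃ − β₂T) − γ₂IT + σ₂HE
    dI/dt = s + ρIT/(ω + T) − γ₃IT − μI − σ₃IE/(υ + E)
    dE/dt = π − θE

With any positive source the transfer term σ₂HE keeps seeding the tumor
compartment at *T* = 0, so a tumor-free steady state cannot persist —
the central qualitative conclusion of the model. See the methods
vignette (`vignettes/tumor-immune-dynamics.Rmd`) for the full account,
including which estrogen-block parameter values are package defaults
rather than published estimates.

## Worked example

```r
library(estrodyn)

p  <- table1_params()                 # canonical published rates
tf <- tumor_free_equilibrium(p)
tf
#> <equilibrium> tumor_free [estrogen_free]  feasible: TRUE  residual: 1.11e-16
#>        H        T        I
#> 2.333333 0.000000 1.379310

local_stability(tf, p)
#> <stability> tumor_free [estrogen_free]: stable
#> eigenvalues: -0.261379+0i, -0.290000+0i, -0.700000+0i

tumor_free_stability_condition(p)
#> $resistance   1.241379      $stable   TRUE

find_stability_boundary(p, "alpha2", 0.5, 2.0)
#> [1] 1.24137931
```

The healthy tissue settles at *H* = α₁/β₁ = 2.33, the immune system at
*I* = s/μ = 1.379310345, and the tumor dies out: the middle eigenvalue
α₂ − γ₂s/μ = −0.261 < 0 because the resistance coefficient 1.241
exceeds α₂ = 0.98. Bisection on α₂ recovers that same threshold as the
stability boundary.

Sweeping the estrogen source shows the dose response:

```r
sw <- sweep_estrogen_source(default_estrogen_params(),
                            pi_values = seq(0, 1, 0.25), t_end = 60)
sw$records[, c("pi_src", "outcome", "H", "T", "I")]
#>   pi_src         outcome      H         T     I
#> 1   0.00 tumor_clearance 2.3333 9.549e-08 1.379
#> 2   0.25     coexistence 1.4739 1.805e-01 1.499
#> 3   0.50     coexistence 0.9878 2.490e-01 1.455
#> 4   0.75     coexistence 0.6618 2.695e-01 1.413
#> 5   1.00     coexistence 0.4341 2.605e-01 1.377
```

Without exogenous estrogen the immune system clears the tumor; any
positive dose sustains a persistent tumor and erodes the host
population.

A config-driven command-line dispatcher over the same functions ships
at `system.file("cli", "estrodyn.R", package = "estrodyn")` with
subcommands `equilibria | simulate | sweep | recover`.

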