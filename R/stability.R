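#' @title Stability analysis
#' @description Local stability of each fixed point is read off the
#'   eigenvalues of the analytic Jacobian (the linearization governs the
#'   local phase portrait at hyperbolic equilibria). Trace/determinant
#'   and Routh-Hurwitz sign conditions are reported as diagnostics, and
#'   the tumor-free state is additionally screened for global asymptotic
#'   stability by the Castillo-Chavez compartment-splitting conditions.
#' @name estrodyn-stability
NULL

.eps_marginal <- 1e-9

.classify_eigen <- function(ev, eps = .eps_marginal) {
  re <- Re(ev)
  if (all(re < -eps)) "stable"
  else if (any(re > eps)) "unstable"
  else "marginal"
}

# monic characteristic polynomial coefficients of a 3x3 matrix:
# lambda^3 + a*lambda^2 + b*lambda + c
.charpoly3 <- function(J) {
  stopifnot(nrow(J) == 3L, ncol(J) == 3L)
  a <- -sum(diag(J))
  b <- (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) +
       (J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1]) +
       (J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2])
  c(1, a, b, -det(J))
}

#' Local stability of an equilibrium
#'
#' Evaluates the analytic Jacobian at the equilibrium state, computes its
#' eigenvalues and classifies the point: `stable` when every real part is
#' below `-1e-9`, `unstable` when some real part exceeds `+1e-9`,
#' `marginal` in the band between (the band absorbs double-precision
#' eigensolver noise near bifurcations). Diagnostics include the
#' real parts, the characteristic-polynomial Routh-Hurwitz table of the
#' cell-compartment block, the trace and determinant of the tumor/immune
#' 2x2 sub-block (the block that decides stability at the coexisting
#' state), and — for the estrogen-free tumor-free state — the closed-form
#' eigenvalue triple `(-alpha1, alpha2 - gamma2*s/mu, -mu)` with the
#' resistance coefficient `s*gamma2/mu`. Infeasible equilibria are
#' analysed too but flagged `hypothetical`.
#'
#' @param eq an `estrodyn_equilibrium`.
#' @param params validated parameter set for `eq$model`.
#' @return an `estrodyn_stability` report.
#' @export
local_stability <- function(eq, params) {
  stopifnot(inherits(eq, "estrodyn_equilibrium"))
  model <- eq$model
  p <- .as_params(params, model)
  st <- eq$state
  if (any(!is.finite(st)))
    stop("equilibrium state has non-finite coordinates; nothing to linearise",
         call. = FALSE)
  J <- model_jacobian(model, pmax(st, 0), p)
  ev <- as.complex(eigen(J, only.values = TRUE)$values)
  ev <- ev[order(-Re(ev))]
  diagnostics <- list(real_parts = Re(ev))
  cell_block <- if (model == "estrogen") J[1:3, 1:3] else J
  rh <- routh_hurwitz(.charpoly3(cell_block))
  diagnostics$routh_hurwitz <- rh
  tw <- J[c("T", "I"), c("T", "I")]
  diagnostics$block_trace <- sum(diag(tw))
  diagnostics$block_det <- tw[1, 1] * tw[2, 2] - tw[1, 2] * tw[2, 1]
  if (model == "estrogen_free" && eq$label == "tumor_free") {
    diagnostics$closed_form_eigenvalues <-
      c(-p[["alpha1"]], p[["alpha2"]] - p[["gamma2"]] * p[["s"]] / p[["mu"]],
        -p[["mu"]])
    diagnostics$resistance_coefficient <-
      p[["s"]] * p[["gamma2"]] / p[["mu"]]
  }
  structure(list(equilibrium = eq,
                 eigenvalues = ev,
                 classification = .classify_eigen(ev),
                 hypothetical = !eq$feasible,
                 diagnostics = diagnostics),
            class = "estrodyn_stability")
}

#' @export
print.estrodyn_stability <- function(x, ...) {
  cat(sprintf("<stability> %s [%s]: %s%s\n", x$equilibrium$label,
              x$equilibrium$model, x$classification,
              if (x$hypothetical) " (hypothetical: infeasible state)" else ""))
  cat("eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Tumor-free stability condition of the estrogen-free model
#'
#' The tumor-free state is locally stable exactly when the immune
#' resistance coefficient `s*gamma2/mu` (kill rate times immune supply
#' over immune turnover) exceeds the tumor per-capita growth rate
#' `alpha2`: the middle eigenvalue of the tumor-free Jacobian is
#' `alpha2 - gamma2*s/mu` and the other two (`-alpha1`, `-mu`) are always
#' negative.
#'
#' @param params validated estrogen-free parameter set.
#' @return list with `resistance` (`s*gamma2/mu`) and `stable`
#'   (`alpha2 < resistance`).
#' @examples
#' tumor_free_stability_condition(table1_params())
#' @export
tumor_free_stability_condition <- function(params) {
  p <- .as_params(params, "estrogen_free")
  resistance <- p[["s"]] * p[["gamma2"]] / p[["mu"]]
  list(resistance = resistance, stable = p[["alpha2"]] < resistance)
}

#' Routh-Hurwitz criterion for quadratic and cubic polynomials
#'
#' Sign conditions on monic characteristic-polynomial coefficients that
#' are equivalent to every root lying in the open left half-plane.
#' Degree 2 (`lambda^2 + a*lambda + b`): `a > 0` and `b > 0`. Degree 3
#' (`lambda^3 + a*lambda^2 + b*lambda + c`): `a > 0`, `c > 0`,
#' `a*b > c`.
#'
#' @param coeffs numeric vector of length 3 or 4, leading coefficient 1,
#'   in decreasing power order.
#' @return list with `stable` (logical) and `conditions` (data.frame of
#'   the individual sign checks with margins).
#' @examples
#' routh_hurwitz(c(1, 1, 1))        # lambda^2 + lambda + 1: stable
#' routh_hurwitz(c(1, -0.5, 1))     # negative trace: unstable
#' @export
routh_hurwitz <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (!length(coeffs) %in% c(3L, 4L))
    stop("only degree 2 or 3 polynomials are supported", call. = FALSE)
  if (any(!is.finite(coeffs)))
    stop("non-finite coefficient", call. = FALSE)
  if (abs(coeffs[1] - 1) > 1e-12)
    stop("leading coefficient must be normalized to 1", call. = FALSE)
  if (length(coeffs) == 3L) {
    a <- coeffs[2]; b <- coeffs[3]
    conditions <- rbind(.cond("a_positive", a > 0, a),
                        .cond("b_positive", b > 0, b))
  } else {
    a <- coeffs[2]; b <- coeffs[3]; cc <- coeffs[4]
    conditions <- rbind(.cond("a_positive", a > 0, a),
                        .cond("c_positive", cc > 0, cc),
                        .cond("ab_gt_c", a * b > cc, a * b - cc))
  }
  list(stable = all(conditions$satisfied), conditions = conditions)
}

#' Castillo-Chavez global stability of the tumor-free state
#'
#' Splits the state into undamaged compartments `X` (host, immune and —
#' in the estrogen model — estrogen) and the damaged compartment `Z = T`,
#' writing `dZ/dt = G(X, Z) = A*Z - Gstar(X, Z)` with
#' `A = D_Z G(X_tf, 0)`. Global asymptotic stability of the tumor-free
#' state needs (H1) the tumor-free `X` subsystem to be globally stable
#' and (H2) `Gstar(X, Z) >= 0` on the admissible region. Here `Gstar`
#' is evaluated at the tumor-free `X` over a tumor-density grid
#' `[0, growth/beta2]`: in the estrogen-free model it reduces to
#' `beta2*T^2 >= 0`, so the tumor-free state is the unique globally
#' stable one; with a positive estrogen source the transfer term
#' `sigma2*H*E` makes `Gstar = beta2*T^2 - sigma2*H*E < 0` near `T = 0`,
#' so H2 fails and no amount of immune resistance restores global
#' stability. In the estrogen model H1 additionally requires the
#' tumor-free state to exist (`pi_src/theta <= alpha1/sigma1`).
#'
#' @inheritParams tumor_free_equilibrium
#' @param global_A_growth_rate which tumor growth rate enters
#'   `A = growth - 2*beta2*T - gamma2*I` for the estrogen model:
#'   `"alpha3_consistent"` (default; the rate actually present in the
#'   estrogen vector field) or `"alpha2_as_printed"` (the estrogen-free
#'   rate, retained as an alternative reading).
#' @return an `estrodyn_global_stability` report with fields `A`,
#'   `Gstar_min`, `H1_holds`, `H2_holds`, `verdict`.
#' @export
castillo_chavez_global <- function(params,
                                   model = c("estrogen_free", "estrogen"),
                                   global_A_growth_rate =
                                     c("alpha3_consistent",
                                       "alpha2_as_printed")) {
  model <- .check_model(match.arg(model))
  option <- match.arg(global_A_growth_rate)
  p <- .as_params(params, model)
  tf <- tumor_free_equilibrium(p, model)
  Istar <- tf$state[["I"]]
  if (model == "estrogen_free") {
    growth_A <- p[["alpha2"]]
    growth_field <- p[["alpha2"]]
    transfer <- 0
    H1 <- TRUE  # logistic host + linear immune subsystem: always globally stable
  } else {
    growth_A <- if (option == "alpha3_consistent") p[["alpha3"]] else
      p[["alpha2"]]
    growth_field <- p[["alpha3"]]
    E <- p[["pi_src"]] / p[["theta"]]
    Htf <- max(tf$state[["H"]], 0)
    transfer <- p[["sigma2"]] * Htf * E
    H1 <- tf$feasible
  }
  A <- growth_A - p[["gamma2"]] * Istar   # 1x1 M-matrix at T = 0
  # Gstar(T) = A*T - G(X_tf, T); G evaluated with the tumor-free X frozen
  Tgrid <- seq(0, growth_field / p[["beta2"]], length.out = 201L)
  Gstar <- (growth_A - growth_field) * Tgrid + p[["beta2"]] * Tgrid^2 -
    transfer
  H2 <- all(Gstar >= -1e-12)
  structure(list(model = model, growth_rate_option = option,
                 A = A, Gstar_min = min(Gstar),
                 H1_holds = H1, H2_holds = H2,
                 verdict = if (H1 && H2) "globally_stable" else
                   "not_globally_stable"),
            class = "estrodyn_global_stability")
}

#' @export
print.estrodyn_global_stability <- function(x, ...) {
  cat(sprintf("<global stability> %s: %s (H1 %s, H2 %s, A = %.4g, min G* = %.4g)\n",
              x$model, x$verdict, x$H1_holds, x$H2_holds, x$A, x$Gstar_min))
  invisible(x)
}
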