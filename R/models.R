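#' Right-hand side of the estrogen-free tumor-immune model
#'
#' Three competing compartments: normal host cells `H`, tumor cells `T`
#' and immune effector cells `I` (NK / CD8+), all as normalized
#' dimensionless densities. The vector field is
#' \deqn{dH/dt = H(\alpha_1 - \beta_1 H - \delta_1 T)}
#' \deqn{dT/dt = T(\alpha_2 - \beta_2 T) - \gamma_2 I T}
#' \deqn{dI/dt = s + \rho I T/(\omega + T) - \gamma_3 I T - \mu I}
#' i.e. logistic host growth with competitive inhibition by the tumor,
#' logistic tumor growth with immune predation, and a constant immune
#' source with a saturating (Michaelis-Menten) tumor-stimulated response,
#' tumor-driven inactivation and natural turnover.
#'
#' @param state named numeric `(H, T, I)`, all `>= 0`.
#' @param params validated estrogen-free parameter set (see
#'   [validate_params()]).
#' @return named numeric derivative `(H, T, I)` in day^-1.
#' @seealso [rhs_estrogen()], [model_jacobian()]
#' @examples
#' p <- table1_params()
#' rhs_estrogen_free(c(H = p[["alpha1"]] / p[["beta1"]], T = 0,
#'                     I = p[["s"]] / p[["mu"]]), p)  # tumor-free fixed point
#' @export
rhs_estrogen_free <- function(state, params) {
  p <- .as_params(params, "estrogen_free")
  x <- .check_state(state, "estrogen_free")
  H <- x[["H"]]; Tm <- x[["T"]]; I <- x[["I"]]
  c(H = H * (p[["alpha1"]] - p[["beta1"]] * H - p[["delta1"]] * Tm),
    T = Tm * (p[["alpha2"]] - p[["beta2"]] * Tm) - p[["gamma2"]] * I * Tm,
    I = p[["s"]] + p[["rho"]] * I * Tm / (p[["omega"]] + Tm) -
        p[["gamma3"]] * I * Tm - p[["mu"]] * I)
}

#' Right-hand side of the estrogen-extended model
#'
#' Adds a 17-beta-estradiol compartment `E` with constant source `pi_src`
#' and first-order clearance `theta`. Estrogen damages host-cell DNA
#' (`-sigma1*H*E` on hosts), converts a fraction of the damaged cells into
#' tumor cells (`+sigma2*H*E`, with `sigma2 < sigma1`), boosts tumor
#' growth through autocrine receptor signalling (`alpha3 > alpha2`
#' replacing `alpha2`), and suppresses the immune compartment through a
#' saturating term `-sigma3*I*E/(upsilon + E)`.
#'
#' @param state named numeric `(H, T, I, E)`, all `>= 0`.
#' @param params validated estrogen parameter set.
#' @return named numeric derivative `(H, T, I, E)` in day^-1.
#' @export
rhs_estrogen <- function(state, params) {
  p <- .as_params(params, "estrogen")
  x <- .check_state(state, "estrogen")
  H <- x[["H"]]; Tm <- x[["T"]]; I <- x[["I"]]; E <- x[["E"]]
  c(H = H * (p[["alpha1"]] - p[["beta1"]] * H - p[["delta1"]] * Tm) -
        p[["sigma1"]] * H * E,
    T = Tm * (p[["alpha3"]] - p[["beta2"]] * Tm) - p[["gamma2"]] * I * Tm +
        p[["sigma2"]] * H * E,
    I = p[["s"]] + p[["rho"]] * I * Tm / (p[["omega"]] + Tm) -
        p[["gamma3"]] * I * Tm - p[["mu"]] * I -
        p[["sigma3"]] * I * E / (p[["upsilon"]] + E),
    E = p[["pi_src"]] - p[["theta"]] * E)
}

#' Analytic Jacobian of either model
#'
#' Partial derivatives of the vector field evaluated at a state: 3x3 for
#' the estrogen-free model, 4x4 for the estrogen model. The estrogen row
#' of the 4x4 Jacobian is `(0, 0, 0, -theta)` — the estrogen compartment
#' is decoupled from the cell populations — so `-theta` is always an
#' eigenvalue of the estrogen model.
#'
#' @param model `"estrogen_free"` or `"estrogen"`.
#' @param state named numeric state at which to evaluate.
#' @param params validated parameter set for `model`.
#' @return numeric matrix with dimnames the state names, units day^-1.
#' @export
model_jacobian <- function(model, state, params) {
  model <- .check_model(model)
  p <- .as_params(params, model)
  x <- .check_state(state, model)
  H <- x[["H"]]; Tm <- x[["T"]]; I <- x[["I"]]
  omega <- p[["omega"]]
  if (model == "estrogen_free") {
    J <- matrix(0, 3, 3, dimnames = list(names(x), names(x)))
    J["H", "H"] <- p[["alpha1"]] - 2 * p[["beta1"]] * H - p[["delta1"]] * Tm
    J["H", "T"] <- -p[["delta1"]] * H
    J["T", "T"] <- p[["alpha2"]] - 2 * p[["beta2"]] * Tm - p[["gamma2"]] * I
    J["T", "I"] <- -p[["gamma2"]] * Tm
    J["I", "T"] <- p[["rho"]] * I * omega / (omega + Tm)^2 - p[["gamma3"]] * I
    J["I", "I"] <- p[["rho"]] * Tm / (omega + Tm) - p[["gamma3"]] * Tm -
      p[["mu"]]
    return(J)
  }
  E <- x[["E"]]; ups <- p[["upsilon"]]
  J <- matrix(0, 4, 4, dimnames = list(names(x), names(x)))
  J["H", "H"] <- p[["alpha1"]] - 2 * p[["beta1"]] * H - p[["delta1"]] * Tm -
    p[["sigma1"]] * E
  J["H", "T"] <- -p[["delta1"]] * H
  J["H", "E"] <- -p[["sigma1"]] * H
  J["T", "H"] <- p[["sigma2"]] * E
  J["T", "T"] <- p[["alpha3"]] - 2 * p[["beta2"]] * Tm - p[["gamma2"]] * I
  J["T", "I"] <- -p[["gamma2"]] * Tm
  J["T", "E"] <- p[["sigma2"]] * H
  J["I", "T"] <- p[["rho"]] * I * omega / (omega + Tm)^2 - p[["gamma3"]] * I
  J["I", "I"] <- p[["rho"]] * Tm / (omega + Tm) - p[["gamma3"]] * Tm -
    p[["mu"]] - p[["sigma3"]] * E / (ups + E)
  J["I", "E"] <- -p[["sigma3"]] * I * ups / (ups + E)^2
  J["E", "E"] <- -p[["theta"]]
  J
}

# dispatch helper: evaluate the RHS for a model id
.model_rhs <- function(model, state, params) {
  if (.check_model(model) == "estrogen_free")
    rhs_estrogen_free(state, params)
  else rhs_estrogen(state, params)
}

# accept either a validated set or a raw named vector/list
.as_params <- function(params, model) {
  if (inherits(params, "estrodyn_params")) {
    if (!identical(attr(params, "model"), model))
      stop("parameter set is for model ", sQuote(attr(params, "model")),
           ", expected ", sQuote(model), call. = FALSE)
    return(params)
  }
  validate_params(params, model)
}
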