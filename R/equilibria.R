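#' @title Equilibria of the tumor-immune models
#' @description Fixed points of both vector fields with feasibility and
#'   existence-condition checks. Closed forms are used wherever the
#'   coordinates decouple; the mutually coupled tumor/immune coordinates
#'   of the coexisting (and estrogen tumor-takeover) states are reduced
#'   to a scalar equation in the tumor density and solved by bracketed
#'   root-finding.
#' @name estrodyn-equilibria
NULL

.cond <- function(name, satisfied, margin = NA_real_) {
  data.frame(name = name, satisfied = satisfied, margin = margin,
             stringsAsFactors = FALSE)
}

# scaled RHS residual: max |f(x*)| / max(1, max |x*|)
.residual <- function(model, state, params) {
  if (any(!is.finite(state))) return(Inf)
  f <- .model_rhs(model, pmax(state, 0), params)
  max(abs(f)) / max(1, max(abs(state)))
}

.residual_tol <- 1e-10

.new_equilibrium <- function(label, model, state, params, conditions,
                             require = TRUE, branch = NULL) {
  coords_ok <- all(is.finite(state)) && all(state >= -1e-12)
  res <- .residual(model, state, params)
  feasible <- isTRUE(require) && coords_ok &&
    all(conditions$satisfied) && res < .residual_tol
  structure(list(label = label, model = model,
                 state = stats::setNames(as.numeric(state),
                                         .state_names(model)),
                 feasible = feasible,
                 conditions = rbind(conditions,
                                    .cond("rhs_residual_lt_1e-10",
                                          res < .residual_tol,
                                          .residual_tol - res)),
                 residual = res, branch = branch),
            class = "estrodyn_equilibrium")
}

#' @export
print.estrodyn_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> %s [%s]%s  feasible: %s  residual: %.3g\n",
              x$label, x$model,
              if (is.null(x$branch)) "" else paste0(" (", x$branch, ")"),
              x$feasible, x$residual))
  print(round(x$state, 8))
  bad <- x$conditions[!x$conditions$satisfied, "name"]
  if (length(bad)) cat("failed conditions:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Tumor-free equilibrium
#'
#' Estrogen-free model: `(H, T, I) = (alpha1/beta1, 0, s/mu)`; exists and
#' is feasible for every valid parameter set. Estrogen model:
#' `E = pi_src/theta`, `H = (alpha1 - sigma1*E)/beta1`, `T = 0`,
#' `I = s(E + upsilon) / (mu(E + upsilon) + sigma3*E)`; the host
#' coordinate is nonnegative — and the state biologically admissible —
#' only when the steady estrogen level satisfies
#' `E <= alpha1/sigma1`, i.e. estrogen-driven DNA damage does not outpace
#' host renewal. Note that with a positive estrogen source this state is
#' only a pseudo-equilibrium of the full system: the conversion term
#' `sigma2*H*E` keeps seeding the tumor compartment at `T = 0`, so
#' `dT/dt > 0` there and the residual condition fails — the state is
#' reported with `feasible = FALSE` and the nonzero residual, while the
#' existence condition `E_le_alpha1_over_sigma1` records whether the
#' printed coordinates are admissible. This mirrors the model's central
#' conclusion: with exogenous estrogen the tumor-free state cannot
#' persist at all.
#'
#' @param params validated parameter set for `model`.
#' @param model `"estrogen_free"` or `"estrogen"`.
#' @return an `estrodyn_equilibrium` (label `"tumor_free"`).
#' @examples
#' tumor_free_equilibrium(table1_params())$state[["I"]]  # s/mu
#' @export
tumor_free_equilibrium <- function(params,
                                   model = c("estrogen_free", "estrogen")) {
  model <- .check_model(match.arg(model))
  p <- .as_params(params, model)
  if (model == "estrogen_free") {
    st <- c(p[["alpha1"]] / p[["beta1"]], 0, p[["s"]] / p[["mu"]])
    return(.new_equilibrium("tumor_free", model, st, p,
                            .cond("all_rates_positive", TRUE)))
  }
  E <- p[["pi_src"]] / p[["theta"]]
  H <- (p[["alpha1"]] - p[["sigma1"]] * E) / p[["beta1"]]
  I <- p[["s"]] * (E + p[["upsilon"]]) /
    (p[["mu"]] * (E + p[["upsilon"]]) + p[["sigma3"]] * E)
  margin <- p[["alpha1"]] / p[["sigma1"]] - E
  .new_equilibrium("tumor_free", model, c(H, 0, I, E), p,
                   .cond("E_le_alpha1_over_sigma1", margin >= 0, margin))
}

# immune coordinate as a function of tumor density (estrogen-free: E = 0)
.immune_at <- function(Tm, p, E = 0) {
  den <- p[["mu"]] - p[["rho"]] * Tm / (p[["omega"]] + Tm) +
    p[["gamma3"]] * Tm
  if (E > 0) den <- den + p[["sigma3"]] * E / (p[["upsilon"]] + E)
  p[["s"]] / den
}

# scalar fixed-point equation in T for states with coupled T and I.
# with_host: include the sigma2*H*E tumor source (coexisting state).
.tumor_gap <- function(Tm, p, model, with_host) {
  if (model == "estrogen_free") {
    I <- .immune_at(Tm, p)
    if (!is.finite(I) || I < 0) return(NA_real_)
    return(Tm * (p[["alpha2"]] - p[["beta2"]] * Tm) - p[["gamma2"]] * I * Tm)
  }
  E <- p[["pi_src"]] / p[["theta"]]
  I <- .immune_at(Tm, p, E)
  if (!is.finite(I) || I < 0) return(NA_real_)
  val <- Tm * (p[["alpha3"]] - p[["beta2"]] * Tm) - p[["gamma2"]] * I * Tm
  if (with_host) {
    H <- (p[["alpha1"]] - p[["delta1"]] * Tm - p[["sigma1"]] * E) /
      p[["beta1"]]
    val <- val + p[["sigma2"]] * H * E
  }
  val
}

# all roots of fun on (lo, hi] by sign-scan + uniroot + Newton polish
.scan_roots <- function(fun, lo, hi, n_grid = 600L) {
  grid <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(grid, fun, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1L)) {
    v1 <- vals[i]; v2 <- vals[i + 1L]
    if (!is.finite(v1) || !is.finite(v2)) next
    if (v1 == 0) { roots <- c(roots, grid[i]); next }
    if (v1 * v2 < 0) {
      r <- stats::uniroot(fun, c(grid[i], grid[i + 1L]), tol = 1e-13)$root
      # Newton polish (numeric derivative) to drive |f| to machine level
      for (k in 1:6) {
        f0 <- fun(r)
        if (!is.finite(f0) || abs(f0) < 1e-14) break
        h <- max(1e-9, abs(r) * 1e-9)
        d <- (fun(r + h) - fun(r - h)) / (2 * h)
        if (!is.finite(d) || d == 0) break
        step <- f0 / d
        if (!is.finite(step) || abs(step) > (hi - lo)) break
        r <- r - step
      }
      roots <- c(roots, r)
    }
  }
  if (is.finite(vals[n_grid]) && vals[n_grid] == 0)
    roots <- c(roots, grid[n_grid])
  sort(unique(roots))
}

#' Dead equilibria (host-cell extinction states)
#'
#' Two flavours in each model. Type 2 ("dead2"): both host and tumor
#' extinct; estrogen-free `(0, 0, s/mu)`, estrogen model
#' `(0, 0, s/(mu + sigma3 E/(upsilon+E)), E)` with `E = pi_src/theta` —
#' always admissible (the tissue-removal state). Type 1 ("dead1"): hosts
#' extinct, tumor persists. In the estrogen-free model the tumor
#' coordinate is taken as a root of the quadratic
#' `gamma3 T^2 + (mu + omega*gamma3 - rho) T + mu*omega = 0`; a real
#' positive root needs `mu + omega*gamma3 < rho` and a nonnegative
#' discriminant, and because that quadratic is exactly the denominator of
#' the immune coordinate the state is essentially never a finite feasible
#' fixed point — it is reported with its failed conditions rather than
#' suppressed. Both quadratic branches are returned; the `+sqrt`
#' branch is labeled `"primary"`. In the estrogen model the
#' tumor-takeover state solves `T = (alpha3 - gamma2*I(T))/beta2`
#' self-consistently by bracketed root-finding.
#'
#' @inheritParams tumor_free_equilibrium
#' @return list of `estrodyn_equilibrium` objects (dead2 first).
#' @export
dead_equilibria <- function(params, model = c("estrogen_free", "estrogen")) {
  model <- .check_model(match.arg(model))
  p <- .as_params(params, model)
  out <- list()
  if (model == "estrogen_free") {
    out[[1]] <- .new_equilibrium("dead2", model,
                                 c(0, 0, p[["s"]] / p[["mu"]]), p,
                                 .cond("s_mu_positive", TRUE))
    u1 <- p[["gamma3"]]
    u2 <- p[["mu"]] + p[["omega"]] * p[["gamma3"]] - p[["rho"]]
    u3 <- p[["mu"]] * p[["omega"]]
    disc <- u2^2 - 4 * u1 * u3
    conds <- rbind(.cond("mu_plus_omega_gamma3_lt_rho", u2 < 0, -u2),
                   .cond("discriminant_nonneg", disc >= 0, disc))
    mk_dead1 <- function(Tstar, branch) {
      I <- if (is.finite(Tstar)) .immune_at(Tstar, p) else NA_real_
      st <- c(0, Tstar, I)
      cs <- rbind(conds, .cond("coordinates_finite_nonneg",
                               all(is.finite(st)) && all(st >= 0)))
      .new_equilibrium("dead1", model, st, p, cs, branch = branch)
    }
    if (u1 > 0 && disc >= 0) {
      out[[2]] <- mk_dead1((-u2 + sqrt(disc)) / (2 * u1), "primary")
      out[[3]] <- mk_dead1((-u2 - sqrt(disc)) / (2 * u1), "secondary")
    } else if (u1 == 0 && u2 < 0) {
      out[[2]] <- mk_dead1(-u3 / u2, "primary")   # linear degenerate case
    } else {
      out[[2]] <- mk_dead1(NA_real_, "primary")
    }
    return(out)
  }
  E <- p[["pi_src"]] / p[["theta"]]
  Idead2 <- p[["s"]] /
    (p[["mu"]] + if (E > 0) p[["sigma3"]] * E / (p[["upsilon"]] + E) else 0)
  out[[1]] <- .new_equilibrium("dead2", model, c(0, 0, Idead2, E), p,
                               .cond("s_positive", TRUE))
  fun <- function(Tm) .tumor_gap(Tm, p, model, with_host = FALSE)
  hi <- p[["alpha3"]] / p[["beta2"]]
  roots <- .scan_roots(fun, 1e-12, hi)
  roots <- roots[roots > 1e-10]
  if (!length(roots)) {
    st <- c(0, NA_real_, NA_real_, E)
    out[[2]] <- .new_equilibrium("dead1", model, st, p,
                                 .cond("no_root_in_bracket", FALSE),
                                 branch = "primary")
  } else {
    for (i in seq_along(roots)) {
      Tm <- roots[i]
      I <- .immune_at(Tm, p, E)
      cs <- .cond("I_lt_alpha3_over_gamma2",
                  I < p[["alpha3"]] / p[["gamma2"]],
                  p[["alpha3"]] / p[["gamma2"]] - I)
      out[[length(out) + 1L]] <-
        .new_equilibrium("dead1", model, c(0, Tm, I, E), p, cs,
                         branch = if (i == 1L) "primary" else
                           paste0("root", i))
    }
  }
  out
}

#' Coexisting equilibrium
#'
#' All populations strictly positive. The tumor and immune coordinates
#' are mutually defined, so the state is found by solving the scalar
#' equation `dT/dt = 0` in the tumor density `T` (with
#' `I(T) = s / (mu - rho*T/(omega+T) + gamma3*T [+ sigma3*E/(upsilon+E)])`
#' and, in the estrogen model, `H(T) = (alpha1 - delta1*T - sigma1*E)/beta1`
#' substituted) by bracketed root-finding over `(1e-12, Tmax]`. The host
#' coordinate follows from `dH/dt = 0`. Existence diagnostics recorded:
#' nonnegativity of `H` (equivalently
#' `(alpha2*delta1 - alpha1*beta2)/(gamma2*delta1) <= I*` in the
#' estrogen-free model), positivity of the immune denominator, and the
#' net-growth comparison `alpha2/beta2 >= alpha1/delta1` required for a
#' positive immune coordinate.
#'
#' @inheritParams tumor_free_equilibrium
#' @param all_roots if `TRUE` return a list with every root of the scalar
#'   equation (ordered by tumor density); default returns the first.
#' @return an `estrodyn_equilibrium` (label `"coexisting"`), or a list of
#'   them when `all_roots = TRUE`.
#' @export
coexisting_equilibrium <- function(params,
                                   model = c("estrogen_free", "estrogen"),
                                   all_roots = FALSE) {
  model <- .check_model(match.arg(model))
  p <- .as_params(params, model)
  E <- if (model == "estrogen") p[["pi_src"]] / p[["theta"]] else 0
  growth <- if (model == "estrogen") p[["alpha3"]] else p[["alpha2"]]
  fun <- function(Tm) .tumor_gap(Tm, p, model, with_host = TRUE)
  hi <- growth / p[["beta2"]]
  if (model == "estrogen") {
    # sigma2*H*E source can push the root beyond the logistic cap
    Hmax <- max((p[["alpha1"]] - p[["sigma1"]] * E) / p[["beta1"]], 0)
    hi <- hi + sqrt(p[["sigma2"]] * Hmax * E / p[["beta2"]]) + 1e-6
  }
  roots <- .scan_roots(fun, 1e-12, hi)
  roots <- roots[roots > 1e-10]
  sigma1E <- if (model == "estrogen") p[["sigma1"]] * E else 0
  net_growth_cond <- .cond(
    "net_tumor_growth_ge_host",
    p[["alpha2"]] / p[["beta2"]] >= p[["alpha1"]] / p[["delta1"]],
    p[["alpha2"]] / p[["beta2"]] - p[["alpha1"]] / p[["delta1"]])
  mk <- function(Tm, branch) {
    if (!is.finite(Tm)) {
      st <- if (model == "estrogen") c(NA, NA, NA, E) else c(NA, NA, NA)
      return(.new_equilibrium("coexisting", model, st, p,
                              rbind(.cond("no_root_in_bracket", FALSE),
                                    net_growth_cond),
                              branch = branch))
    }
    I <- .immune_at(Tm, p, E)
    H <- (p[["alpha1"]] - p[["delta1"]] * Tm - sigma1E) / p[["beta1"]]
    st <- if (model == "estrogen") c(H, Tm, I, E) else c(H, Tm, I)
    ith <- (p[["alpha2"]] * p[["delta1"]] - p[["alpha1"]] * p[["beta2"]]) /
      (p[["gamma2"]] * p[["delta1"]])
    conds <- rbind(
      .cond("H_nonneg", H >= 0, H),
      .cond("immune_denominator_positive",
            is.finite(I) && I > 0, I),
      .cond("I_ge_net_growth_gap", is.finite(I) && I >= ith, I - ith),
      net_growth_cond)
    .new_equilibrium("coexisting", model, st, p, conds, branch = branch)
  }
  if (!length(roots)) {
    res <- list(mk(NA_real_, "primary"))
  } else {
    res <- lapply(seq_along(roots), function(i)
      mk(roots[i], if (i == 1L) "primary" else paste0("root", i)))
  }
  if (all_roots) res else res[[1L]]
}

#' All equilibria of a model
#'
#' Convenience composition: tumor-free, type-2 dead, type-1 dead (all
#' branches), then coexisting (all roots), each residual-checked.
#'
#' @inheritParams tumor_free_equilibrium
#' @return list of `estrodyn_equilibrium` objects in fixed order.
#' @export
all_equilibria <- function(params, model = c("estrogen_free", "estrogen")) {
  model <- .check_model(match.arg(model))
  p <- .as_params(params, model)
  c(list(tumor_free_equilibrium(p, model)),
    dead_equilibria(p, model),
    coexisting_equilibrium(p, model, all_roots = TRUE))
}
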