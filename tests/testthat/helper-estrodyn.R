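# shared fixtures and independent oracles, built in code

table1 <- table1_params()
estro_defaults <- default_estrogen_params()

# central finite-difference Jacobian: independent of model_jacobian()
fd_jacobian <- function(model, state, params, h = 1e-6) {
  f <- function(x) estrodyn:::.model_rhs(model, pmax(x, 0), params)
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(state + e) - f(state - e)) / (2 * h)
  }
  dimnames(J) <- list(names(state), names(state))
  J
}

# scaled difference used for Jacobian agreement checks
jac_rel_err <- function(Ja, Jfd) max(abs(Ja - Jfd)) / max(1, max(abs(Ja)))

# random feasible state (away from the axes so FD stencils stay interior)
random_state <- function(model) {
  nm <- estrodyn:::.state_names(model)
  stats::setNames(stats::runif(length(nm), 0.05, 3), nm)
}

# parameter set construction that bypasses the structural-constraint
# validator, for white-box reduction tests (sigma = 0, alpha3 = alpha2)
raw_estrogen_params <- function(...) {
  vals <- unlist(list(...))
  base <- stats::setNames(as.numeric(estro_defaults), names(estro_defaults))
  base[names(vals)] <- vals
  structure(base, model = "estrogen", class = "estrodyn_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

condition_flag <- function(eq, name) {
  eq$conditions$satisfied[eq$conditions$name == name]
}
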