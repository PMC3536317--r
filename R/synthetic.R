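#' @title Synthetic scenarios and parameter recovery
#' @description No measured trajectories exist for these models — the
#'   only inputs the analysis consumes are parameter sets and initial
#'   conditions. This module generates everything needed to exercise the
#'   pipeline end-to-end: random feasible parameter sets drawn around the
#'   canonical values, ground-truth scenarios, noisy observed
#'   trajectories, and bounded least-squares recovery of selected
#'   parameters from those observations.
#' @name estrodyn-synthetic
NULL

#' Default sampling ranges for random parameter sets
#'
#' Each parameter is drawn uniformly from `[0.5, 1.5]` times its default
#' value ([table1_params()] / [default_estrogen_params()]), wide enough
#' to cross the tumor-free stability boundary (the resistance coefficient
#' `s*gamma2/mu` spans roughly 0.2-5.6 over these ranges while `alpha2`
#' spans 0.49-1.47) yet centred on the canonical regime.
#'
#' @param model model id.
#' @return named list of `c(lo, hi)` intervals.
#' @export
default_param_ranges <- function(model = c("estrogen_free", "estrogen")) {
  model <- .check_model(match.arg(model))
  base <- if (model == "estrogen") default_estrogen_params() else
    table1_params()
  lapply(stats::setNames(as.numeric(base), names(base)),
         function(v) c(0.5 * v, 1.5 * v))
}

#' Draw a random feasible parameter set
#'
#' Independent uniform draws per parameter, redrawn (up to 1000 times)
#' until the structural constraints hold (`sigma2 < sigma1`,
#' `alpha3 > alpha2`, positivity). Deterministic given `seed`.
#'
#' @param ranges named list of `c(lo, hi)` intervals (defaults to
#'   [default_param_ranges()]); degenerate intervals `[v, v]` pin a
#'   parameter.
#' @param model model id.
#' @param seed optional integer seed.
#' @return validated `estrodyn_params`.
#' @export
sample_parameter_set <- function(ranges = NULL,
                                 model = c("estrogen_free", "estrogen"),
                                 seed = NULL) {
  model <- .check_model(match.arg(model))
  if (is.null(ranges)) ranges <- default_param_ranges(model)
  fields <- .param_fields(model)
  missing <- setdiff(fields, names(ranges))
  if (length(missing))
    stop("missing range(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in fields) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0)
      stop("range for ", nm, " must be an ordered nonnegative interval",
           call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(1000L)) {
    draw <- vapply(fields, function(nm) {
      r <- ranges[[nm]]
      if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
    }, numeric(1))
    p <- tryCatch(validate_params(draw, model), error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  stop("infeasible ranges: 1000 draws rejected by parameter validation",
       call. = FALSE)
}

#' Define a synthetic ground-truth scenario
#'
#' @param model model id.
#' @param true_params validated parameter set (ground truth).
#' @param init initial state.
#' @param observation_times strictly increasing positive times (days);
#'   default 41 equally spaced points over `(0, t_end]`.
#' @param noise_sd observation noise standard deviation — scalar or one
#'   value per compartment, in state units.
#' @param seed integer seed driving the noise draws.
#' @param t_end horizon used for the default observation grid.
#' @return an `estrodyn_scenario`.
#' @export
make_scenario <- function(model = c("estrogen_free", "estrogen"),
                          true_params = NULL, init = NULL,
                          observation_times = NULL, noise_sd = 0,
                          seed = 1L, t_end = 30) {
  model <- .check_model(match.arg(model))
  if (is.null(true_params))
    true_params <- if (model == "estrogen") default_estrogen_params() else
      table1_params()
  p <- .as_params(true_params, model)
  if (is.null(init))
    init <- if (model == "estrogen")
      initial_state_preset("ic_estrogen_paper") else
        c(H = 1, T = 0.25, I = 0.4 / 0.29)
  init <- .check_state(init, model)
  if (is.null(observation_times))
    observation_times <- seq(t_end / 41, t_end, length.out = 41L)
  observation_times <- as.numeric(observation_times)
  if (any(observation_times <= 0) || any(diff(observation_times) <= 0))
    stop("observation_times must be positive and strictly increasing",
         call. = FALSE)
  nc <- length(.state_names(model))
  noise_sd <- rep_len(as.numeric(noise_sd), nc)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(model = model, true_params = p, init = init,
                 observation_times = observation_times,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "estrodyn_scenario")
}

#' Generate noisy observations from a scenario
#'
#' Ground truth is integrated at tight tolerance (`rtol 1e-10`,
#' `atol 1e-12`); additive Gaussian noise of the scenario's standard
#' deviation is applied per compartment and truncated at zero (densities
#' cannot be negative). Bitwise reproducible from the scenario seed.
#'
#' @param scenario an `estrodyn_scenario`.
#' @return an `estrodyn_observations`: list with `scenario`, `times`,
#'   `observed` and `truth` state matrices.
#' @export
generate_observations <- function(scenario) {
  stopifnot(inherits(scenario, "estrodyn_scenario"))
  tr <- integrate_model(scenario$model, scenario$true_params,
                        scenario$init, times = scenario$observation_times,
                        rtol = 1e-10, atol = 1e-12)
  truth <- tr$states
  set.seed(scenario$seed)
  noise <- matrix(stats::rnorm(length(truth), 0,
                               rep(scenario$noise_sd,
                                   each = nrow(truth))),
                  nrow = nrow(truth))
  observed <- pmax(truth + noise, 0)
  colnames(observed) <- colnames(truth)
  structure(list(scenario = scenario, times = scenario$observation_times,
                 observed = observed, truth = truth),
            class = "estrodyn_observations")
}

#' Recover parameters from observed trajectories
#'
#' Bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) on the stacked residuals between the model
#' solution and the observed state matrix, over a chosen subset of free
#' parameters; all other parameters are held at the scenario truth. A
#' local fit from a supplied starting guess — no global search — so the
#' guess should be in the right basin (within a few tens of percent for
#' the default scenarios).
#'
#' @param observed an `estrodyn_observations`.
#' @param free_names character vector of parameters to estimate (possibly
#'   empty: returns the truth and its residual loss).
#' @param init_guess named numeric starting values for the free
#'   parameters; defaults to the truth values.
#' @param bounds named list of `c(lo, hi)` per free parameter; default
#'   `[0.2, 5]` times the starting guess.
#' @param rtol,atol solver tolerances used inside the fit.
#' @return list with `params` (full fitted set), `estimates` (free
#'   values), `loss` (sum of squared residuals), `converged` (logical)
#'   and the raw `fit` object (or `NULL` when nothing is free).
#' @export
recover_parameters <- function(observed, free_names, init_guess = NULL,
                               bounds = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(observed, "estrodyn_observations"))
  sc <- observed$scenario
  truth <- sc$true_params
  fields <- .param_fields(sc$model)
  if (length(free_names) && !all(free_names %in% fields))
    stop("unknown free parameter(s): ",
         paste(setdiff(free_names, fields), collapse = ", "),
         call. = FALSE)
  model_states <- function(p)
    integrate_model(sc$model, p, sc$init, times = sc$observation_times,
                    rtol = rtol, atol = atol)$states
  make_params <- function(free_vals) {
    raw <- stats::setNames(as.numeric(truth), names(truth))
    raw[free_names] <- free_vals
    validate_params(raw, sc$model)
  }
  if (!length(free_names)) {
    res <- model_states(truth) - observed$observed
    return(list(params = truth, estimates = numeric(0),
                loss = sum(res^2), converged = TRUE, fit = NULL))
  }
  if (is.null(init_guess))
    init_guess <- stats::setNames(as.numeric(truth[free_names]), free_names)
  init_guess <- init_guess[free_names]
  if (is.null(bounds))
    bounds <- lapply(stats::setNames(as.numeric(init_guess), free_names),
                     function(v) c(0.2 * v, 5 * v))
  lower <- vapply(free_names, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free_names, function(nm) bounds[[nm]][2], numeric(1))
  big <- sqrt(.Machine$double.xmax) / 1e6
  resid_fn <- function(v) {
    p <- tryCatch(make_params(v), error = function(e) NULL)
    if (is.null(p)) return(rep(big, length(observed$observed)))
    sim <- tryCatch(model_states(p), error = function(e) NULL)
    if (is.null(sim)) return(rep(big, length(observed$observed)))
    as.vector(sim - observed$observed)
  }
  fit <- minpack.lm::nls.lm(par = init_guess, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- stats::setNames(as.numeric(fit$par), free_names)
  list(params = make_params(est), estimates = est,
       loss = sum(fit$fvec^2), converged = fit$info %in% 1:4, fit = fit)
}
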