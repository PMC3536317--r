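#' Integrate a model forward in time
#'
#' Adaptive Runge-Kutta 4(5) (Dormand-Prince, via [deSolve::ode()]
#' method `"ode45"`) from a feasible initial state. Output is saved on a
#' dense grid (at least 201 points unless an explicit `times` vector is
#' supplied). Negative undershoot beyond `-1e-8` in any compartment
#' aborts with an error naming the failing time — undershoot is never
#' clipped, because clipping masks model or solver defects; milder
#' undershoot is tolerated and reported in `solver_meta$warnings`.
#'
#' @param model `"estrogen_free"` or `"estrogen"`.
#' @param params validated parameter set.
#' @param init named feasible initial state (see
#'   [initial_state_preset()]).
#' @param t_end final time in days (ignored when `times` is given).
#' @param times optional explicit save times (first entry may be > 0; the
#'   integration still starts from `init` at `t = 0`).
#' @param rtol,atol relative / absolute solver tolerances.
#' @param n_out number of saved points when `times` is not given.
#' @return an `estrodyn_trajectory`: list with `model`, `params`,
#'   `times`, `states` (matrix, one row per time), `solver_meta`.
#' @examples
#' tr <- integrate_model("estrogen_free", table1_params(),
#'                       initial_state_preset("ic_estrogen_free_paper"),
#'                       t_end = 50)
#' tail(as.data.frame(tr), 1)
#' @export
integrate_model <- function(model, params, init, t_end = NULL, times = NULL,
                            rtol = 1e-8, atol = 1e-10, n_out = 201L) {
  model <- .check_model(model)
  p <- .as_params(params, model)
  y0 <- .check_state(init, model)
  if (is.null(times)) {
    if (is.null(t_end) || !is.finite(t_end) || t_end <= 0)
      stop("t_end must be a positive number of days", call. = FALSE)
    times <- seq(0, t_end, length.out = max(201L, as.integer(n_out)))
    keep <- rep(TRUE, length(times))
  } else {
    times <- as.numeric(times)
    if (any(diff(times) <= 0) || any(times < 0))
      stop("times must be nonnegative and strictly increasing",
           call. = FALSE)
    keep <- rep(TRUE, length(times))
    if (times[1] > 0) {          # integration always starts at t = 0
      times <- c(0, times)
      keep <- c(FALSE, keep)
    }
  }
  deriv <- function(t, y, parms) {
    list(if (model == "estrogen_free")
      rhs_estrogen_free(pmax(y, 0), parms) else
        rhs_estrogen(pmax(y, 0), parms))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = p,
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times))
    stop(sprintf("solver failed near t = %.6g days", sol[nrow(sol), 1]),
         call. = FALSE)
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- .state_names(model)
  if (any(!is.finite(states)))
    stop("non-finite state encountered during integration", call. = FALSE)
  minc <- min(states)
  if (minc < -1e-8) {
    bad <- which(states < -1e-8, arr.ind = TRUE)[1, 1]
    stop(sprintf("negative undershoot %.3g at t = %.6g days", minc,
                 times[bad]), call. = FALSE)
  }
  warnings <- character(0)
  if (minc < 0)
    warnings <- sprintf("numerical undershoot down to %.3g (tolerated)",
                        minc)
  structure(list(model = model, params = p,
                 times = times[keep],
                 states = states[keep, , drop = FALSE],
                 solver_meta = list(method = "ode45", rtol = rtol,
                                    atol = atol, n_steps = nrow(sol),
                                    warnings = warnings)),
            class = "estrodyn_trajectory")
}

#' @export
as.data.frame.estrodyn_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
print.estrodyn_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, %d points over [0, %.4g] days\n",
              x$model, length(x$times), max(x$times)))
  print(utils::head(as.data.frame(x), 3))
  cat("...\n")
  print(utils::tail(as.data.frame(x), 1))
  invisible(x)
}

#' Closed-form estrogen relaxation
#'
#' The estrogen compartment is decoupled (`dE/dt = pi_src - theta*E`),
#' so its solution is exactly
#' `E(t) = pi_src/theta + (E0 - pi_src/theta) * exp(-theta * t)`. Used as
#' an independent oracle for the numerical integrator.
#'
#' @param E0 initial estrogen level.
#' @param pi_src constant estrogen source (units day^-1).
#' @param theta clearance rate (day^-1), must be positive.
#' @param t time or vector of times (days).
#' @return estrogen level(s) at `t`.
#' @export
estrogen_closed_form <- function(E0, pi_src, theta, t) {
  if (!is.finite(theta) || theta <= 0)
    stop("theta must be positive", call. = FALSE)
  Einf <- pi_src / theta
  Einf + (E0 - Einf) * exp(-theta * t)
}

#' Classify the long-run outcome of a trajectory
#'
#' Matches the terminal state against the feasible equilibria by relative
#' distance and applies the precedence
#' `tumor_clearance > host_extinction > coexistence > tumor_escape >
#' undecided`. `tumor_clearance` requires terminal tumor burden below
#' `clearance_threshold` and proximity to a feasible tumor-free state;
#' `host_extinction` requires terminal host density below the threshold
#' and proximity to a feasible dead state; `tumor_escape` requires the
#' terminal tumor burden to exceed every feasible equilibrium's tumor
#' coordinate by the match tolerance while still growing
#' (`dT/dt >= 0` at the end).
#'
#' @param traj an `estrodyn_trajectory`.
#' @param equilibria list of `estrodyn_equilibrium` (e.g.
#'   [all_equilibria()] output).
#' @param clearance_threshold absolute tumor (host) density below which a
#'   compartment counts as extinct.
#' @param match_tol relative distance for matching an equilibrium.
#' @return list with `label`, `terminal_state`, `matched_equilibrium`
#'   (label or `NA`), `distance`.
#' @export
classify_outcome <- function(traj, equilibria, clearance_threshold = 1e-6,
                             match_tol = 1e-3) {
  stopifnot(inherits(traj, "estrodyn_trajectory"))
  terminal <- traj$states[nrow(traj$states), ]
  out <- function(label, eq = NULL, dist = NA_real_)
    list(label = label, terminal_state = terminal,
         matched_equilibrium = if (is.null(eq)) NA_character_ else eq$label,
         distance = dist)
  feas <- Filter(function(e) isTRUE(e$feasible), equilibria)
  if (!length(feas)) return(out("undecided"))
  dist_to <- function(e)
    max(abs(terminal - e$state)) / max(1, max(abs(e$state)))
  d <- vapply(feas, dist_to, numeric(1))
  labels <- vapply(feas, function(e) e$label, character(1))
  pick <- function(which_lab) {
    i <- which(labels %in% which_lab & d < match_tol)
    if (!length(i)) NULL else i[which.min(d[i])]
  }
  if (terminal[["T"]] < clearance_threshold) {
    i <- pick("tumor_free")
    if (!is.null(i)) return(out("tumor_clearance", feas[[i]], d[i]))
  }
  if (terminal[["H"]] < clearance_threshold) {
    i <- pick(c("dead1", "dead2"))
    if (!is.null(i)) return(out("host_extinction", feas[[i]], d[i]))
  }
  i <- pick("coexisting")
  if (!is.null(i)) return(out("coexistence", feas[[i]], d[i]))
  eqT <- vapply(feas, function(e) e$state[["T"]], numeric(1))
  dTdt <- .model_rhs(traj$model, pmax(terminal, 0), traj$params)[["T"]]
  if (all(terminal[["T"]] > eqT + match_tol * pmax(1, eqT)) && dTdt >= -1e-10)
    return(out("tumor_escape"))
  out("undecided")
}
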