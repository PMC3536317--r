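#' @title Parameter sweeps and stability boundaries
#' @name estrodyn-sweep
NULL

# leading (largest real part) eigenvalue of the tumor-free Jacobian
.tf_leading_eig <- function(params, model) {
  tf <- tumor_free_equilibrium(params, model)
  J <- model_jacobian(model, pmax(tf$state, 0), params)
  max(Re(eigen(J, only.values = TRUE)$values))
}

.set_param <- function(params, name, value) {
  model <- attr(params, "model")
  raw <- stats::setNames(as.numeric(params), names(params))
  if (!name %in% names(raw))
    stop("unknown parameter: ", name, call. = FALSE)
  raw[[name]] <- value
  validate_params(raw, model)
}

#' Sweep the estrogen source rate
#'
#' Re-solves equilibria, tumor-free local stability and a forward
#' simulation for every value of the constant estrogen source `pi_src`
#' on a grid, recording terminal populations, outcome labels and
#' tumor-free feasibility (`pi_src/theta <= alpha1/sigma1`). Stability
#' boundaries (sign changes of the leading tumor-free eigenvalue between
#' adjacent grid points) are refined by bisection. The record of whether
#' terminal tumor burden is non-decreasing — and host/immune burden
#' non-increasing — across the grid is the model's dose-response
#' readout: more exogenous estrogen, more tumor.
#'
#' @param base_params validated estrogen-model parameter set (its
#'   `pi_src` entry is overridden per grid point).
#' @param pi_values sorted nonnegative grid with at least 2 points.
#' @param init initial state for the per-point simulation.
#' @param t_end simulation horizon (days).
#' @param rtol,atol solver tolerances.
#' @return an `estrodyn_sweep`: list with `swept_parameter`, `grid`,
#'   `records` (data.frame, one row per grid point), `boundary_estimates`
#'   and the monotonicity flags `tumor_nondecreasing`,
#'   `host_nonincreasing`, `immune_nonincreasing`.
#' @export
sweep_estrogen_source <- function(base_params,
                                  pi_values = seq(0, 1, by = 0.1),
                                  init = initial_state_preset(
                                    "ic_estrogen_paper"),
                                  t_end = 100, rtol = 1e-8, atol = 1e-10) {
  p0 <- .as_params(base_params, "estrogen")
  pi_values <- as.numeric(pi_values)
  if (length(pi_values) < 2L)
    stop("pi_values must contain at least 2 points", call. = FALSE)
  if (any(diff(pi_values) <= 0) || any(pi_values < 0))
    stop("pi_values must be sorted, distinct and nonnegative",
         call. = FALSE)
  rows <- lapply(pi_values, function(pi) {
    tryCatch({
      p <- .set_param(p0, "pi_src", pi)
      tf <- tumor_free_equilibrium(p, "estrogen")
      tf_exists <- tf$conditions$satisfied[
        tf$conditions$name == "E_le_alpha1_over_sigma1"]
      lead <- .tf_leading_eig(p, "estrogen")
      tr <- integrate_model("estrogen", p, init, t_end = t_end,
                            rtol = rtol, atol = atol)
      eqs <- all_equilibria(p, "estrogen")
      oc <- classify_outcome(tr, eqs)
      term <- tr$states[nrow(tr$states), ]
      data.frame(pi_src = pi, tumor_free_exists = tf_exists,
                 leading_eigenvalue = lead, outcome = oc$label,
                 H = term[["H"]], T = term[["T"]], I = term[["I"]],
                 E = term[["E"]], failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pi_src = pi, tumor_free_exists = NA,
                 leading_eigenvalue = NA_real_,
                 outcome = paste0("error: ", conditionMessage(e)),
                 H = NA_real_, T = NA_real_, I = NA_real_, E = NA_real_,
                 failed = TRUE, stringsAsFactors = FALSE)
    })
  })
  records <- do.call(rbind, rows)
  boundaries <- numeric(0)
  le <- records$leading_eigenvalue
  for (i in seq_len(nrow(records) - 1L)) {
    if (any(is.na(le[c(i, i + 1L)]))) next
    if (sign(le[i]) != sign(le[i + 1L]) && le[i] != 0) {
      b <- tryCatch(
        find_stability_boundary(p0, "pi_src", records$pi_src[i],
                                records$pi_src[i + 1L], model = "estrogen"),
        error = function(e) NA_real_)
      if (is.finite(b)) boundaries <- c(boundaries, b)
    }
  }
  ok <- !records$failed
  structure(list(swept_parameter = "pi_src", grid = pi_values,
                 records = records, boundary_estimates = boundaries,
                 tumor_nondecreasing = all(diff(records$T[ok]) >= -1e-8),
                 host_nonincreasing = all(diff(records$H[ok]) <= 1e-8),
                 immune_nonincreasing = all(diff(records$I[ok]) <= 1e-8)),
            class = "estrodyn_sweep")
}

#' @export
print.estrodyn_sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s over [%g, %g], %d points\n", x$swept_parameter,
              min(x$grid), max(x$grid), length(x$grid)))
  print(x$records[, c("pi_src", "leading_eigenvalue", "outcome",
                      "H", "T", "I")])
  if (length(x$boundary_estimates))
    cat("stability boundaries at:",
        paste(signif(x$boundary_estimates, 8), collapse = ", "), "\n")
  invisible(x)
}

#' Locate a tumor-free stability boundary by bisection
#'
#' Bisects a single parameter between `lo` and `hi` on the sign of the
#' leading eigenvalue of the tumor-free Jacobian, to an interval width
#' below `tol`. For `alpha2` in the estrogen-free model the boundary is
#' known in closed form — `alpha2 = s*gamma2/mu`, the immune resistance
#' coefficient — which serves as a cross-check of the numerical route.
#'
#' @param params validated parameter set (values other than `param_name`
#'   held fixed).
#' @param param_name name of the parameter to vary.
#' @param lo,hi bracket; the leading eigenvalue must change sign across
#'   it.
#' @param model model id.
#' @param tol bisection interval tolerance.
#' @return the critical parameter value.
#' @examples
#' find_stability_boundary(table1_params(), "alpha2", 0.5, 2)  # s*gamma2/mu
#' @export
find_stability_boundary <- function(params, param_name, lo, hi,
                                    model = c("estrogen_free", "estrogen"),
                                    tol = 1e-8) {
  model <- .check_model(match.arg(model))
  p0 <- .as_params(params, model)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("need lo < hi", call. = FALSE)
  f <- function(v) .tf_leading_eig(.set_param(p0, param_name, v), model)
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi))
    stop("no stability boundary: leading eigenvalue has the same sign at ",
         "both bracket ends", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
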