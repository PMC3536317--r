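#' @title Reading and writing configs, reports and trajectories
#' @name estrodyn-io
NULL

#' Read / write a parameter set as a flat key:value file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), chosen by extension; keys are
#' the transliterated rate symbols (`alpha1`, `beta1`, ..., `pi_src`,
#' `theta`).
#'
#' @param path file path.
#' @param model model id the values must validate against.
#' @return `read_params_file()`: validated `estrodyn_params`.
#' @export
read_params_file <- function(path, model = c("estrogen_free", "estrogen")) {
  model <- match.arg(model)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_params(raw, model)
}

#' @rdname read_params_file
#' @param params validated parameter set to write.
#' @export
write_params_file <- function(params, path) {
  stopifnot(inherits(params, "estrodyn_params"))
  vals <- as.list(stats::setNames(as.numeric(params), names(params)))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(vals, path)
  invisible(path)
}

# JSON-ready representation of an equilibrium
.equilibrium_record <- function(eq) {
  list(label = eq$label, model = eq$model, branch = eq$branch,
       state = as.list(eq$state), feasible = eq$feasible,
       residual = eq$residual,
       conditions = lapply(seq_len(nrow(eq$conditions)), function(i)
         list(name = eq$conditions$name[i],
              satisfied = eq$conditions$satisfied[i],
              margin = eq$conditions$margin[i])))
}

.stability_record <- function(rep) {
  list(label = rep$equilibrium$label,
       classification = rep$classification,
       hypothetical = rep$hypothetical,
       eigenvalues = lapply(rep$eigenvalues, function(z)
         list(re = Re(z), im = Im(z))),
       routh_hurwitz_stable = rep$diagnostics$routh_hurwitz$stable,
       block_trace = rep$diagnostics$block_trace,
       block_det = rep$diagnostics$block_det)
}

#' Full equilibrium + stability report for a parameter set
#'
#' @param params validated parameter set.
#' @param model model id.
#' @return list (JSON-serializable) with one record per equilibrium
#'   (coordinates, feasibility, conditions, eigenvalues, classification)
#'   plus the Castillo-Chavez global verdict for the tumor-free state.
#' @export
equilibrium_report <- function(params,
                               model = c("estrogen_free", "estrogen")) {
  model <- .check_model(match.arg(model))
  p <- .as_params(params, model)
  eqs <- all_equilibria(p, model)
  recs <- lapply(eqs, function(eq) {
    r <- .equilibrium_record(eq)
    if (all(is.finite(eq$state)))
      r$stability <- .stability_record(local_stability(eq, p))
    r
  })
  glob <- castillo_chavez_global(p, model)
  list(model = model,
       params = as.list(stats::setNames(as.numeric(p), names(p))),
       equilibria = recs,
       global_stability = list(A = glob$A, Gstar_min = glob$Gstar_min,
                               H1_holds = glob$H1_holds,
                               H2_holds = glob$H2_holds,
                               verdict = glob$verdict))
}

#' Write a trajectory as CSV (plus optional metadata sidecar)
#'
#' One row per saved point, header `t,H,T,I[,E]`; solver metadata and
#' parameters go to `<path>.meta.json` when `sidecar = TRUE`.
#'
#' @param traj an `estrodyn_trajectory`.
#' @param path output CSV path.
#' @param sidecar write the JSON metadata sidecar?
#' @export
write_trajectory_csv <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "estrodyn_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (sidecar) {
    meta <- list(model = traj$model,
                 params = as.list(stats::setNames(as.numeric(traj$params),
                                                  names(traj$params))),
                 solver = traj$solver_meta)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
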