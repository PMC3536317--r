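#' Parameter sets for the tumor-immune models
#'
#' The estrogen-free model has eleven rate constants; the estrogen model
#' adds seven more. All rates are per day; the thresholds `omega` and
#' `upsilon` are in population / estrogen units. `table1_params()` returns
#' the canonical published estrogen-free set; `default_estrogen_params()`
#' extends it with the package's documented defaults for the estrogen
#' block (no published values exist for those; see the methods vignette).
#'
#' @name estrodyn-params
NULL

# Field order is the canonical serialization order.
.ef_fields <- c("alpha1", "beta1", "delta1", "alpha2", "beta2", "gamma2",
                "gamma3", "s", "rho", "omega", "mu")
.es_fields <- c(.ef_fields,
                c("alpha3", "sigma1", "sigma2", "sigma3", "upsilon",
                  "pi_src", "theta"))

.model_ids <- c("estrogen_free", "estrogen")

.check_model <- function(model) {
  if (!(is.character(model) && length(model) == 1L && model %in% .model_ids))
    stop("unknown model id: must be one of ",
         paste(sQuote(.model_ids), collapse = ", "), call. = FALSE)
  model
}

.param_fields <- function(model) {
  switch(.check_model(model), estrogen_free = .ef_fields, estrogen = .es_fields)
}

#' Validate a named list/vector of model parameters
#'
#' Checks completeness, finiteness and the structural constraints of the
#' model: every rate strictly positive except `gamma3` (tumor-driven
#' immune inactivation, may be zero) and `pi_src` (external estrogen
#' source, may be zero); for the estrogen model additionally
#' `sigma2 < sigma1` (only part of the estrogen-damaged host cells
#' survive immune clearance to join the tumor compartment) and
#' `alpha3 > alpha2` (autocrine estrogen stimulation adds to the natural
#' tumor growth rate).
#'
#' @param raw named list or numeric vector of parameter values.
#' @param model `"estrogen_free"` or `"estrogen"`.
#' @return A named numeric vector of class `estrodyn_params` with a
#'   `model` attribute, fields in canonical order.
#' @examples
#' p <- validate_params(table1_params(), "estrogen_free")
#' p[["s"]] / p[["mu"]]   # tumor-free immune equilibrium level
#' @export
validate_params <- function(raw, model = c("estrogen_free", "estrogen")) {
  model <- .check_model(match.arg(model))
  fields <- .param_fields(model)
  raw <- unlist(raw)
  if (is.null(names(raw))) stop("parameters must be named", call. = FALSE)
  missing <- setdiff(fields, names(raw))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- as.numeric(raw[fields])
  names(p) <- fields
  if (any(!is.finite(p)))
    stop("non-finite parameter(s): ",
         paste(fields[!is.finite(p)], collapse = ", "), call. = FALSE)
  may_be_zero <- c("gamma3", "pi_src")
  strict <- setdiff(fields, may_be_zero)
  bad <- strict[p[strict] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  zero_ok <- intersect(may_be_zero, fields)
  bad0 <- zero_ok[p[zero_ok] < 0]
  if (length(bad0))
    stop("parameter(s) must be nonnegative: ",
         paste(bad0, collapse = ", "), call. = FALSE)
  if (model == "estrogen") {
    if (p[["sigma2"]] >= p[["sigma1"]])
      stop("constraint violated: sigma2 < sigma1 ",
           "(damaged host cells partially cleared before joining the tumor)",
           call. = FALSE)
    if (p[["alpha3"]] <= p[["alpha2"]])
      stop("constraint violated: alpha3 > alpha2 ",
           "(autocrine stimulation adds to natural tumor growth)",
           call. = FALSE)
  }
  structure(p, model = model, class = "estrodyn_params")
}

#' @rdname estrodyn-params
#' @return `table1_params()`: named numeric vector of the published
#'   estrogen-free rates (with the configurable default `gamma3 = 0.1`).
#' @param gamma3 immune inactivation rate by tumor cells (day^-1); no
#'   published value, default 0.1 so that immune predation (`gamma2 = 0.9`)
#'   dominates inactivation.
#' @export
table1_params <- function(gamma3 = 0.1) {
  validate_params(c(
    alpha1 = 0.70, beta1 = 0.30, delta1 = 1.0,
    alpha2 = 0.98, beta2 = 0.40, gamma2 = 0.9,
    gamma3 = gamma3,
    s = 0.4, rho = 0.2, omega = 0.3, mu = 0.29
  ), "estrogen_free")
}

#' @rdname estrodyn-params
#' @param pi_src constant estrogen source rate (estrogen units day^-1).
#' @param ... overrides for any estrogen-model field.
#' @return `default_estrogen_params()`: named numeric vector extending
#'   `table1_params()` with the package defaults `alpha3 = 1.0`,
#'   `sigma1 = 0.3`, `sigma2 = 0.2`, `sigma3 = 0.1`, `upsilon = 0.5`,
#'   `theta = 0.97`. These estrogen-block values are package defaults,
#'   not published estimates.
#' @export
default_estrogen_params <- function(pi_src = 0.2, gamma3 = 0.1, ...) {
  base <- c(unclass(table1_params(gamma3 = gamma3)),
            alpha3 = 1.0, sigma1 = 0.3, sigma2 = 0.2, sigma3 = 0.1,
            upsilon = 0.5, pi_src = pi_src, theta = 0.97)
  dots <- unlist(list(...))
  if (length(dots)) {
    unknown <- setdiff(names(dots), .es_fields)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    base[names(dots)] <- dots
  }
  validate_params(base, "estrogen")
}

#' @export
print.estrodyn_params <- function(x, ...) {
  cat("<estrodyn_params> model:", attr(x, "model"), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# state vector helpers -------------------------------------------------------

.state_names <- function(model) {
  if (.check_model(model) == "estrogen") c("H", "T", "I", "E") else
    c("H", "T", "I")
}

.check_state <- function(state, model) {
  nm <- .state_names(model)
  state <- unlist(state)
  if (!is.null(names(state)) && all(nm %in% names(state)))
    state <- state[nm]
  if (length(state) != length(nm))
    stop("state must have ", length(nm), " components (",
         paste(nm, collapse = ", "), ")", call. = FALSE)
  state <- as.numeric(state)
  if (any(!is.finite(state))) stop("non-finite state component", call. = FALSE)
  if (any(state < 0)) stop("state components must be >= 0", call. = FALSE)
  stats::setNames(state, nm)
}

#' Initial-condition presets
#'
#' Published starting states: the estrogen-free runs use
#' `(H, T, I) = (1, 1e-5, s/mu = 1.379310345)`; the estrogen-model section
#' instead lists `T(0) = 10` together with `E(0) = 2`. Both presets are
#' shipped as printed; the factor-of-10^6 difference between the two tumor
#' initial loads is a discrepancy in the source material, surfaced here
#' rather than silently resolved.
#'
#' @param preset `"ic_estrogen_free_paper"` or `"ic_estrogen_paper"`.
#' @return named numeric state vector.
#' @export
initial_state_preset <- function(preset = c("ic_estrogen_free_paper",
                                            "ic_estrogen_paper")) {
  preset <- match.arg(preset)
  switch(preset,
    ic_estrogen_free_paper = c(H = 1, T = 1e-5, I = 0.4 / 0.29),
    ic_estrogen_paper      = c(H = 1, T = 10,   I = 0.4 / 0.29, E = 2))
}
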