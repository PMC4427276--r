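# Generalized mass action (GMA) models: power-law fluxes, stoichiometric
# rows, steady-state residuals, analytic Jacobians and the two objective
# functionals (production fold F1, concentration total F2).

#' Declare a model variable
#'
#' A variable is one pool or effector of a GMA model: a metabolite
#' concentration or an enzyme activity.  Its `role` says how the optimizer
#' treats it: `tunable` variables are searched by the genetic algorithm,
#' `solved` variables are determined by the Newton steady-state solver, and
#' `fixed` variables stay at their basal value.
#'
#' @param name Variable identifier, unique within a model.
#' @param role One of `"tunable"`, `"solved"`, `"fixed"`.  A variable may be
#'   both GA-tuned and Newton-solved (the GA value is then the Newton start);
#'   declare it `"tunable"` and list it in the problem's `solved` set.
#' @param basal Basal (reference) value.  Must be positive unless the
#'   variable carries a zero kinetic order in every flux, in which case it is
#'   inert and any value is allowed.
#' @param bounds Optional numeric `c(lo, hi)` with `lo <= hi`.  Required for
#'   tunable and solved variables.
#' @return A `gma_variable` list.
#' @export
gma_variable <- function(name, role = c("fixed", "tunable", "solved"),
                         basal = 1, bounds = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(basal), length(basal) == 1L, is.finite(basal))
  if (!is.null(bounds)) {
    stopifnot(is.numeric(bounds), length(bounds) == 2L, bounds[1] <= bounds[2])
    bounds <- as.numeric(bounds)
  }
  structure(list(name = name, role = role, basal = as.numeric(basal),
                 bounds = bounds),
            class = "gma_variable")
}

#' Declare a power-law flux
#'
#' A single reaction rate of the form v = gamma * prod_j x_j^(f_j), where
#' `gamma` is the rate constant and the `f_j` are kinetic orders (real, may
#' be negative or fractional).
#'
#' @param name Flux identifier, unique within a model.
#' @param rate_constant Positive rate constant gamma.
#' @param kinetic_orders Named numeric vector: variable name -> exponent.
#'   Variables not named carry exponent zero.
#' @return A `power_law_flux` list.
#' @export
power_law_flux <- function(name, rate_constant, kinetic_orders = numeric()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(rate_constant), length(rate_constant) == 1L,
            is.finite(rate_constant), rate_constant > 0)
  if (length(kinetic_orders)) {
    stopifnot(is.numeric(kinetic_orders), !is.null(names(kinetic_orders)),
              all(nzchar(names(kinetic_orders))),
              !anyDuplicated(names(kinetic_orders)),
              all(is.finite(kinetic_orders)))
  }
  structure(list(name = name, rate_constant = as.numeric(rate_constant),
                 kinetic_orders = kinetic_orders),
            class = "power_law_flux")
}

#' Declare a stoichiometric row
#'
#' One pool balance dX/dt = sum of signed flux contributions.
#'
#' @param pool Pool (variable) name the row balances.
#' @param terms Named numeric vector: flux name -> signed stoichiometric
#'   coefficient (e.g. `c(V_GAPD = 2, V_PK = -1)`).
#' @return A `stoich_row` list.
#' @export
stoich_row <- function(pool, terms) {
  stopifnot(is.character(pool), length(pool) == 1L,
            is.numeric(terms), length(terms) >= 1L,
            !is.null(names(terms)), all(nzchar(names(terms))),
            all(is.finite(terms)), all(terms != 0))
  structure(list(pool = pool, terms = terms), class = "stoich_row")
}

#' Build a GMA model
#'
#' Assembles variables, power-law fluxes and stoichiometric rows into a
#' validated model object.  Internally the model caches log rate constants,
#' the kinetic-order matrix F (fluxes x variables) and the stoichiometric
#' matrix S (rows x fluxes) so that flux and residual evaluation are dense
#' matrix products in log space.
#'
#' @param variables List of [gma_variable()] objects (order defines the state
#'   vector layout).
#' @param fluxes List of [power_law_flux()] objects.
#' @param rows List of [stoich_row()] objects.
#' @param metadata Free-form named list kept with the model and serialized
#'   with it.
#' @return A `gma_model` object.
#' @export
gma_model <- function(variables, fluxes, rows, metadata = list()) {
  stopifnot(is.list(variables), length(variables) >= 1L,
            is.list(fluxes), length(fluxes) >= 1L,
            is.list(rows), length(rows) >= 1L, is.list(metadata))
  lapply(variables, function(v) stopifnot(inherits(v, "gma_variable")))
  lapply(fluxes, function(v) stopifnot(inherits(v, "power_law_flux")))
  lapply(rows, function(v) stopifnot(inherits(v, "stoich_row")))

  var_names <- vapply(variables, `[[`, character(1), "name")
  flux_names <- vapply(fluxes, `[[`, character(1), "name")
  if (anyDuplicated(var_names))
    stop("duplicate variable names: ",
         paste(unique(var_names[duplicated(var_names)]), collapse = ", "))
  if (anyDuplicated(flux_names))
    stop("duplicate flux names: ",
         paste(unique(flux_names[duplicated(flux_names)]), collapse = ", "))

  nvar <- length(var_names); nflux <- length(flux_names)
  Fmat <- matrix(0, nflux, nvar, dimnames = list(flux_names, var_names))
  for (i in seq_len(nflux)) {
    ko <- fluxes[[i]]$kinetic_orders
    if (length(ko)) {
      bad <- setdiff(names(ko), var_names)
      if (length(bad))
        stop("flux '", flux_names[i], "' references unknown variable(s): ",
             paste(bad, collapse = ", "))
      Fmat[i, names(ko)] <- ko
    }
  }
  Smat <- matrix(0, length(rows), nflux,
                 dimnames = list(vapply(rows, `[[`, character(1), "pool"),
                                 flux_names))
  for (k in seq_along(rows)) {
    tm <- rows[[k]]$terms
    bad <- setdiff(names(tm), flux_names)
    if (length(bad))
      stop("row '", rows[[k]]$pool, "' references unknown flux(es): ",
           paste(bad, collapse = ", "))
    Smat[k, names(tm)] <- Smat[k, names(tm)] + tm
  }

  for (v in variables) {
    needs_pos <- any(Fmat[, v$name] != 0)
    if (needs_pos && v$basal <= 0)
      stop("variable '", v$name, "' has non-positive basal value ",
           "but a nonzero kinetic order")
    if (v$role %in% c("tunable", "solved") && is.null(v$bounds))
      stop("variable '", v$name, "' is ", v$role, " but has no bounds")
  }

  structure(list(
    variables = variables, fluxes = fluxes, rows = rows, metadata = metadata,
    var_names = var_names, flux_names = flux_names,
    loggamma = log(vapply(fluxes, `[[`, numeric(1), "rate_constant")),
    F = Fmat, S = Smat,
    Sp = pmax(Smat, 0), Sn = pmax(-Smat, 0)
  ), class = "gma_model")
}

#' @export
print.gma_model <- function(x, ...) {
  roles <- vapply(x$variables, `[[`, character(1), "role")
  cat("GMA model: ", length(x$variables), " variables (",
      sum(roles == "tunable"), " tunable, ", sum(roles == "fixed"),
      " fixed), ", length(x$fluxes), " power-law fluxes, ",
      length(x$rows), " stoichiometric rows\n", sep = "")
  invisible(x)
}

# ---- state helpers ---------------------------------------------------------

#' Basal state of a model
#'
#' @param model A `gma_model`.
#' @return Named numeric vector of basal values in variable order.
#' @export
basal_state <- function(model) {
  stats::setNames(vapply(model$variables, `[[`, numeric(1), "basal"),
                  model$var_names)
}

# Coerce a state to a full named vector in model variable order; unnamed
# vectors of full length are taken positionally.
as_model_state <- function(model, state) {
  nvar <- length(model$var_names)
  if (is.null(names(state))) {
    if (length(state) != nvar)
      stop("state has length ", length(state), ", expected ", nvar)
    return(stats::setNames(as.numeric(state), model$var_names))
  }
  bad <- setdiff(names(state), model$var_names)
  if (length(bad))
    stop("state names unknown to model: ", paste(bad, collapse = ", "))
  out <- basal_state(model)
  out[names(state)] <- as.numeric(state)
  out
}

# Domain check: every variable with a nonzero kinetic order anywhere must be
# strictly positive (real exponents need a positive base).
check_state_domain <- function(model, state) {
  active <- colSums(model$F != 0) > 0
  bad <- which(active & !(state > 0))
  if (length(bad))
    stop("non-positive value for variable '", model$var_names[bad[1]],
         "' which carries a nonzero kinetic order", call. = FALSE)
  invisible(TRUE)
}

# ---- evaluation ------------------------------------------------------------

# Batch flux evaluation on an nvar x m state matrix, log-space accumulation.
# Values are clamped away from zero so boundary states (a tunable at a lower
# bound of 0) degrade to ~0 or ~Inf fluxes instead of NaN.
flux_batch <- function(model, X) {
  LX <- log(pmax(X, .Machine$double.xmin))
  exp(model$loggamma + model$F %*% LX)
}

residual_batch <- function(model, X) model$S %*% flux_batch(model, X)

#' Evaluate all power-law fluxes at a state
#'
#' Each flux is gamma_i * prod_j x_j^(f_ij), accumulated as a sum of
#' logarithms to avoid under/overflow with large kinetic orders.
#'
#' @param model A `gma_model`.
#' @param state Named (or positional, full-length) numeric state vector;
#'   entries with a nonzero kinetic order must be strictly positive.
#' @return Named numeric vector of flux values, one per model flux.
#' @export
evaluate_fluxes <- function(model, state) {
  x <- as_model_state(model, state)
  check_state_domain(model, x)
  lx <- log(x)
  lx[!is.finite(lx)] <- 0  # inert variables only (zero column in F)
  drop(exp(model$loggamma + model$F %*% lx))
}

#' Steady-state residuals
#'
#' The time derivative of each pool: residual_k = sum over row k of
#' coefficient * flux.  A state is a steady state iff all residuals vanish.
#'
#' @inheritParams evaluate_fluxes
#' @return Numeric vector, one entry per stoichiometric row, named by pool.
#' @export
steady_state_residuals <- function(model, state) {
  v <- evaluate_fluxes(model, state)
  drop(model$S %*% v)
}

#' Jacobian of the steady-state residuals
#'
#' Analytic derivatives of the residual vector with respect to a subset of
#' variables.  In linear space d v_i / d x_j = f_ij v_i / x_j; in log space
#' (u_j = ln x_j) d residual_k / d u_j = sum_i s_ki f_ij v_i, which is the
#' natural form for the Newton solver.
#'
#' @inheritParams evaluate_fluxes
#' @param wrt Variable indices or names to differentiate with respect to.
#' @param space `"linear"` (d/dx) or `"log"` (d/d ln x).
#' @return Matrix with one row per stoichiometric row and one column per
#'   `wrt` variable.
#' @export
residual_jacobian <- function(model, state, wrt = seq_along(model$var_names),
                              space = c("linear", "log")) {
  space <- match.arg(space)
  x <- as_model_state(model, state)
  check_state_domain(model, x)
  idx <- resolve_var_index(model, wrt)
  if (!length(idx)) stop("'wrt' must name at least one variable")
  v <- evaluate_fluxes(model, x)
  J <- model$S %*% (model$F[, idx, drop = FALSE] * v)
  if (space == "linear")
    J <- sweep(J, 2L, x[idx], "/")
  dimnames(J) <- list(rownames(model$S), model$var_names[idx])
  J
}

resolve_var_index <- function(model, which) {
  if (is.character(which)) {
    idx <- match(which, model$var_names)
    if (anyNA(idx))
      stop("unknown variable(s): ", paste(which[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(which)
    if (any(idx < 1L | idx > length(model$var_names)))
      stop("variable index out of range")
    idx
  }
}

# ---- objectives ------------------------------------------------------------

#' Objective specification for pathway optimization
#'
#' Pairs the target flux (whose fold increase over a reference state is the
#' production objective F1) with the subset of components whose summed
#' concentration is the cost objective F2.
#'
#' @param model A `gma_model`.
#' @param target_flux Name of the flux to maximize.
#' @param f2_subset Variable names or indices summed into F2.
#' @param reference_state State used as the denominator of the production
#'   fold (defaults to the basal state).
#' @return An `objective_spec` list.
#' @export
objective_spec <- function(model, target_flux, f2_subset,
                           reference_state = basal_state(model)) {
  if (!(target_flux %in% model$flux_names))
    stop("target flux '", target_flux, "' not in model")
  f2_idx <- if (length(f2_subset)) resolve_var_index(model, f2_subset)
            else integer()
  ref <- as_model_state(model, reference_state)
  ref_flux <- evaluate_fluxes(model, ref)[[target_flux]]
  structure(list(target_flux = target_flux, f2_index = f2_idx,
                 f2_names = model$var_names[f2_idx],
                 reference_state = ref, reference_flux = ref_flux),
            class = "objective_spec")
}

#' Production fold F1
#'
#' Target flux at `state` divided by the target flux at the objective's
#' reference state; dimensionless, 1 at the reference itself.
#'
#' @param model A `gma_model`.
#' @param objective An [objective_spec()].
#' @param state State vector.
#' @return The fold change (scalar).
#' @export
production_fold <- function(model, objective, state) {
  v <- evaluate_fluxes(model, state)
  v[[objective$target_flux]] / objective$reference_flux
}

#' Concentration total F2
#'
#' Sum of the state values over the objective's component subset; the cost
#' functional minimized by the two-level cooperative scheme.
#'
#' @inheritParams production_fold
#' @return Scalar sum (0 for an empty subset).
#' @export
concentration_total <- function(objective, state) {
  if (!length(objective$f2_index)) return(0)
  x <- state
  if (!is.null(names(x)) && all(objective$f2_names %in% names(x)))
    sum(as.numeric(x[objective$f2_names]))
  else
    sum(as.numeric(x[objective$f2_index]))
}
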