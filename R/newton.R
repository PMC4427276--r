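# Newton-Raphson steady-state solver.
#
# The square subsystem (as many solved variables as stoichiometric rows) is
# solved in log-concentration space, which keeps every iterate strictly
# positive without projection.  Each row is split into its positive part
# P_k(x) (production) and negative part N_k(x) (consumption); the iteration
# drives g_k = ln P_k - ln N_k to zero, whose Jacobian entries are
# flux-weighted kinetic orders.  For S-system rows (one production and one
# consumption term) g is exactly linear in log concentrations, so a single
# undamped step lands on the root.  Convergence is always certified on the
# raw residual max-norm, the quantity the steady-state condition constrains.

#' Newton solver settings
#'
#' @param max_iterations Maximum number of Newton steps (default 50).
#' @param tolerance Convergence threshold on the residual max-norm
#'   (default 1e-6).
#' @param damping Step multiplier in (0, 1]; 1 is a full Newton step.
#' @param max_step Cap on the log-space step max-norm per iteration; tames
#'   wild starts proposed by the genetic algorithm.
#' @param step_norm_stop If `TRUE`, also stop once the damped step max-norm
#'   falls below `tolerance` (off by default; the residual criterion is the
#'   contract).
#' @param condition_limit Condition-number estimate above which the Jacobian
#'   is declared rank-deficient.
#' @return A `newton_config` list.
#' @export
newton_config <- function(max_iterations = 50L, tolerance = 1e-6,
                          damping = 1.0, max_step = 5.0,
                          step_norm_stop = FALSE, condition_limit = 1e12) {
  stopifnot(max_iterations >= 1L, tolerance > 0, damping > 0, damping <= 1,
            max_step > 0, condition_limit > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, damping = damping,
                 max_step = max_step, step_norm_stop = isTRUE(step_norm_stop),
                 condition_limit = condition_limit),
            class = "newton_config")
}

#' Residual max-norm
#'
#' The max-norm of [steady_state_residuals()]; this is the quantity the
#' Newton solver compares against its tolerance.
#'
#' @inheritParams evaluate_fluxes
#' @return Scalar, >= 0.
#' @export
residual_norm <- function(model, state) {
  max(abs(steady_state_residuals(model, state)))
}

new_newton_result <- function(status, iterations, residual_norm, state,
                              step_norms, residual_norms) {
  structure(list(status = status, iterations = as.integer(iterations),
                 residual_norm = residual_norm, state = state,
                 step_norms = step_norms, residual_norms = residual_norms),
            class = "newton_result")
}

#' @export
print.newton_result <- function(x, ...) {
  cat("Newton result: ", x$status, " after ", x$iterations,
      " iteration(s), residual max-norm ",
      format(x$residual_norm, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Solve the steady-state subsystem by Newton-Raphson
#'
#' Iterates on the designated `solve_for` variables (all others held fixed)
#' until the steady-state residual max-norm drops below the tolerance, the
#' iteration budget is exhausted, or the Jacobian degenerates.  Failures are
#' reported in the result status, never thrown, except for the structural
#' error of a non-square system.
#'
#' @param model A `gma_model`.
#' @param start Strictly positive starting state (full vector).
#' @param solve_for Variable names or indices; must number exactly as many
#'   as the model has stoichiometric rows.
#' @param config A [newton_config()].
#' @return A `newton_result` with fields `status` (one of `"converged"`,
#'   `"max_iterations"`, `"singular_jacobian"`, `"domain_error"`),
#'   `iterations`, `residual_norm`, `state`, `step_norms` and
#'   `residual_norms` (one entry per evaluation, including the start).
#' @export
newton_solve <- function(model, start, solve_for, config = newton_config()) {
  stopifnot(inherits(config, "newton_config"))
  idx <- resolve_var_index(model, solve_for)
  nrows <- nrow(model$S)
  if (length(idx) != nrows)
    stop("non-square system: ", length(idx), " solved variable(s) for ",
         nrows, " stoichiometric row(s)")
  x <- as_model_state(model, start)
  if (any(x[idx] <= 0) || !all(is.finite(x)))
    return(new_newton_result("domain_error", 0L, Inf, x, numeric(), numeric()))

  Fs <- model$F[, idx, drop = FALSE]
  u <- log(x[idx])
  step_norms <- numeric()
  res_norms <- numeric()
  iterations <- 0L
  status <- "max_iterations"

  repeat {
    lx <- log(pmax(x, .Machine$double.xmin))
    v <- exp(model$loggamma + model$F %*% lx)
    r <- drop(model$S %*% v)
    rn <- max(abs(r))
    res_norms <- c(res_norms, rn)
    if (!is.finite(rn)) { status <- "domain_error"; break }
    if (rn < config$tolerance) { status <- "converged"; break }
    if (iterations >= config$max_iterations) { status <- "max_iterations"; break }

    P <- drop(model$Sp %*% v); N <- drop(model$Sn %*% v)
    if (any(P <= 0) || any(N <= 0)) { status <- "domain_error"; break }
    vF <- Fs * drop(v)
    J <- (model$Sp %*% vF) / P - (model$Sn %*% vF) / N
    if (!all(is.finite(J))) { status <- "domain_error"; break }
    rc <- tryCatch(rcond(J), error = function(e) 0)
    if (!is.finite(rc) || rc < 1 / config$condition_limit) {
      status <- "singular_jacobian"; break
    }
    du <- drop(solve(J, log(P) - log(N)))
    mx <- max(abs(du))
    if (mx > config$max_step) du <- du * (config$max_step / mx)
    du <- config$damping * du
    u <- u - du
    x[idx] <- exp(u)
    iterations <- iterations + 1L
    step_norms <- c(step_norms, max(abs(du)))
    if (config$step_norm_stop && max(abs(du)) < config$tolerance) {
      rn <- residual_norm(model, x)
      res_norms <- c(res_norms, rn)
      status <- if (rn < config$tolerance) "converged" else "max_iterations"
      break
    }
  }
  new_newton_result(status, iterations, res_norms[length(res_norms)], x,
                    step_norms, res_norms)
}
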