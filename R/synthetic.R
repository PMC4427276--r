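# Deterministic generators of GMA models with planted (exactly known)
# steady-state roots, and of tiny grid-enumerable optimization problems.
# They make the Newton solver and the optimizer testable without the
# bundled benchmarks and carry no biological-realism claims.

#' Generate a GMA model with a planted steady-state root
#'
#' Draws random power-law fluxes (exponents uniform in `exponent_range`,
#' log-uniform rate constants) and signed unit/half/double stoichiometric
#' coefficients, picks a random positive root, then rescales each row's
#' negative-coefficient terms by the ratio of the positive to the negative
#' flux sum at the root, so every row vanishes at the root to machine
#' precision.  Degenerate draws are redrawn with bounded retries: rows
#' whose coefficients all share one sign, and models whose steady-state
#' Jacobian (with respect to the solved variables, at the root) is too
#' ill-conditioned for local Newton convergence.  Deterministic given
#' `seed`.
#'
#' @param seed Integer seed.
#' @param n_vars Number of variables.
#' @param n_rows Number of stoichiometric rows (`<= n_vars`); the first
#'   `n_rows` variables are marked solved, the rest fixed.
#' @param terms_per_row Fluxes per row (`>= 2`); 2 yields S-system form
#'   (exactly one production and one consumption term), for which the
#'   steady-state equations are linear in log concentrations.
#' @param exponent_range Range for kinetic orders.
#' @return A `planted_model`: `model` (a `gma_model`), `root` (named state
#'   with residual max-norm < 1e-12), `seed`.
#' @export
generate_planted_model <- function(seed, n_vars = 4L, n_rows = 2L,
                                   terms_per_row = 3L,
                                   exponent_range = c(-1.5, 1.5)) {
  stopifnot(n_rows >= 1L, n_rows <= n_vars, terms_per_row >= 2L,
            length(exponent_range) == 2L,
            exponent_range[1] <= exponent_range[2])
  set.seed(seed)
  for (attempt in 1:50) {
    pm <- draw_planted_model(n_vars, n_rows, terms_per_row, exponent_range)
    # row-normalized conditioning of the solved subsystem at the root: a
    # nearly rank-deficient subsystem loses its root under tiny
    # perturbations of the fixed variables, which defeats the purpose of
    # planting one
    J <- residual_jacobian(pm$model, pm$root, wrt = seq_len(n_rows),
                           space = "log")
    rn <- sqrt(rowSums(J^2))
    rc <- if (all(rn > 1e-8))
      tryCatch(rcond(J / rn), error = function(e) 0)
    else 0
    if (is.finite(rc) && rc > 1e-2) {
      pm$seed <- seed
      return(pm)
    }
  }
  stop("failed to draw a well-conditioned planted model after 50 tries")
}

draw_planted_model <- function(n_vars, n_rows, terms_per_row,
                               exponent_range) {
  vn <- paste0("x", seq_len(n_vars))
  root <- stats::setNames(exp(stats::runif(n_vars, -0.5, 0.5)), vn)

  fluxes <- list(); rows <- list()
  for (k in seq_len(n_rows)) {
    coeffs <- NULL
    for (try in 1:100) {
      cand <- sample(c(-2, -1, -0.5, 0.5, 1, 2), terms_per_row, replace = TRUE)
      if (any(cand > 0) && any(cand < 0)) { coeffs <- cand; break }
    }
    if (is.null(coeffs))
      stop("failed to draw a mixed-sign stoichiometric row after 100 tries")
    fl <- vector("list", terms_per_row)
    vals <- numeric(terms_per_row)
    for (t in seq_len(terms_per_row)) {
      expo <- stats::runif(n_vars, exponent_range[1], exponent_range[2])
      fl[[t]] <- power_law_flux(sprintf("v%d_%d", k, t),
                                exp(stats::runif(1, -0.7, 0.7)),
                                stats::setNames(expo, vn))
      vals[t] <- fl[[t]]$rate_constant * prod(root^expo)
    }
    pos <- coeffs > 0
    P <- sum(coeffs[pos] * vals[pos])
    N <- sum(-coeffs[!pos] * vals[!pos])
    coeffs[!pos] <- coeffs[!pos] * (P / N)
    fluxes <- c(fluxes, fl)
    rows[[k]] <- stoich_row(vn[k], stats::setNames(
      coeffs, vapply(fl, `[[`, character(1), "name")))
  }
  variables <- lapply(seq_len(n_vars), function(i)
    gma_variable(vn[i],
                 role = if (i <= n_rows) "solved" else "fixed",
                 basal = root[i],
                 bounds = if (i <= n_rows) root[i] * c(0.5, 2)))
  model <- gma_model(variables, fluxes, rows,
                     metadata = list(generator = "planted"))
  structure(list(model = model, root = root, seed = NA_integer_),
            class = "planted_model")
}

#' Generate a tiny grid-enumerable optimization problem
#'
#' A planted three-variable, one-row model whose first two variables are
#' tunable on narrow bounds around the root and whose third is
#' Newton-solved.  With the 6-bit preset the genetic search space is
#' exactly the 64 x 64 decode grid, so [toy_grid_optimum()] can find the
#' global optimum by exhaustive enumeration.
#'
#' @param seed Integer seed (drives both the model draw and the preset
#'   seed).
#' @return An `ncga_problem` with a small preset (30 members, 60
#'   generations, 6 bits per variable, penalty mode).
#' @export
generate_toy_problem <- function(seed = 1L) {
  pm <- generate_planted_model(seed, n_vars = 3L, n_rows = 1L,
                               terms_per_row = 3L,
                               exponent_range = c(-1.5, 1.5))
  root <- pm$root
  variables <- list(
    gma_variable("x1", "tunable", root[["x1"]], root[["x1"]] * c(0.6, 1.8)),
    gma_variable("x2", "tunable", root[["x2"]], root[["x2"]] * c(0.6, 1.8)),
    gma_variable("x3", "solved", root[["x3"]], root[["x3"]] * c(0.5, 2))
  )
  model <- gma_model(variables, pm$model$fluxes, pm$model$rows,
                     metadata = c(pm$model$metadata, list(toy = TRUE)))
  target <- model$flux_names[which(model$S[1, ] > 0)[1]]
  obj <- objective_spec(model, target, c("x1", "x2"),
                        reference_state = root)
  preset <- ncga_config(
    genetic = genetic_config(population_size = 30L, bits_per_variable = 6L,
                             crossover_points = 1L, mutation_rate = 0.3),
    max_generations = 60L, penalty_weight = 10, seed = seed)
  ncga_problem(model, obj, solved = "x3", preset = preset,
               metadata = list(seed = seed, generator = "toy"))
}

#' Exhaustive grid optimum of a two-tunable problem
#'
#' Enumerates every decodable value combination of the two tunable
#' variables (the full 2^L x 2^L grid of the binary encoding), evaluates
#' each state with the same scoring used by the optimizer, and returns the
#' best entry.  Serves as an enumeration oracle for the genetic search.
#'
#' @param problem An `ncga_problem` with exactly two tunable variables.
#' @param config Scoring configuration (default: the problem preset).
#' @return List: `f1`, `f2`, `score`, `state`, `n_grid`.
#' @export
toy_grid_optimum <- function(problem, config = problem$preset) {
  stopifnot(length(problem$tunable_names) == 2L)
  L <- config$genetic$bits_per_variable
  vals <- lapply(1:2, function(j) {
    b <- problem$tunable_bounds[[j]]
    b[1] + (0:(2^L - 1)) / (2^L - 1) * (b[2] - b[1])
  })
  grid <- expand.grid(vals[[1]], vals[[2]])
  x0 <- basal_state(problem$model)
  X <- matrix(x0, length(x0), nrow(grid), dimnames = list(names(x0), NULL))
  X[problem$tunable_index[1], ] <- grid[[1]]
  X[problem$tunable_index[2], ] <- grid[[2]]
  ev <- eval_states(problem, X, config)
  ib <- best_eval_index(ev)
  list(f1 = ev$f1_fold[ib], f2 = ev$f2_total[ib],
       score = ev$penalized_score[ib],
       state = stats::setNames(X[, ib], rownames(X)),
       n_grid = nrow(grid))
}
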