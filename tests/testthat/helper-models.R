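# Shared fixtures, all built in code.

# v = gamma * x^2 feeding a single pool.
single_flux_model <- function(gamma = 3) {
  gma_model(
    variables = list(gma_variable("x", "solved", 1, c(0.1, 10))),
    fluxes = list(power_law_flux("v", gamma, c(x = 2))),
    rows = list(stoich_row("x", c(v = 1)))
  )
}

case1_best <- function() {
  load_solution(system.file("extdata", "case1_best_reported.json",
                            package = "ncga"))
}

case2_best <- function() {
  load_solution(system.file("extdata", "case2_best_reported.json",
                            package = "ncga"))
}

# A problem whose tunable variables are pinned to exact values via
# degenerate [v, v] decode bounds, so a cooperative chromosome decodes to
# the given state exactly (any bits).
pinned_subpops <- function(problem, values, n = 2L, L = 4L) {
  lapply(seq_along(problem$tunable_names), function(j) {
    nm <- problem$tunable_names[j]
    sp <- ncga:::new_subpopulation(nm, problem$tunable_index[j],
                                   c(values[[nm]], values[[nm]]), n, L)
    sp
  })
}

# Shrink a preset for fast structural tests.
modify_config_for_test <- function(config, pop = 10L, gens = NULL, ...) {
  ncga:::modify_ncga_config(
    config, genetic = list(population_size = pop),
    max_generations = if (is.null(gens)) config$max_generations else gens,
    roster_size = NULL, ...)
}

# Independent oracle: direct log-linear solve of an S-system-form model
# (every row one production and one consumption term) for the first
# n_rows variables, all others fixed at `fixed_state`.
ssystem_loglinear_solve <- function(model, fixed_state, solve_idx) {
  nr <- nrow(model$S)
  A <- matrix(0, nr, length(solve_idx))
  b <- numeric(nr)
  lx <- log(fixed_state)
  other <- setdiff(seq_along(model$var_names), solve_idx)
  for (k in seq_len(nr)) {
    terms <- model$S[k, ]
    ip <- which(terms > 0); im <- which(terms < 0)
    stopifnot(length(ip) == 1L, length(im) == 1L)
    fp <- model$F[ip, ]; fn <- model$F[im, ]
    lhs <- fp - fn
    rhs <- log(-terms[im] * model$fluxes[[im]]$rate_constant /
                 (terms[ip] * model$fluxes[[ip]]$rate_constant))
    A[k, ] <- lhs[solve_idx]
    b[k] <- rhs - sum(lhs[other] * lx[other])
  }
  u <- solve(A, b)
  out <- fixed_state
  out[solve_idx] <- exp(u)
  out
}
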