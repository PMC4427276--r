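# The NCGA main loop: binary sub-populations (one per tunable variable),
# representative selection, cooperative-chromosome evaluation against the
# flux objective under the steady-state constraint, credit assignment back
# to sub-chromosomes, and reproduction.  Also the single-chromosome baseline
# GA used for comparison.

BIG_PENALTY <- 1e15      # out-of-bounds / failed evaluations rank below everything
RESID_CAP <- 1e12        # residual norms are capped before weighting so that
                         # in-bounds scores stay above the out-of-bounds band

#' NCGA run settings
#'
#' @param genetic A [genetic_config()].
#' @param newton A [newton_config()]; its tolerance also defines steady-state
#'   feasibility in penalty mode.
#' @param max_generations Generation budget.  Generations sweep the
#'   sub-populations round-robin: each generation evolves one
#'   sub-population, whose members are evaluated in the context of the other
#'   sub-populations' representatives.
#' @param representative_selection How the context representative of each
#'   non-evolving sub-population is chosen: `"fitness"` takes the
#'   best-credited member, resolving near-ties toward the lowest decoded
#'   concentration (the sub-chromosome fitness; this is the second level of
#'   the two-level scheme and exerts the F2-minimization pressure);
#'   `"random"` draws a member uniformly each generation.
#' @param steady_state_mode `"penalty"` scores candidates as
#'   F1 - penalty_weight * residual max-norm; `"refine"` runs the Newton
#'   solver on the solved-variable subset and scores F1 at the refined state,
#'   treating non-convergence or out-of-bounds refinements as infeasible.
#' @param penalty_weight Weight on the residual norm in penalty mode.
#' @param roster_size Cooperative chromosomes evaluated per generation
#'   (default: the population size, so every member of the evolving
#'   sub-population is tested each generation).
#' @param context_exploration Fraction of roster entries in which one
#'   randomly chosen collaborator coordinate of the context is redrawn
#'   uniformly within its bounds instead of taken from the incumbent best
#'   solution (in `"fitness"` mode; the final tenth of the generation
#'   budget always evaluates in the fixed incumbent context).  Pure
#'   incumbent-context evaluation is coordinate ascent, which stalls on
#'   diagonal ridges of the penalized score; perturbing one collaborator at
#'   a time restores pairwise joint moves without wasting evaluations on
#'   fully random contexts.
#' @param stall_generations Early stop once the best record is feasible and
#'   unimproved (relative 1e-6) for this many generations.
#' @param seed Integer seed; all randomness of a run flows from it.
#' @return An `ncga_config` list.
#' @export
ncga_config <- function(genetic = genetic_config(), newton = newton_config(),
                        max_generations = 300L,
                        representative_selection = c("fitness", "random"),
                        steady_state_mode = c("penalty", "refine"),
                        penalty_weight = 10, roster_size = NULL,
                        stall_generations = 50L, seed = 1L,
                        context_exploration = 0.95) {
  representative_selection <- match.arg(representative_selection)
  steady_state_mode <- match.arg(steady_state_mode)
  stopifnot(inherits(genetic, "genetic_config"),
            inherits(newton, "newton_config"),
            max_generations >= 1L, penalty_weight > 0,
            stall_generations >= 1L,
            context_exploration >= 0, context_exploration <= 1)
  if (is.null(roster_size)) roster_size <- genetic$population_size
  stopifnot(roster_size >= 1L, roster_size <= genetic$population_size)
  structure(list(genetic = genetic, newton = newton,
                 max_generations = as.integer(max_generations),
                 representative_selection = representative_selection,
                 steady_state_mode = steady_state_mode,
                 penalty_weight = penalty_weight,
                 roster_size = as.integer(roster_size),
                 stall_generations = as.integer(stall_generations),
                 seed = as.integer(seed),
                 context_exploration = context_exploration),
            class = "ncga_config")
}

# Merge user overrides into a config (used by presets and the CLI).
modify_ncga_config <- function(config, ...) {
  ov <- list(...)
  args <- unclass(config)
  for (nm in names(ov)) {
    if (nm %in% c("genetic", "newton") && is.list(ov[[nm]]) &&
        !inherits(ov[[nm]], paste0(nm, "_config"))) {
      args[[nm]] <- do.call(paste0(nm, "_config"),
                            utils::modifyList(unclass(args[[nm]]), ov[[nm]]))
    } else args[[nm]] <- ov[[nm]]
  }
  do.call(ncga_config, args)
}

#' Sub-chromosome fitness
#'
#' The fitness of a sub-chromosome is its decoded concentration value;
#' lower is fitter.  This is the first level of the two-level scheme: it
#' exerts the minimization pressure on the concentration total F2.
#'
#' @param sub 0/1 integer bit vector.
#' @param bounds `c(lo, hi)` decode bounds.
#' @param gray Decode as Gray code.
#' @return The decoded value.
#' @export
sub_fitness <- function(sub, bounds, gray = FALSE) {
  decode_bits(sub, bounds[1], bounds[2], gray = gray)
}

# ---- cooperative evaluation ------------------------------------------------

col_max_abs <- function(R) {
  out <- abs(R[1L, ])
  k <- nrow(R)
  if (k > 1L) for (i in 2:k) out <- pmax(out, abs(R[i, ]))
  out
}

# Total box violation of the tunable coordinates, per column of X.
bound_violation <- function(problem, X) {
  viol <- numeric(ncol(X))
  for (j in seq_along(problem$tunable_names)) {
    x <- X[problem$tunable_index[j], ]
    b <- problem$tunable_bounds[[j]]
    viol <- viol + pmax(0, b[1] - x) + pmax(0, x - b[2])
  }
  viol
}

# Batch evaluation of full states (nvar x m matrix) under the problem's
# objective.  Returns a data.frame with one row per state.
eval_states <- function(problem, X, config) {
  model <- problem$model
  obj <- problem$objective
  tol <- config$newton$tolerance
  m <- ncol(X)

  if (config$steady_state_mode == "penalty") {
    V <- flux_batch(model, X)
    rn <- col_max_abs(model$S %*% V)
    f1 <- V[obj$target_flux, ] / obj$reference_flux
    f2 <- colSums(X[obj$f2_index, , drop = FALSE])
    viol <- bound_violation(problem, X)
    score <- f1 - config$penalty_weight * pmin(rn, RESID_CAP)
    oob <- viol > 0
    score[oob] <- -BIG_PENALTY - viol[oob]
    score[!is.finite(score)] <- -BIG_PENALTY * 10
    data.frame(f1_fold = f1, f2_total = f2, residual_norm = rn,
               feasible = (rn < tol) & !oob, penalized_score = score)
  } else {
    out <- data.frame(f1_fold = numeric(m), f2_total = numeric(m),
                      residual_norm = numeric(m), feasible = logical(m),
                      penalized_score = numeric(m))
    solved_idx <- resolve_var_index(model, problem$solved_names)
    for (i in seq_len(m)) {
      res <- newton_solve(model, X[, i], problem$solved_names, config$newton)
      x <- res$state
      viol <- bound_violation(problem, matrix(x, ncol = 1L))
      for (k in solved_idx) {
        b <- model$variables[[k]]$bounds
        if (!is.null(b))
          viol <- viol + max(0, b[1] - x[k]) + max(0, x[k] - b[2])
      }
      ok <- res$status == "converged" && viol == 0
      f1 <- production_fold(model, obj, pmax(x, .Machine$double.xmin))
      out$f1_fold[i] <- f1
      out$f2_total[i] <- concentration_total(obj, x)
      out$residual_norm[i] <- res$residual_norm
      out$feasible[i] <- ok
      out$penalized_score[i] <- if (ok) f1 else
        -BIG_PENALTY - (if (res$status == "converged") viol
                        else min(res$residual_norm, RESID_CAP))
    }
    out
  }
}

fitness_record <- function(row) {
  list(f1_fold = row$f1_fold, f2_total = row$f2_total,
       residual_norm = row$residual_norm, feasible = row$feasible,
       penalized_score = row$penalized_score)
}

#' Evaluate a cooperative chromosome
#'
#' Builds the full candidate state (tunable variables from the decoded
#' representatives, every other variable at its basal value) and scores it.
#' In penalty mode the score is F1 minus the weighted steady-state residual
#' max-norm, with out-of-bounds states ranked below every in-bounds state.
#' In refine mode the Newton solver first refines the solved-variable subset
#' from the proposed values; non-convergence or a refined value outside its
#' bounds makes the record infeasible, ranked by violation magnitude.
#'
#' @param coop A `cooperative_chromosome` (see [assemble_cooperative()]).
#' @param problem An optimization problem (see [ncga_problem()]).
#' @param config An [ncga_config()].
#' @return A fitness record: `f1_fold`, `f2_total`, `residual_norm`,
#'   `feasible`, `penalized_score`.
#' @export
evaluate_cooperative <- function(coop, problem, config = problem$preset) {
  x <- basal_state(problem$model)
  ds <- coop$decoded_state
  x[names(ds)] <- ds
  fitness_record(eval_states(problem, matrix(x, ncol = 1L), config)[1L, ])
}

# Near-tie comparison used for best-so-far updates, elitism and tie-breaks:
# challenger b beats incumbent a on penalized score; within relative 1e-6
# of a tie, the lower concentration total wins.
record_improves <- function(a, b, rel = 1e-6) {
  if (is.null(a)) return(TRUE)
  gap <- b$penalized_score - a$penalized_score
  if (abs(gap) <= rel * max(1, abs(a$penalized_score), abs(b$penalized_score)))
    return(b$f2_total < a$f2_total)
  gap > 0
}

# Index of the best row of an eval_states frame under the same rule.
best_eval_index <- function(ev, rel = 1e-6) {
  s <- ev$penalized_score
  top <- max(s)
  near <- which(abs(s - top) <= rel * max(1, abs(s), na.rm = TRUE))
  near[which.min(ev$f2_total[near])]
}

# ---- representative selection ---------------------------------------------

# Roster as an index matrix (roster_size x n_subpops).  values is the list
# of decoded-value vectors per sub-population.
roster_indices <- function(values, mode, roster_size, n_members) {
  ns <- length(values)
  if (mode == "fitness") {
    M <- matrix(0L, roster_size, ns)
    for (j in seq_len(ns)) M[, j] <- order(values[[j]])[seq_len(roster_size)]
    M
  } else {
    matrix(sample.int(n_members, roster_size * ns, replace = TRUE),
           roster_size, ns)
  }
}

#' Select cooperative-chromosome representatives
#'
#' In `"fitness"` mode the members of every sub-population are ranked
#' ascending by their decoded value (the sub-chromosome fitness, lowest
#' first) and the i-th roster entry combines the i-th ranked member of each
#' sub-population; the concentration totals along the roster are therefore
#' non-decreasing.  In `"random"` mode combinations are drawn uniformly with
#' replacement.
#'
#' @param subpops List of sub-populations.
#' @param mode `"fitness"` or `"random"`.
#' @param roster_size Number of cooperative chromosomes to assemble.
#' @param gray Decode as Gray code.
#' @return List of `cooperative_chromosome` objects.
#' @export
select_representatives <- function(subpops, mode = c("fitness", "random"),
                                   roster_size = 1L, gray = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(subpops[[1L]]$bits)
  stopifnot(all(vapply(subpops, function(s) nrow(s$bits), 0L) == n),
            roster_size >= 1L, roster_size <= n)
  values <- lapply(subpops, subpop_values, gray = gray)
  M <- roster_indices(values, mode, roster_size, n)
  lapply(seq_len(roster_size), function(i)
    assemble_cooperative(subpops, M[i, ], gray = gray))
}

# ---- credit comparison -----------------------------------------------------

# Vectorized preference between credited members: higher credit wins; within
# a relative 1e-6 near-tie (or when neither has ever been credited), the
# lower decoded concentration wins (the F2 pressure of the two-level scheme).
credit_prefers <- function(ca, va, cb, vb, rel = 1e-6) {
  fin <- is.finite(ca) & is.finite(cb)
  near <- (fin & abs(ca - cb) <= rel * pmax(1, abs(ca), abs(cb))) |
    (!is.finite(ca) & !is.finite(cb))
  ifelse(near, va <= vb, ca > cb)
}

# The k most preferred members of a sub-population: best credit, near-ties
# resolved toward the lowest decoded value; uncredited populations fall back
# to pure concentration ranking.
pick_best_members <- function(credit, values, k = 1L, rel = 1e-6) {
  avail <- seq_along(credit)
  out <- integer(k)
  for (i in seq_len(k)) {
    fin <- is.finite(credit[avail])
    cand <- if (any(fin)) {
      best <- max(credit[avail][fin])
      avail[fin & credit[avail] >= best - rel * max(1, abs(best))]
    } else avail
    pick <- cand[which.min(values[cand])]
    out[i] <- pick
    avail <- avail[avail != pick]
  }
  out
}

# ---- reproduction ----------------------------------------------------------

# One reproduction cycle of a sub-population.  Mating pool: binary
# tournament on credited cooperative score (survival pressure, ties toward
# low concentration); the pool is then ordered by sub-chromosome fitness
# (decoded value, ascending) and adjacent members are paired for crossover,
# followed by per-individual mutation.  The elitism_count best-credited
# parents re-enter unchanged and keep their credit; all other credits reset
# until the sub-population's next evaluation turn.
reproduce_subpop <- function(sp, credit, values, gcfg) {
  n <- nrow(sp$bits)
  a <- sample.int(n, n, replace = TRUE)
  b <- sample.int(n, n, replace = TRUE)
  pool <- ifelse(credit_prefers(credit[a], values[a], credit[b], values[b]),
                 a, b)
  pool <- pool[order(values[pool])]
  np <- n %/% 2L
  odd <- pool[2L * seq_len(np) - 1L]
  even <- pool[2L * seq_len(np)]
  ch <- crossover_pairs(sp$bits[odd, , drop = FALSE],
                        sp$bits[even, , drop = FALSE],
                        gcfg$crossover_points)
  children <- matrix(0L, n, ncol(sp$bits))
  children[2L * seq_len(np) - 1L, ] <- ch$a
  children[2L * seq_len(np), ] <- ch$b
  if (n %% 2L == 1L) children[n, ] <- sp$bits[pool[n], ]
  children <- mutate_pop(children, gcfg$mutation_rate)
  e <- gcfg$elitism_count
  n_imm <- min(floor(gcfg$immigrant_fraction * n), n - e)
  if (n_imm > 0L) {
    L <- ncol(sp$bits)
    children[seq.int(n - e - n_imm + 1L, n - e), ] <-
      matrix(sample(0:1, n_imm * L, replace = TRUE), n_imm, L)
  }
  new_credit <- rep(-Inf, n)
  if (e > 0L) {
    elite <- pick_best_members(credit, values, e)
    slots <- seq.int(n - e + 1L, n)
    children[slots, ] <- sp$bits[elite, , drop = FALSE]
    new_credit[slots] <- credit[elite]
  }
  sp$bits <- children
  list(sp = sp, credit = new_credit)
}

# ---- engine ----------------------------------------------------------------

init_subpops <- function(problem, config) {
  gcfg <- config$genetic
  lapply(seq_along(problem$tunable_names), function(j)
    new_subpopulation(problem$tunable_names[j], problem$tunable_index[j],
                      problem$tunable_bounds[[j]],
                      gcfg$population_size, gcfg$bits_per_variable))
}

#' Initialize the NCGA algorithm state
#'
#' Seeds the RNG, draws the initial random sub-populations and clears all
#' credits (no member has yet participated in a cooperative evaluation).
#'
#' @param problem An [ncga_problem()].
#' @param config An [ncga_config()].
#' @return Algorithm state consumed by [step_generation()].
#' @export
init_ncga <- function(problem, config = problem$preset) {
  set.seed(config$seed)
  subpops <- init_subpops(problem, config)
  list(subpops = subpops,
       credits = lapply(subpops, function(s) rep(-Inf, nrow(s$bits))),
       generation = 0L, best = NULL, best_state = NULL, stall = 0L)
}

# Build the full-state matrix for a roster index matrix M.
roster_states <- function(problem, values, M) {
  x0 <- basal_state(problem$model)
  X <- matrix(x0, length(x0), nrow(M),
              dimnames = list(names(x0), NULL))
  for (j in seq_len(ncol(M)))
    X[problem$tunable_index[j], ] <- values[[j]][M[, j]]
  X
}

#' Advance the NCGA by one generation
#'
#' Generations sweep the sub-populations round-robin.  Each member of the
#' evolving sub-population is assembled into a cooperative chromosome with
#' representatives of every other sub-population -- the incumbent best
#' solution's coordinates for most roster entries, randomly drawn members
#' for an exploration fraction (all entries, in the `"random"` ablation
#' mode) -- then evaluated and credited with its cooperative score.  The
#' best-so-far record is updated, then the evolving sub-population
#' reproduces: binary tournament on credit (ties toward low concentration),
#' mating pool ordered ascending by sub-chromosome fitness and paired
#' adjacently, k-point crossover, per-individual mutation, and elitism.
#' Population sizes are conserved.
#'
#' @param algo Algorithm state from [init_ncga()] or a previous step.
#' @param problem An [ncga_problem()].
#' @param config An [ncga_config()].
#' @return List with the updated `algo` and the generation `record`
#'   (generation index, best-so-far fitness, mean roster F2, feasible count).
#' @export
step_generation <- function(algo, problem, config = problem$preset) {
  gcfg <- config$genetic
  subpops <- algo$subpops
  nsub <- length(subpops)
  n <- gcfg$population_size
  j <- (algo$generation %% nsub) + 1L
  values <- lapply(subpops, subpop_values, gray = gcfg$gray_code)

  # incumbent context: the best joint solution seen so far; before the
  # first evaluation, the lowest-concentration member of each
  # sub-population (the literal lowest-sub-fitness-first selection)
  incumbent <- if (!is.null(algo$best_state))
    unname(algo$best_state[problem$tunable_index])
  else vapply(values, min, 0)

  m <- config$roster_size
  x0 <- basal_state(problem$model)
  X <- matrix(x0, length(x0), m, dimnames = list(names(x0), NULL))
  X[problem$tunable_index, ] <- matrix(incumbent, nsub, m)
  if (config$representative_selection == "random") {
    # ablation mode: one representative drawn uniformly per sub-population
    # each generation (shared by the whole roster, so within-generation
    # credits stay comparable)
    for (o in seq_len(nsub)[-j])
      X[problem$tunable_index[o], ] <- values[[o]][sample.int(n, 1L)]
  } else if (nsub > 1L) {
    # exploration entries: one collaborator coordinate redrawn uniformly
    # within its bounds, enabling pairwise joint moves off the incumbent;
    # the final tenth of the budget polishes in a fixed context
    frac <- if (algo$generation >= 0.9 * config$max_generations) 0
            else config$context_exploration
    rand_entry <- which(stats::runif(m) < frac)
    if (length(rand_entry)) {
      others <- seq_len(nsub)[-j]
      o_pick <- others[sample.int(length(others), length(rand_entry),
                                  replace = TRUE)]
      for (i in seq_along(rand_entry)) {
        b <- problem$tunable_bounds[[o_pick[i]]]
        X[problem$tunable_index[o_pick[i]], rand_entry[i]] <-
          stats::runif(1L, b[1], b[2])
      }
    }
  }
  X[problem$tunable_index[j], ] <- values[[j]][seq_len(m)]
  ev <- eval_states(problem, X, config)

  # fresh credit for the tested members of the evolving sub-population
  algo$credits[[j]][seq_len(m)] <- ev$penalized_score

  ib <- best_eval_index(ev)
  challenger <- fitness_record(ev[ib, ])
  if (record_improves(algo$best, challenger)) {
    algo$best <- challenger
    algo$best_state <- stats::setNames(X[, ib], rownames(X))
    algo$stall <- 0L
  } else algo$stall <- algo$stall + 1L

  # concentration total of the representative set nominated this
  # generation by the configured rule (lowest sub-fitness first, or a
  # uniform draw in the random ablation mode) -- the trajectory the
  # two-level evaluation concept is judged by
  rep_vals <- if (config$representative_selection == "fitness")
    vapply(values, min, 0)
  else vapply(values, function(v) v[sample.int(length(v), 1L)], 0)
  rep_state <- x0
  rep_state[problem$tunable_index] <- rep_vals
  algo$generation <- algo$generation + 1L
  record <- list(generation = algo$generation, best = algo$best,
                 selected_f2 = ev$f2_total[ib],
                 representative_f2 = concentration_total(problem$objective,
                                                         rep_state),
                 mean_f2 = mean(ev$f2_total),
                 n_feasible = sum(ev$feasible))

  rep_out <- reproduce_subpop(subpops[[j]], algo$credits[[j]], values[[j]],
                              gcfg)
  algo$subpops[[j]] <- rep_out$sp
  algo$credits[[j]] <- rep_out$credit
  list(algo = algo, record = record)
}

history_frame <- function(records) {
  data.frame(
    generation = vapply(records, `[[`, 0L, "generation"),
    best_score = vapply(records, function(r) r$best$penalized_score, 0),
    best_f1 = vapply(records, function(r) r$best$f1_fold, 0),
    best_f2 = vapply(records, function(r) r$best$f2_total, 0),
    best_residual = vapply(records, function(r) r$best$residual_norm, 0),
    best_feasible = vapply(records, function(r) r$best$feasible, TRUE),
    selected_f2 = vapply(records, `[[`, 0, "selected_f2"),
    representative_f2 = vapply(records, `[[`, 0, "representative_f2"),
    mean_f2 = vapply(records, `[[`, 0, "mean_f2"),
    n_feasible = vapply(records, `[[`, 0L, "n_feasible")
  )
}

new_ncga_run <- function(algo, records, terminated_by, config, method) {
  structure(list(best_state = algo$best_state, best_fitness = algo$best,
                 history = history_frame(records),
                 terminated_by = terminated_by, seed = config$seed,
                 config = config, method = method,
                 final_subpops = algo$subpops),
            class = "ncga_run")
}

#' @export
print.ncga_run <- function(x, ...) {
  cat(x$method, " run (seed ", x$seed, "): ", nrow(x$history),
      " generation(s), terminated by ", x$terminated_by, "\n",
      "  best F1 fold ", format(x$best_fitness$f1_fold, digits = 6),
      ", F2 total ", format(x$best_fitness$f2_total, digits = 8),
      ", residual max-norm ",
      format(x$best_fitness$residual_norm, digits = 4),
      if (x$best_fitness$feasible) " (feasible)" else "", "\n", sep = "")
  invisible(x)
}

#' Run the Newton cooperative genetic algorithm
#'
#' Runs the cooperative co-evolutionary loop until the generation budget is
#' exhausted or the best record is feasible and has stalled for
#' `stall_generations` generations.  Fully reproducible from `config$seed`.
#'
#' @param problem An [ncga_problem()].
#' @param config An [ncga_config()]; defaults to the problem's preset.
#' @return An `ncga_run`: best state and fitness record, per-generation
#'   history, termination reason, and the final sub-populations.
#' @export
run_ncga <- function(problem, config = problem$preset) {
  algo <- init_ncga(problem, config)
  records <- vector("list", config$max_generations)
  terminated_by <- "max_generations"
  g <- 0L
  while (g < config$max_generations) {
    st <- step_generation(algo, problem, config)
    algo <- st$algo
    g <- g + 1L
    records[[g]] <- st$record
    if (algo$best$feasible && algo$stall >= config$stall_generations) {
      terminated_by <- "constraint_optimum"
      break
    }
  }
  new_ncga_run(algo, records[seq_len(g)], terminated_by, config, "NCGA")
}

# ---- baseline: single-chromosome GA ----------------------------------------

#' Run the single-chromosome baseline GA
#'
#' The traditional-GA comparator: one population in which each individual
#' concatenates the bit strings of all tunable variables (chromosome length
#' = bits_per_variable x number of tunables).  Evaluation, scoring and
#' budget are identical to [run_ncga()]; selection is a binary tournament on
#' the penalized score with elitism.
#'
#' @inheritParams run_ncga
#' @return An `ncga_run` (method `"baselineGA"`).
#' @export
run_baseline_ga <- function(problem, config = problem$preset) {
  set.seed(config$seed)
  gcfg <- config$genetic
  n <- gcfg$population_size
  L <- gcfg$bits_per_variable
  ntun <- length(problem$tunable_names)
  Ltot <- L * ntun
  B <- matrix(sample(0:1, n * Ltot, replace = TRUE), n, Ltot)
  segs <- lapply(seq_len(ntun), function(j) ((j - 1L) * L + 1L):(j * L))

  decode_pop <- function(B) {
    X <- matrix(basal_state(problem$model), length(problem$model$var_names),
                nrow(B), dimnames = list(problem$model$var_names, NULL))
    for (j in seq_len(ntun)) {
      b <- problem$tunable_bounds[[j]]
      X[problem$tunable_index[j], ] <-
        decode_matrix(B[, segs[[j]], drop = FALSE], b[1], b[2],
                      gray = gcfg$gray_code)
    }
    X
  }

  algo <- list(generation = 0L, best = NULL, best_state = NULL, stall = 0L)
  records <- vector("list", config$max_generations)
  terminated_by <- "max_generations"
  g <- 0L
  while (g < config$max_generations) {
    X <- decode_pop(B)
    ev <- eval_states(problem, X[, seq_len(config$roster_size), drop = FALSE],
                      config)
    idx_eval <- seq_len(config$roster_size)
    ib <- best_eval_index(ev)
    challenger <- fitness_record(ev[ib, ])
    if (record_improves(algo$best, challenger)) {
      algo$best <- challenger
      algo$best_state <- stats::setNames(X[, idx_eval[ib]],
                                         problem$model$var_names)
      algo$stall <- 0L
    } else algo$stall <- algo$stall + 1L
    algo$generation <- g + 1L
    records[[g + 1L]] <- list(generation = algo$generation, best = algo$best,
                              selected_f2 = ev$f2_total[ib],
                              representative_f2 = ev$f2_total[ib],
                              mean_f2 = mean(ev$f2_total),
                              n_feasible = sum(ev$feasible))
    g <- g + 1L
    if (algo$best$feasible && algo$stall >= config$stall_generations) {
      terminated_by <- "constraint_optimum"
      break
    }
    # reproduction: tournament on score, adjacent pairing, crossover, mutation
    score <- rep(-Inf, n)
    score[idx_eval] <- ev$penalized_score
    a <- sample.int(n, n, replace = TRUE)
    b <- sample.int(n, n, replace = TRUE)
    pool <- ifelse(score[a] >= score[b], a, b)  # mates pair in drawn order
    np <- n %/% 2L
    odd <- pool[2L * seq_len(np) - 1L]
    even <- pool[2L * seq_len(np)]
    ch <- crossover_pairs(B[odd, , drop = FALSE], B[even, , drop = FALSE],
                          gcfg$crossover_points)
    children <- matrix(0L, n, Ltot)
    children[2L * seq_len(np) - 1L, ] <- ch$a
    children[2L * seq_len(np), ] <- ch$b
    if (n %% 2L == 1L) children[n, ] <- B[pool[n], ]
    children <- mutate_pop(children, gcfg$mutation_rate)
    if (gcfg$elitism_count > 0L) {
      elite <- order(score, decreasing = TRUE)[seq_len(gcfg$elitism_count)]
      children[seq.int(n - gcfg$elitism_count + 1L, n), ] <-
        B[elite, , drop = FALSE]
    }
    B <- children
  }
  run <- new_ncga_run(c(algo, list(subpops = NULL)), records[seq_len(g)],
                      terminated_by, config, "baselineGA")
  run$final_subpops <- NULL
  run$chromosome_length <- Ltot
  run
}
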