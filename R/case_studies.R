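# Optimization problems: the pairing of a GMA model with an objective,
# variable roles, bounds and an algorithm preset; the two bundled benchmark
# problems; and a solution-validation utility.

#' Define an optimization problem
#'
#' @param model A `gma_model`; variables with role `"tunable"` (and their
#'   bounds) define the search space.
#' @param objective An [objective_spec()].
#' @param solved Variable names the Newton solver determines in refine mode;
#'   must number exactly as many as the model has stoichiometric rows.  A
#'   solved variable may also be tunable, in which case its GA value is the
#'   Newton starting point.
#' @param preset Default [ncga_config()] for this problem.
#' @param metadata Free-form named list (kept on serialization).
#' @param validation_bounds Optional named list `variable -> c(lo, hi)` that
#'   [validate_solution()] reports against when it differs from the search
#'   bounds (e.g. a published range that the published solution itself
#'   violates).
#' @return An `ncga_problem`.
#' @export
ncga_problem <- function(model, objective, solved = character(),
                         preset = ncga_config(), metadata = list(),
                         validation_bounds = NULL) {
  stopifnot(inherits(model, "gma_model"), inherits(objective, "objective_spec"),
            inherits(preset, "ncga_config"))
  roles <- vapply(model$variables, `[[`, character(1), "role")
  tun <- which(roles == "tunable")
  if (!length(tun)) stop("problem has no tunable variables")
  if (length(solved)) {
    if (length(solved) != nrow(model$S))
      stop("solved set has ", length(solved), " variable(s) but the model has ",
           nrow(model$S), " stoichiometric row(s)")
    resolve_var_index(model, solved)
  }
  structure(list(
    model = model, objective = objective,
    tunable_names = model$var_names[tun],
    tunable_index = tun,
    tunable_bounds = lapply(model$variables[tun], `[[`, "bounds"),
    solved_names = solved,
    fixed_values = basal_state(model)[roles == "fixed"],
    preset = preset, metadata = metadata,
    validation_bounds = validation_bounds
  ), class = "ncga_problem")
}

#' @export
print.ncga_problem <- function(x, ...) {
  cat("Optimization problem: maximize fold of flux '",
      x$objective$target_flux, "'\n", sep = "")
  cat("  ", length(x$tunable_names), " tunable variable(s): ",
      paste(x$tunable_names, collapse = ", "), "\n", sep = "")
  cat("  F2 subset: ", paste(x$objective$f2_names, collapse = ", "),
      "\n", sep = "")
  if (length(x$solved_names))
    cat("  Newton-solved (refine mode): ",
        paste(x$solved_names, collapse = ", "), "\n", sep = "")
  inv <- x$preset
  cat("  preset: ", inv$genetic$population_size, " members x ",
      length(x$tunable_names), " sub-populations, ",
      inv$max_generations, " generations, ", inv$genetic$crossover_points,
      "-point crossover, mutation ", inv$genetic$mutation_rate,
      ", mode ", inv$steady_state_mode, "\n", sep = "")
  invisible(x)
}

extdata <- function(file) {
  p <- system.file("extdata", file, package = "ncga")
  if (!nzchar(p)) stop("bundled file not found: ", file)
  p
}

#' Benchmark problem 1: ethanol production in S. cerevisiae
#'
#' The five-pool GMA model of anaerobic fermentation in
#' \emph{Saccharomyces cerevisiae} (glucose uptake through pyruvate kinase,
#' with polysaccharide and polyol branches), in coordinates normalized to
#' the basal steady state.  Objective: maximize the fold change of the
#' pyruvate kinase flux V_PK; the concentration total sums the five
#' metabolites X1-X5 and the six tuned enzymes Y1-Y6.  Metabolites are
#' bounded to [0.8, 1.2] (about 20% around basal), enzymes to [0, 50]; Y7
#' and Y8 stay fixed at 1.
#'
#' @return An `ncga_problem` with the benchmark preset (11 sub-populations
#'   of 150, 300 generations, 2-point crossover, mutation 0.3).
#' @export
build_case1 <- function() {
  load_problem(extdata("case1.yaml"))
}

#' Benchmark problem 2: tryptophan biosynthesis in E. coli
#'
#' The three-pool GMA model of the tryptophan operon in
#' \emph{Escherichia coli} (mRNA, anthranilate synthase, tryptophan), with
#' mRNA/enzyme/trp concentrations normalized to basal and the remaining
#' components in model units.  Objective: maximize the fold change of the
#' tryptophan production flux V_34; the concentration total sums X1-X6 and
#' X8.  Seven components are tunable: X1-X3 in [0.8, 1.2], X4 in
#' [0, 0.00624], X5 in [4, 10], X6 in [500, 5000], X8 in [0, 1000].
#'
#' The published component range for X5 is [5, 10], but the published best
#' solution (X5 = 4.0172) and the comparator solutions (4.0) lie below it;
#' the bundled search bounds therefore open the range to [4, 10] while
#' [validate_solution()] keeps reporting against the published [5, 10].
#' Set `x5_published_bounds = TRUE` to search the published range instead.
#'
#' @param x5_published_bounds Use the published [5, 10] search range for X5.
#' @return An `ncga_problem` with the benchmark preset (7 sub-populations
#'   of 150, 350 generations, 1-point crossover, mutation 0.2).
#' @export
build_case2 <- function(x5_published_bounds = FALSE) {
  problem <- load_problem(extdata("case2.yaml"))
  if (isTRUE(x5_published_bounds)) {
    j <- match("X5", problem$tunable_names)
    problem$tunable_bounds[[j]] <- c(5, 10)
    i <- match("X5", problem$model$var_names)
    problem$model$variables[[i]]$bounds <- c(5, 10)
  }
  problem
}

#' Validate a candidate solution
#'
#' Pure function of its inputs: checks every tunable variable against the
#' problem's validation bounds (the published ranges), evaluates the
#' steady-state residual vector and both objectives.
#'
#' @param problem An `ncga_problem`.
#' @param state Named (possibly partial: tunables only) or full state
#'   vector.
#' @return An `ncga_validation` report: `bounds` data frame (variable,
#'   value, lo, hi, in_bounds), `residuals`, `residual_norm`, `f1_fold`,
#'   `f2_total`.
#' @export
validate_solution <- function(problem, state) {
  x <- as_model_state(problem$model, state)
  vb <- lapply(seq_along(problem$tunable_names), function(j) {
    nm <- problem$tunable_names[j]
    b <- problem$validation_bounds[[nm]]
    if (is.null(b)) problem$tunable_bounds[[j]] else as.numeric(b)
  })
  val <- x[problem$tunable_index]
  lo <- vapply(vb, `[`, 0, 1L); hi <- vapply(vb, `[`, 0, 2L)
  bounds <- data.frame(variable = problem$tunable_names, value = unname(val),
                       lo = lo, hi = hi,
                       in_bounds = val >= lo & val <= hi,
                       row.names = NULL)
  r <- steady_state_residuals(problem$model, x)
  structure(list(bounds = bounds, residuals = r,
                 residual_norm = max(abs(r)),
                 f1_fold = production_fold(problem$model, problem$objective, x),
                 f2_total = concentration_total(problem$objective, x),
                 state = x),
            class = "ncga_validation")
}

#' @export
print.ncga_validation <- function(x, ...) {
  cat("Solution validation\n")
  cat("  F1 fold:", format(x$f1_fold, digits = 6),
      "  F2 total:", format(x$f2_total, digits = 8), "\n")
  cat("  residual max-norm:", format(x$residual_norm, digits = 4), "\n")
  nb <- x$bounds[!x$bounds$in_bounds, ]
  if (nrow(nb) == 0L) cat("  all", nrow(x$bounds), "bounds pass\n")
  else {
    cat("  bound violations:\n")
    for (i in seq_len(nrow(nb)))
      cat(sprintf("    %s = %g outside [%g, %g]\n", nb$variable[i],
                  nb$value[i], nb$lo[i], nb$hi[i]))
  }
  invisible(x)
}

# ---- problem serialization -------------------------------------------------

#' Read an optimization problem from a YAML config
#'
#' The config names a model file (resolved relative to the config's
#' directory), the objective, the solved set, the algorithm preset, optional
#' validation bounds, and metadata.  The reference state is stored
#' explicitly in the config, never inferred.
#'
#' @param path Path to a problem YAML file.
#' @return An `ncga_problem`.
#' @export
load_problem <- function(path) {
  if (!file.exists(path)) stop("no such problem file: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("model", "objective"))
    if (is.null(cfg[[key]])) stop("problem config missing '", key, "'")
  model <- load_model(file.path(dirname(path), cfg$model))
  ref <- if (is.null(cfg$objective$reference_state)) basal_state(model)
         else vapply(cfg$objective$reference_state, as.numeric, 0)
  obj <- objective_spec(model, cfg$objective$target_flux,
                        unlist(cfg$objective$f2_subset), ref)
  preset <- if (is.null(cfg$preset)) ncga_config()
            else do.call(modify_ncga_config, c(list(ncga_config()), cfg$preset))
  vb <- if (is.null(cfg$validation_bounds)) NULL
        else lapply(cfg$validation_bounds, as.numeric)
  ncga_problem(model, obj, solved = as.character(unlist(cfg$solved)),
               preset = preset,
               metadata = if (is.null(cfg$metadata)) list() else cfg$metadata,
               validation_bounds = vb)
}

#' Write an optimization problem to a YAML config plus model JSON
#'
#' @param problem An `ncga_problem`.
#' @param path Output YAML path; the model is written next to it.
#' @param model_file File name for the model JSON (defaults to the config
#'   name with a `.json` extension).
#' @return `path`, invisibly.
#' @export
save_problem <- function(problem, path, model_file = NULL) {
  if (is.null(model_file))
    model_file <- paste0(sub("\\.ya?ml$", "", basename(path)), "_model.json")
  save_model(problem$model, file.path(dirname(path), model_file))
  pr <- unclass(problem$preset)
  cfg <- list(
    model = model_file,
    objective = list(
      target_flux = problem$objective$target_flux,
      f2_subset = as.list(problem$objective$f2_names),
      reference_state = lapply(as.list(problem$objective$reference_state),
                               dec_string)
    ),
    solved = as.list(problem$solved_names),
    preset = list(
      max_generations = pr$max_generations,
      representative_selection = pr$representative_selection,
      steady_state_mode = pr$steady_state_mode,
      penalty_weight = pr$penalty_weight,
      roster_size = pr$roster_size,
      stall_generations = pr$stall_generations,
      seed = pr$seed,
      genetic = unclass(pr$genetic),
      newton = unclass(pr$newton)
    ),
    metadata = problem$metadata
  )
  if (!is.null(problem$validation_bounds))
    cfg$validation_bounds <- lapply(problem$validation_bounds, as.list)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a solution vector from JSON
#'
#' Solution files map variable names to values (decimal strings or
#' numbers), e.g. the bundled published best solutions
#' `case1_best_reported.json` and `case2_best_reported.json`.
#'
#' @param path Path to a solution JSON file.
#' @return Named numeric vector.
#' @export
load_solution <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vapply(obj, as.numeric, 0)
}
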