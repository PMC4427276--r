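# Repeated seeded runs, summary statistics over runs, and the paired
# ablation experiments (cooperative vs single-chromosome representation;
# fitness-based vs random representative selection).

#' Repeated seeded optimization runs
#'
#' Run `i` uses seed `base_seed + i - 1`; statistics aggregate the best
#' record of every run.  The standard deviation is the sample standard
#' deviation.  If `out_dir` is given, a per-run CSV and a summary CSV are
#' written there.
#'
#' @param problem An `ncga_problem`.
#' @param config An [ncga_config()] (default: the problem preset).
#' @param n_runs Number of independent runs.
#' @param base_seed First seed.
#' @param method `"ncga"` or `"baseline"` (single-chromosome GA).
#' @param out_dir Optional output directory for `per_run.csv` and
#'   `summary.csv`.
#' @return An `experiment_stats` object: per-run data frame, best/mean/sd
#'   of F1 and F2, and the best run's state.
#' @export
run_experiment <- function(problem, config = problem$preset, n_runs = 20L,
                           base_seed = 1L, method = c("ncga", "baseline"),
                           out_dir = NULL) {
  method <- match.arg(method)
  stopifnot(n_runs >= 1L)
  runner <- if (method == "ncga") run_ncga else run_baseline_ga
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- modify_ncga_config(config, seed = base_seed + i - 1L)
    runs[[i]] <- runner(problem, cfg)
  }
  per_run <- data.frame(
    run = seq_len(n_runs),
    seed = base_seed + seq_len(n_runs) - 1L,
    f1 = vapply(runs, function(r) r$best_fitness$f1_fold, 0),
    f2 = vapply(runs, function(r) r$best_fitness$f2_total, 0),
    residual_norm = vapply(runs, function(r) r$best_fitness$residual_norm, 0),
    feasible = vapply(runs, function(r) r$best_fitness$feasible, TRUE),
    generations = vapply(runs, function(r) nrow(r$history), 0L),
    terminated_by = vapply(runs, `[[`, "", "terminated_by")
  )
  ibest <- which.max(per_run$f1)
  stats <- structure(list(
    n_runs = n_runs, method = method, base_seed = base_seed,
    per_run = per_run,
    best_f1 = per_run$f1[ibest], best_state = runs[[ibest]]$best_state,
    mean_f1 = mean(per_run$f1),
    sd_f1 = if (n_runs > 1L) stats::sd(per_run$f1) else 0,
    best_f2 = min(per_run$f2), mean_f2 = mean(per_run$f2),
    sd_f2 = if (n_runs > 1L) stats::sd(per_run$f2) else 0,
    runs = runs
  ), class = "experiment_stats")
  if (!is.null(out_dir)) write_experiment_csv(stats, out_dir)
  stats
}

summary_frame <- function(stats) {
  data.frame(statistic = c("best", "mean", "sd"),
             f1 = c(stats$best_f1, stats$mean_f1, stats$sd_f1),
             f2 = c(stats$best_f2, stats$mean_f2, stats$sd_f2))
}

write_experiment_csv <- function(stats, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(stats$per_run, file.path(out_dir, "per_run.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_frame(stats), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.experiment_stats <- function(x, ...) {
  cat(x$method, " experiment: ", x$n_runs, " run(s), seeds ",
      x$base_seed, "..", x$base_seed + x$n_runs - 1L, "\n", sep = "")
  cat(sprintf("  F1 best %.4f  mean %.4f  sd %.4f\n",
              x$best_f1, x$mean_f1, x$sd_f1))
  cat(sprintf("  F2 best %.4f  mean %.4f  sd %.4f\n",
              x$best_f2, x$mean_f2, x$sd_f2))
  invisible(x)
}

#' Paired ablation runs
#'
#' Pairs of same-seed runs that differ only in the ablated axis:
#' `"representation"` pairs the cooperative NCGA against the
#' single-chromosome baseline GA at an equal evaluation budget;
#' `"representative_selection"` pairs fitness-based against random
#' representative selection.  Pair `i` uses seed `base_seed + i - 1`.
#'
#' @param problem An `ncga_problem`.
#' @param config Base configuration.
#' @param n_pairs Number of seed pairs.
#' @param base_seed First seed.
#' @param axis `"representation"` or `"representative_selection"`.
#' @param out_dir Optional directory for the pair CSV and per-generation
#'   trajectory CSVs.
#' @return An `ablation_result`: `pairs` data frame (per-seed best F1/F2 of
#'   both arms and the final generation's nominated-representative F2) and
#'   the two run lists.
#' @export
run_ablation <- function(problem, config = problem$preset, n_pairs = 10L,
                         base_seed = 1L,
                         axis = c("representation", "representative_selection"),
                         out_dir = NULL) {
  axis <- match.arg(axis)
  stopifnot(n_pairs >= 1L)
  runs_a <- vector("list", n_pairs); runs_b <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    seed <- base_seed + i - 1L
    if (axis == "representation") {
      runs_a[[i]] <- run_ncga(problem, modify_ncga_config(config, seed = seed))
      runs_b[[i]] <- run_baseline_ga(problem,
                                     modify_ncga_config(config, seed = seed))
    } else {
      runs_a[[i]] <- run_ncga(problem, modify_ncga_config(
        config, seed = seed, representative_selection = "fitness"))
      runs_b[[i]] <- run_ncga(problem, modify_ncga_config(
        config, seed = seed, representative_selection = "random"))
    }
  }
  final_f2 <- function(r) r$history$representative_f2[nrow(r$history)]
  pairs <- data.frame(
    pair = seq_len(n_pairs), seed = base_seed + seq_len(n_pairs) - 1L,
    f1_a = vapply(runs_a, function(r) r$best_fitness$f1_fold, 0),
    f1_b = vapply(runs_b, function(r) r$best_fitness$f1_fold, 0),
    f2_a = vapply(runs_a, function(r) r$best_fitness$f2_total, 0),
    f2_b = vapply(runs_b, function(r) r$best_fitness$f2_total, 0),
    final_f2_a = vapply(runs_a, final_f2, 0),
    final_f2_b = vapply(runs_b, final_f2, 0)
  )
  out <- structure(list(axis = axis, pairs = pairs,
                        arm_a = if (axis == "representation") "ncga" else "fitness",
                        arm_b = if (axis == "representation") "baseline" else "random",
                        runs_a = runs_a, runs_b = runs_b),
                   class = "ablation_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
    traj <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      rbind(cbind(pair = i, arm = out$arm_a, runs_a[[i]]$history),
            cbind(pair = i, arm = out$arm_b, runs_b[[i]]$history))
    }))
    utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Ablation (", x$axis, "): ", nrow(x$pairs), " same-seed pair(s)\n",
      sep = "")
  cat(sprintf("  %s best F1 >= %s in %d/%d pairs\n", x$arm_a, x$arm_b,
              sum(x$pairs$f1_a >= x$pairs$f1_b), nrow(x$pairs)))
  cat(sprintf("  %s final representative F2 <= %s in %d/%d pairs\n", x$arm_a,
              x$arm_b, sum(x$pairs$final_f2_a <= x$pairs$final_f2_b),
              nrow(x$pairs)))
  invisible(x)
}
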