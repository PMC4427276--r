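# The cooperative engine: two-level fitness, representative selection,
# generation stepping, full runs, and the single-chromosome baseline.

test_that("sub-chromosome fitness is the decoded concentration", {
  expect_identical(sub_fitness(rep(0L, 16), c(0, 50)), 0)
  set.seed(3)
  bits <- replicate(10, sample(0:1, 8, replace = TRUE), simplify = FALSE)
  fit <- vapply(bits, sub_fitness, 0, bounds = c(0, 50))
  dec <- vapply(bits, decode_bits, 0, lo = 0, hi = 50)
  expect_identical(order(fit), order(dec))
})

test_that("representative sub-fitness totals equal the assembled concentration total", {
  p1 <- build_case1()
  set.seed(6)
  algo <- init_ncga(p1, modify_config_for_test(p1$preset, 8L))
  roster <- select_representatives(algo$subpops, "fitness", roster_size = 3L)
  for (coop in roster) {
    subfits <- vapply(seq_along(algo$subpops), function(j)
      sub_fitness(coop$representatives[[j]]$bits, algo$subpops[[j]]$bounds), 0)
    # the F2 subset of case 1 is exactly the tunable set
    expect_equal(sum(subfits),
                 concentration_total(p1$objective, coop$decoded_state),
                 tolerance = 1e-12)
  }
})

test_that("cooperative evaluation reproduces the published best record in penalty mode", {
  p1 <- build_case1()
  vals <- case1_best()
  subpops <- pinned_subpops(p1, vals)
  coop <- assemble_cooperative(subpops, rep(1L, length(subpops)))
  rec <- evaluate_cooperative(coop, p1)
  expect_equal(rec$f1_fold, 52.91, tolerance = 0.001)
  expect_equal(rec$f2_total, 294.80, tolerance = 0.005 / 294.80)
  expect_false(rec$feasible)  # the printed winner is not a steady state
  expect_equal(rec$penalized_score,
               rec$f1_fold - 10 * rec$residual_norm, tolerance = 1e-9)
})

test_that("out-of-bounds states rank below every in-bounds state", {
  p1 <- build_case1()
  oob_vals <- case1_best(); oob_vals["Y1"] <- 60  # above the 0-50 range
  oob <- assemble_cooperative(pinned_subpops(p1, oob_vals),
                              rep(1L, 11))
  rec_oob <- evaluate_cooperative(oob, p1)
  # an in-bounds state with dreadful F1 still outranks it
  low_vals <- case1_best(); low_vals[paste0("Y", 1:6)] <- 0.01
  rec_low <- evaluate_cooperative(
    assemble_cooperative(pinned_subpops(p1, low_vals), rep(1L, 11)), p1)
  expect_lt(rec_oob$penalized_score, rec_low$penalized_score)
  expect_false(rec_oob$feasible)
})

test_that("refine mode certifies feasibility at a planted root", {
  tp <- generate_toy_problem(2)
  cfg <- ncga:::modify_ncga_config(tp$preset, steady_state_mode = "refine")
  root <- basal_state(tp$model)   # the toy's basal state is the planted root
  subpops <- pinned_subpops(tp, as.list(root[tp$tunable_names]))
  coop <- assemble_cooperative(subpops, rep(1L, 2))
  rec <- evaluate_cooperative(coop, tp, cfg)
  expect_true(rec$feasible)
  expect_lt(rec$residual_norm, 1e-6)
})

test_that("fitness-mode rosters pair equal ranks with non-decreasing totals", {
  p1 <- build_case1()
  set.seed(14)
  algo <- init_ncga(p1, modify_config_for_test(p1$preset, 12L))
  roster <- select_representatives(algo$subpops, "fitness", roster_size = 12L)
  f2 <- vapply(roster, function(cc)
    concentration_total(p1$objective, cc$decoded_state), 0)
  expect_true(all(diff(f2) >= 0))
  # roster entry 1 combines the lowest-valued member of every sub-population
  mins <- vapply(algo$subpops, function(sp) min(ncga:::subpop_values(sp)), 0)
  expect_equal(unname(roster[[1]]$decoded_state), unname(mins))
  # duplicated sub-populations yield identical representative sequences
  twin <- algo$subpops[c(1, 1)]
  r2 <- select_representatives(twin, "fitness", roster_size = 5L)
  for (cc in r2)
    expect_identical(cc$representatives[[1]]$bits,
                     cc$representatives[[2]]$bits)
})

test_that("a generation step conserves population size and credits scores", {
  tp <- generate_toy_problem(4)
  algo <- init_ncga(tp)
  n <- tp$preset$genetic$population_size
  st <- step_generation(algo, tp)
  expect_identical(vapply(st$algo$subpops, function(s) nrow(s$bits), 0L),
                   rep(n, 2L))
  expect_identical(st$record$generation, 1L)
  expect_true(is.finite(st$record$best$penalized_score))
  expect_identical(st$record$n_feasible, 0L)  # penalty mode, basal solved var
})

test_that("zero mutation and identical members leave a sub-population unchanged", {
  tp <- generate_toy_problem(5)
  cfg <- ncga:::modify_ncga_config(
    tp$preset, genetic = list(mutation_rate = 0, immigrant_fraction = 0))
  algo <- init_ncga(tp, cfg)
  for (j in 1:2)
    algo$subpops[[j]]$bits <-
      matrix(rep(algo$subpops[[j]]$bits[1, ], each = nrow(algo$subpops[[j]]$bits)),
             nrow(algo$subpops[[j]]$bits))
  before <- lapply(algo$subpops, `[[`, "bits")
  st <- step_generation(algo, tp, cfg)
  expect_identical(lapply(st$algo$subpops, `[[`, "bits"), before)
})

test_that("elitism makes the best penalized score non-decreasing", {
  # the concentration tie-break may swap in an equal-score, lower-F2 record,
  # so "non-decreasing" holds up to the relative near-tie width
  tol_ok <- function(s) all(diff(s) >= -1e-6 * pmax(1, abs(s[-length(s)])))
  tp <- generate_toy_problem(6)
  run <- run_ncga(tp, ncga:::modify_ncga_config(tp$preset, max_generations = 100L))
  expect_true(tol_ok(run$history$best_score))
  base <- run_baseline_ga(tp, ncga:::modify_ncga_config(tp$preset,
                                                        max_generations = 100L))
  expect_true(tol_ok(base$history$best_score))
})

test_that("runs are bit-reproducible from the seed and stay within bounds", {
  tp <- generate_toy_problem(7)
  cfg <- ncga:::modify_ncga_config(tp$preset, max_generations = 15L, seed = 77L)
  r1 <- run_ncga(tp, cfg)
  r2 <- run_ncga(tp, cfg)
  expect_identical(r1$best_state, r2$best_state)
  expect_identical(r1$history, r2$history)
  b1 <- run_baseline_ga(tp, cfg)
  b2 <- run_baseline_ga(tp, cfg)
  expect_identical(b1$history, b2$history)
  for (j in seq_along(tp$tunable_names)) {
    b <- tp$tunable_bounds[[j]]
    v <- r1$best_state[[tp$tunable_names[j]]]
    expect_true(v >= b[1] && v <= b[2])
  }
})

test_that("the genetic search locates the exhaustive grid optimum", {
  # NCGA at the toy preset; the baseline bound holds at the benchmark
  # preset budget (150 members, 300 generations)
  big <- function(tp) ncga:::modify_ncga_config(
    tp$preset, max_generations = 300L,
    genetic = list(population_size = 150L))
  for (s in 1:3) {
    tp <- generate_toy_problem(s)
    g <- toy_grid_optimum(tp)
    r <- run_ncga(tp)
    expect_gte(r$best_fitness$f1_fold, 0.95 * g$f1)
    b <- run_baseline_ga(tp, big(tp))
    expect_gte(b$best_fitness$f1_fold, 0.80 * g$f1)
  }
})

test_that("the baseline concatenates all tunables into one chromosome", {
  p1 <- build_case1()
  cfg <- modify_config_for_test(p1$preset, 10L, gens = 2L)
  b <- run_baseline_ga(p1, cfg)
  expect_identical(b$chromosome_length, 11L * 16L)
  expect_identical(b$method, "baselineGA")
})

test_that("benchmark preset runs keep all tunables within the stated ranges", {
  p1 <- build_case1()
  run <- run_ncga(p1, modify_config_for_test(p1$preset, 20L, gens = 33L))
  st <- run$best_state
  for (j in seq_along(p1$tunable_names)) {
    b <- p1$tunable_bounds[[j]]
    v <- st[[p1$tunable_names[j]]]
    expect_true(v >= b[1] && v <= b[2])
  }
  expect_length(st[p1$tunable_names], 11L)
})
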