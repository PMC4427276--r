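# Bundled benchmark problems and the solution validator.

test_that("case 1 carries the published search space and preset", {
  p1 <- build_case1()
  expect_length(p1$tunable_names, 11)
  expect_identical(p1$tunable_names,
                   c(paste0("X", 1:5), paste0("Y", 1:6)))
  for (j in 1:5) expect_equal(p1$tunable_bounds[[j]], c(0.8, 1.2))
  for (j in 6:11) expect_equal(p1$tunable_bounds[[j]], c(0, 50))
  # Y7, Y8 fixed at 1
  expect_equal(unname(p1$fixed_values[c("Y7", "Y8")]), c(1, 1))
  expect_identical(p1$objective$target_flux, "V_PK")
  expect_identical(p1$objective$f2_names,
                   c(paste0("X", 1:5), paste0("Y", 1:6)))
  expect_equal(production_fold(p1$model, p1$objective,
                               p1$objective$reference_state), 1)
  pr <- p1$preset
  expect_identical(pr$max_generations, 300L)
  expect_identical(pr$genetic$population_size, 150L)
  expect_identical(pr$genetic$crossover_points, 2L)
  expect_equal(pr$genetic$mutation_rate, 0.3)
  expect_identical(pr$steady_state_mode, "penalty")
  expect_identical(pr$newton$max_iterations, 50L)
  expect_equal(pr$newton$tolerance, 1e-6)
  # solved set squares with the stoichiometric rows
  expect_length(p1$solved_names, nrow(p1$model$S))
})

test_that("case 2 carries the published search space and preset", {
  p2 <- build_case2()
  expect_length(p2$tunable_names, 7)
  expect_identical(p2$tunable_names,
                   c("X1", "X2", "X3", "X4", "X5", "X6", "X8"))
  expect_equal(p2$tunable_bounds[[match("X4", p2$tunable_names)]],
               c(0, 0.00624))
  expect_equal(p2$tunable_bounds[[match("X6", p2$tunable_names)]],
               c(500, 5000))
  expect_equal(p2$tunable_bounds[[match("X8", p2$tunable_names)]],
               c(0, 1000))
  # the search range for X5 is opened to [4, 10]; the published [5, 10]
  # remains the validation range, and can be requested for the search too
  expect_equal(p2$tunable_bounds[[match("X5", p2$tunable_names)]], c(4, 10))
  expect_equal(as.numeric(p2$validation_bounds$X5), c(5, 10))
  p2pub <- build_case2(x5_published_bounds = TRUE)
  expect_equal(p2pub$tunable_bounds[[match("X5", p2pub$tunable_names)]],
               c(5, 10))
  pr <- p2$preset
  expect_identical(pr$max_generations, 350L)
  expect_identical(pr$genetic$crossover_points, 1L)
  expect_equal(pr$genetic$mutation_rate, 0.2)
  expect_length(p2$solved_names, 3)
})

test_that("variable roles partition each model", {
  for (p in list(build_case1(), build_case2())) {
    roles <- vapply(p$model$variables, `[[`, "", "role")
    expect_true(all(roles %in% c("tunable", "fixed")))
    expect_identical(sort(c(p$tunable_names, names(p$fixed_values))),
                     sort(p$model$var_names))
    # solved overlaps tunable only as the Newton-start convention
    expect_true(all(p$solved_names %in% p$model$var_names))
  }
})

test_that("the validator reproduces the published records and flags X5 only", {
  p1 <- build_case1()
  v1 <- validate_solution(p1, case1_best())
  expect_equal(v1$f1_fold, 52.91, tolerance = 0.001)
  expect_equal(v1$f2_total, 294.80, tolerance = 0.005 / 294.80)
  expect_true(all(v1$bounds$in_bounds))
  # the printed winner badly violates the printed steady-state equations
  expect_gt(v1$residual_norm, 100)

  p2 <- build_case2()
  v2 <- validate_solution(p2, case2_best())
  expect_equal(v2$f1_fold, 3.9759, tolerance = 0.01)
  expect_equal(v2$f2_total, 6006.5581, tolerance = 1e-4 / 6006.5581)
  bad <- v2$bounds[!v2$bounds$in_bounds, ]
  expect_identical(bad$variable, "X5")   # exactly this one violation
  expect_equal(bad$value, 4.0172)
  expect_true(all(abs(v2$residuals) > 0))

  ones <- stats::setNames(rep(1, 13), p1$model$var_names)
  v3 <- validate_solution(p1, ones)
  expect_equal(v3$f1_fold, 1)
  expect_true(all(v3$bounds$in_bounds))
})

test_that("problems round-trip through the config formats", {
  dir <- withr::local_tempdir()
  for (problem in list(build_case1(), generate_toy_problem(3))) {
    f <- file.path(dir, "prob.yaml")
    save_problem(problem, f)
    back <- load_problem(f)
    expect_identical(back$tunable_names, problem$tunable_names)
    expect_equal(back$tunable_bounds, problem$tunable_bounds)
    expect_identical(back$solved_names, problem$solved_names)
    expect_identical(back$objective$target_flux,
                     problem$objective$target_flux)
    expect_equal(back$objective$reference_state,
                 problem$objective$reference_state)
    expect_equal(unclass(back$preset)[names(unclass(back$preset)) != "genetic"],
                 unclass(problem$preset)[names(unclass(problem$preset)) != "genetic"],
                 tolerance = 1e-12)
    expect_equal(unclass(back$preset$genetic),
                 unclass(problem$preset$genetic))
    expect_identical(back$model$F, problem$model$F)
  }
})
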