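# Power-law flux evaluation, steady-state residuals, Jacobians and the two
# objective functionals.

test_that("flux evaluation reproduces the benchmark rate laws", {
  m1 <- build_case1()$model
  ones <- stats::setNames(rep(1, 13), m1$var_names)
  v <- evaluate_fluxes(m1, ones)
  # at a unit state every flux reduces to its rate constant
  expect_equal(v[["V_PK"]], 0.09471)
  expect_equal(unname(v), vapply(m1$fluxes, `[[`, 0, "rate_constant"))

  # published best solution, frozen from an independent log-space hand
  # evaluation of the printed rate laws
  v_best <- evaluate_fluxes(m1, case1_best())
  expect_equal(v_best[["V_PK"]], 5.0094867324, tolerance = 1e-9)

  m2 <- build_case2()$model
  v2 <- evaluate_fluxes(m2, basal_state(m2))
  expect_equal(v2[["V34"]], 1.3103223458, tolerance = 1e-9)
})

test_that("flux evaluation obeys the power-law scale law and positivity", {
  set.seed(11)
  m1 <- build_case1()$model
  for (rep in 1:25) {
    x <- stats::setNames(exp(stats::runif(13, -1, 1)), m1$var_names)
    v <- evaluate_fluxes(m1, x)
    expect_true(all(v > 0))
    i <- sample.int(length(m1$flux_names), 1)
    j <- sample.int(13, 1)
    cc <- exp(stats::runif(1, -1, 1))
    x2 <- x; x2[j] <- x2[j] * cc
    v2 <- evaluate_fluxes(m1, x2)
    expect_equal(v2[[i]], v[[i]] * cc^(m1$F[i, j]), tolerance = 1e-12)
  }
})

test_that("non-positive states with a nonzero kinetic order are rejected", {
  m1 <- build_case1()$model
  x <- basal_state(m1); x["X3"] <- 0
  expect_error(evaluate_fluxes(m1, x), "X3")
  expect_error(steady_state_residuals(m1, x), "X3")
  # an inert variable (zero exponent everywhere) may sit at zero
  m2 <- build_case2()$model
  expect_silent(evaluate_fluxes(m2, basal_state(m2)))  # X13 = 0
})

test_that("steady-state residuals match direct arithmetic and vanish at planted roots", {
  m1 <- build_case1()$model
  r <- steady_state_residuals(m1, rep(1, 13))
  expect_equal(r[["X1"]], 0.8122 - 2.8632, tolerance = 1e-12)

  pm <- generate_planted_model(5, n_vars = 5, n_rows = 3, terms_per_row = 3)
  expect_lt(max(abs(steady_state_residuals(pm$model, pm$root))), 1e-12)

  # duplicated rows give pairwise-equal residuals
  dup <- gma_model(m1$variables, m1$fluxes, c(m1$rows, m1$rows))
  rd <- steady_state_residuals(dup, case1_best())
  expect_equal(unname(rd[1:5]), unname(rd[6:10]))
})

test_that("residuals are linear in the stoichiometric terms", {
  set.seed(21)
  m1 <- build_case1()$model
  half1 <- lapply(m1$rows, function(r) stoich_row(r$pool, r$terms[1]))
  half2_terms <- lapply(m1$rows, function(r) r$terms[-1])
  keep <- vapply(half2_terms, length, 0L) > 0
  x <- stats::setNames(exp(stats::runif(13, -0.5, 0.5)), m1$var_names)
  mA <- gma_model(m1$variables, m1$fluxes, half1)
  mB <- gma_model(m1$variables, m1$fluxes,
                  lapply(which(keep), function(k)
                    stoich_row(m1$rows[[k]]$pool, half2_terms[[k]])))
  rA <- steady_state_residuals(mA, x)
  rB <- steady_state_residuals(mB, x)
  r <- steady_state_residuals(m1, x)
  rB_full <- stats::setNames(numeric(5), names(rA))
  rB_full[names(rB)] <- rB
  expect_equal(unname(r), unname(rA + rB_full), tolerance = 1e-12)
})

test_that("analytic Jacobians agree with central finite differences", {
  set.seed(31)
  models <- list(build_case1()$model, build_case2()$model)
  checked <- 0L
  while (checked < 100L) {
    m <- if (checked %% 4L == 0L) models[[1 + checked %% 2L]] else
      generate_planted_model(1000L + checked, n_vars = 4, n_rows = 2,
                             terms_per_row = 3)$model
    nv <- length(m$var_names)
    x <- stats::setNames(exp(stats::runif(nv, -0.5, 0.5)), m$var_names)
    J <- residual_jacobian(m, x, wrt = seq_len(nv), space = "linear")
    fd <- vapply(seq_len(nv), function(j) {
      h <- 1e-6 * x[j]
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      (steady_state_residuals(m, xp) - steady_state_residuals(m, xm)) / (2 * h)
    }, numeric(nrow(m$S)))
    expect_equal(unname(J), unname(fd), tolerance = 1e-5)
    checked <- checked + 1L
  }
})

test_that("log-space Jacobian is the linear-space one scaled by x", {
  m <- build_case2()$model
  x <- basal_state(m); x["X13"] <- 1  # keep log-scaling finite everywhere
  Jlin <- residual_jacobian(m, x, wrt = 1:12, space = "linear")
  Jlog <- residual_jacobian(m, x, wrt = 1:12, space = "log")
  expect_equal(unname(Jlog), unname(sweep(Jlin, 2, x[1:12], "*")),
               tolerance = 1e-12)
  # a zero kinetic order contributes an exactly zero column entry
  sf <- single_flux_model(gamma = 3)
  expect_equal(unname(residual_jacobian(sf, c(x = 1), wrt = 1))[1, 1], 6)
})

test_that("production fold and concentration total reproduce the published objectives", {
  p1 <- build_case1()
  expect_equal(production_fold(p1$model, p1$objective,
                               p1$objective$reference_state), 1.0)
  f1 <- production_fold(p1$model, p1$objective, case1_best())
  expect_equal(f1, 52.91, tolerance = 0.001)
  expect_equal(concentration_total(p1$objective, case1_best()), 294.80,
               tolerance = 0.005 / 294.80)

  p2 <- build_case2()
  expect_equal(production_fold(p2$model, p2$objective, case2_best()),
               3.9759, tolerance = 0.01)
  expect_equal(concentration_total(p2$objective, case2_best()), 6006.5581,
               tolerance = 1e-4 / 6006.5581)
  # empty subset sums to zero
  o <- objective_spec(p2$model, "V34", integer())
  expect_identical(concentration_total(o, case2_best()), 0)
})
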