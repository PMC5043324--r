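test_that("annealing conserves mass exactly and is seeded-deterministic", {
  cfg <- metropolis_config(n_iter = 2e4, seed = 13, quench = FALSE)
  res <- optimize_distribution(fitness_spec(1.5), g100, cfg)
  expect_lt(abs(sum(res$dist$p) * g100$dx - 1), 1e-9)
  res2 <- optimize_distribution(fitness_spec(1.5), g100, cfg)
  expect_identical(res$dist$p, res2$dist$p)
  expect_identical(res$trace, res2$trace)

  # best-so-far envelope is non-decreasing
  expect_true(all(diff(res$trace$f) >= 0))
  # reported values match a recomputation on the returned distribution
  expect_equal(res$values$f,
               fitness(res$dist, fitness_spec(1.5))$f, tolerance = 1e-9)
})

test_that("single-cell moves also conserve mass and reject negativity", {
  cfg <- metropolis_config(n_iter = 2e4, seed = 3, kernel_width = 0,
                           kernel_width_end = 0, quench = FALSE)
  res <- optimize_distribution(fitness_spec(2), g100, cfg)
  expect_lt(abs(sum(res$dist$p) * g100$dx - 1), 1e-9)
  expect_true(all(res$dist$p >= 0))
})

test_that("above the transition the optimizer returns the uniform profile", {
  res <- opt_run(5, n_iter = 5e4)
  expect_lte(max(abs(res$dist$p - 1)), 0.05)
})

test_that("optimized fitness beats the uniform and two-step benchmarks", {
  for (t in c(0.1, 2, 3.9)) {
    res <- opt_run(t, n_iter = 1e5)
    bench <- max(fitness(make_uniform(g100), fitness_spec(t))$f,
                 two_step_optimum(t)$f_at_opt)
    expect_gte(res$values$f, bench - 1e-3,
               label = sprintf("t = %g: optimized f vs benchmarks", t))
  }
})

test_that("antisymmetry p(x) + p(1-x) = 2 emerges without being enforced", {
  for (t in c(0.1, 3.9)) {
    p <- opt_run(t, n_iter = 1e5)$dist$p
    expect_lte(max(abs(p + rev(p) - 2)), 0.1,
               label = sprintf("t = %g", t))
  }
})

test_that("the returned profile is oriented with male mass at low x", {
  res <- opt_run(1.5, n_iter = 1e5, seed = 4)
  expect_lte(sum(g100$x * res$dist$p) * g100$dx, 0.5 + 1e-9)
})

test_that("family projections are fixed points on exact members", {
  fit <- polish_profile(two_step(0.5), "two_step")
  expect_lt(abs(fit$parameters["c"] - 0.5), 1e-6)
  expect_lte(fit$rms, 1e-9)

  fit <- polish_profile(make_fermi(g100, 0.1), "fermi")
  expect_lt(abs(fit$parameters["Ttilde"] - 0.1), 1e-4)

  k3 <- make_step_profile(g100, c(0.3, 0.7), c(1.6, 1, 0.4))
  fit <- polish_profile(k3, "k_step", k = 3)
  expect_lt(abs(fit$parameters["a"] - 0.3), 1e-3)
  expect_lt(abs(fit$parameters["c"] - 0.6), 1e-3)
})

test_that("Monte Carlo output at t = 3.5 projects onto the exact two-step optimum", {
  res <- opt_run(3.5, n_iter = 1e5)
  fit <- polish_profile(res, "two_step")
  c_star <- two_step_optimum(3.5)$c_exact
  expect_lt(abs(fit$parameters["c"] - c_star) / c_star, 0.25)
})
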