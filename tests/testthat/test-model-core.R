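test_that("constructors build normalized densities on a mirror-exact grid", {
  g <- trait_grid(10)
  expect_equal(g$x, (0:9 + 0.5) / 10)
  expect_equal(rev(g100$x), 1 - g100$x)

  u <- make_uniform(g)
  expect_true(all(u$p == 1))
  expect_equal(sum(u$p) * g$dx, 1)

  # empty breakpoints degenerate to the uniform profile
  expect_equal(make_step_profile(g100, numeric(0), 1)$p, make_uniform(g100)$p)

  # renormalization after discretization
  st <- make_step_profile(g100, 0.3, c(3, 1))
  expect_equal(sum(st$p) * st$grid$dx, 1, tolerance = 1e-12)

  fm <- make_fermi(g100, 0.1)
  expect_equal(sum(fm$p) * fm$grid$dx, 1, tolerance = 1e-12)
  # midpoint symmetry of the logistic: p(1/2) = 1
  expect_equal(fm$p[50] + fm$p[51], 2, tolerance = 1e-9)

  expect_error(make_step_profile(g100, 0.5, c(1, -0.1)), "nonnegative")
  expect_error(make_step_profile(g100, 1.2, c(1, 1)), "inside")
  expect_error(make_fermi(g100, 0), "positive")
  expect_error(trait_dist(g100, rep(2, 100)), "not normalized")
})

test_that("the raw Fermi form satisfies p(x) + p(1-x) = 2 and its cold limit is the step", {
  for (Tt in c(0.03, 0.1, 0.3)) {
    p_raw <- 2 / (1 + exp((g100$x - 0.5) / Tt))
    expect_lt(max(abs(p_raw + rev(p_raw) - 2)), 1e-12)
  }
  cold <- make_fermi(g100, 0.001)
  away <- abs(g100$x - 0.5) > 0.02
  expect_lt(max(abs(cold$p - heaviside_low()$p)[away]), 1e-6)
})

test_that("heterosexual fraction matches its closed forms", {
  expect_equal(heterosexual_fraction(make_uniform(g100)), 0.5,
               tolerance = 1e-9)
  # disjoint male/female supports: every pairing is heterosexual
  expect_equal(heterosexual_fraction(two_step(1)), 1)
  for (c0 in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_equal(heterosexual_fraction(two_step(c0)),
                 3 / 2 - 1 / (1 + c0^2), tolerance = 1e-6)
  }
})

test_that("trait entropy matches closed forms with the 0 ln 0 convention", {
  expect_equal(trait_entropy(make_uniform(g100)), 0)
  expect_equal(trait_entropy(two_step(1)), -log(2), tolerance = 1e-9)
  # -[(1.5 ln 1.5 + 0.5 ln 0.5)/2], by direct integration
  expect_equal(trait_entropy(two_step(0.5)), -0.1308120624,
               tolerance = 1e-6)
  for (c0 in c(0.25, 0.75)) {
    s_exact <- -((1 + c0) * log(1 + c0) + (1 - c0) * log(1 - c0)) / 2
    expect_equal(trait_entropy(two_step(c0)), s_exact, tolerance = 1e-6)
  }
})

test_that("trait variance matches closed forms", {
  expect_equal(trait_variance(make_uniform(g100)), 1 / 12, tolerance = 1e-3)
  # <x> = 3/4, <x^2> = 7/12 for the Heaviside profile
  expect_equal(trait_variance(heaviside_low()), 1 / 48, tolerance = 1e-3)
  point <- trait_dist(g100, c(rep(0, 49), 100, rep(0, 50)))
  expect_lte(trait_variance(point), g100$dx^2 / 12 + 1e-12)
})

test_that("fitness composes the functionals under both measures", {
  expect_equal(fitness(make_uniform(g100), fitness_spec(10))$f, 0.5)
  expect_equal(fitness(two_step(1), fitness_spec(0))$f, 1)
  v <- fitness(make_uniform(g100), fitness_spec(12, "variance"))
  expect_equal(v$f, 1, tolerance = 1e-3)
  expect_equal(v$sigma2, 1 / 12, tolerance = 1e-3)
})

test_that("functionals are mirror-invariant and respect their bounds", {
  profiles <- list(make_uniform(g100), two_step(0.37),
                   make_fermi(g100, 0.08),
                   make_step_profile(g100, c(0.2, 0.8), c(1.6, 1, 0.4)))
  for (d in profiles) {
    m <- mirror_dist(d)
    expect_equal(heterosexual_fraction(d), heterosexual_fraction(m),
                 tolerance = 1e-12)
    expect_equal(trait_entropy(d), trait_entropy(m), tolerance = 1e-12)
    expect_equal(trait_variance(d), trait_variance(m), tolerance = 1e-12)
    n <- heterosexual_fraction(d)
    expect_gte(n, 0); expect_lte(n, 1)
    expect_lte(trait_entropy(d), 1e-9)
    expect_lte(trait_variance(d), 0.25)
  }
})

test_that("disjoint supports give n = 1 exactly", {
  set.seed(42)
  for (rep in 1:5) {
    half <- runif(50)
    p <- c(half, rep(0, 50))
    d <- trait_dist(g100, p / (sum(p) * g100$dx))
    expect_identical(heterosexual_fraction(d), 1)
  }
})

test_that("quadrature of the pairing integral converges in grid size", {
  n_vals <- sapply(c(101, 401), function(M) {
    heterosexual_fraction(make_fermi(trait_grid(M), 0.1))
  })
  expect_lt(abs(n_vals[1] - n_vals[2]), 1e-3)
})
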