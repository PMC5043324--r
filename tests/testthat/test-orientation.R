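test_that("the orientation map follows p / (p + mirror)", {
  expect_equal(orientation_of(c(0.1, 0.4, 0.8), make_uniform(g100)),
               rep(0.5, 3))
  # two-level step: theta = (1 + c)/2 on the heavy side
  expect_equal(orientation_of(0.25, two_step(0.3)), (1 + 0.3) / 2)
  expect_equal(orientation_of(0.75, two_step(0.3)), (1 - 0.3) / 2)
  # Fermi profile: the factor 2 cancels and theta is the logistic
  fm <- make_fermi(g100, 0.1)
  xc <- c(0.333, 0.527, 0.618)
  expect_equal(orientation_of(xc, fm), 1 / (1 + exp((g100$x[floor(xc * 100) + 1]
                                                     - 0.5) / 0.1)),
               tolerance = 1e-9)
  # both sides empty -> undefined
  d <- make_step_profile(g100, c(0.4, 0.6), c(1, 0, 1))
  expect_true(is.na(orientation_of(0.5, d)))
  expect_error(orientation_of(1.2, fm), "\\[0, 1\\]")
})

test_that("orientation involution theta(x) + theta(1-x) = 1 holds where defined", {
  for (d in list(two_step(0.41), make_fermi(g100, 0.07))) {
    xc <- c(0.123, 0.3, 0.456, 0.77)
    expect_equal(orientation_of(xc, d) + orientation_of(1 - xc, d),
                 rep(1, 4), tolerance = 1e-12)
  }
})

test_that("orientation pushforward gives the published atomic structure", {
  od <- orientation_distribution(make_uniform(g100))
  expect_identical(od$kind, "atomic")
  expect_equal(od$atoms$theta, 0.5)
  expect_equal(od$atoms$weight, 1)

  # two classes at (1 -+ c)/2 with weights (1 +- c)/2: the minority-
  # orientation class is the larger share of the population
  od <- orientation_distribution(two_step(0.3))
  expect_equal(od$atoms$theta, c((1 - 0.3) / 2, (1 + 0.3) / 2))
  expect_equal(od$atoms$weight, c((1 + 0.3) / 2, (1 - 0.3) / 2),
               tolerance = 1e-12)
  expect_equal(sum(od$atoms$weight), 1, tolerance = 1e-9)
})

test_that("the Fermi pushforward matches the 2 Ttilde / theta continuum", {
  Tt <- 0.1
  od <- orientation_distribution(make_fermi(g100, Tt))
  expect_identical(od$kind, "continuous")
  an <- analytic_p_theta(Tt)
  sel <- od$density$theta >= 1.2 * an$theta_min &
    od$density$theta <= 0.9 * an$theta_max
  rel <- abs(od$density$P[sel] / an$pdf(od$density$theta[sel]) - 1)
  expect_lt(max(rel), 0.05)
  # conservation of the tabulated density (trapezoid)
  d <- od$density
  integral <- sum(diff(d$theta) * (head(d$P, -1) + d$P[-1]) / 2)
  expect_lt(abs(integral - 1), 1e-2)
})

test_that("pushforward mean equals the direct weighted mean", {
  for (d in list(two_step(0.52), make_fermi(g100, 0.12))) {
    od <- orientation_distribution(d)
    mean_push <- sum(od$atoms$theta * od$atoms$weight)
    w <- rev(d$p) * d$grid$dx
    th <- d$p / (d$p + rev(d$p))
    expect_equal(mean_push, sum(w * th, na.rm = TRUE), tolerance = 1e-6)
  }
})

test_that("the analytic continuum density is exactly normalized with interior support", {
  for (Tt in c(0.03, 0.09, 0.2)) {
    an <- analytic_p_theta(Tt)
    expect_lt(abs(2 * Tt * log(an$theta_max / an$theta_min) - 1), 1e-10)
    expect_gt(an$theta_min, 0)
    expect_lt(an$theta_max, 1)
    expect_equal(an$theta_max - 0.5, 0.5 - an$theta_min, tolerance = 1e-12)
  }
  expect_equal(analytic_p_theta(0.1)$theta_min, 1 / (1 + exp(5)),
               tolerance = 1e-12)
})

test_that("binning integrates atoms and densities with edge-to-lower-bin ties", {
  b <- bin_orientation(orientation_distribution(make_uniform(g100)))
  expect_equal(sum(b$proportion), 1, tolerance = 1e-12)
  expect_equal(b$proportion[4], 1)  # the bin containing theta = 1/2

  b <- bin_orientation(analytic_p_theta(0.09))
  expect_equal(sum(b$proportion), 1, tolerance = 1e-9)
  expect_true(all(diff(b$proportion) < 0))  # 1/theta is decreasing

  # an atom exactly on an interior edge goes to the lower bin
  atom_edge <- structure(list(kind = "atomic",
                              atoms = data.frame(theta = 2 / 7, weight = 1)),
                         class = "orientation_dist")
  b <- bin_orientation(atom_edge)
  expect_equal(b$proportion[2], 1)
})

test_that("Ttilde fitting round-trips and recovers noisy synthetic data", {
  b <- bin_orientation(analytic_p_theta(0.09))
  fit <- fit_ttilde(b)
  expect_lt(abs(fit$Ttilde_hat - 0.09), 1e-4)
  expect_lt(abs(fit$t_hat - 0.4), 0.02)
  expect_true(fit$converged)

  # parameter recovery under 2% multiplicative noise
  errs <- vapply(1:20, function(s) {
    noisy <- generate_fixture("binned_survey",
                              list(Ttilde = 0.05, n_respondents = 1e6,
                                   noise = 0.02), seed = s)
    abs(fit_ttilde(noisy)$Ttilde_hat - 0.05) / 0.05
  }, numeric(1))
  expect_lte(median(errs), 0.1)

  concentrated <- structure(
    data.frame(bin_low = seq(0, 6) / 7, bin_high = seq(1, 7) / 7,
               proportion = c(1, rep(0, 6))),
    class = c("binned_orientation", "data.frame"))
  expect_error(fit_ttilde(concentrated), "at least 3 bins")
})
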