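test_that("two-step closed forms agree with the quadrature", {
  expect_equal(two_step_closed_forms(0), list(n = 0.5, s = 0))
  expect_equal(two_step_closed_forms(1), list(n = 1, s = -log(2)))
  for (c0 in c(0.25, 0.5, 0.75)) {
    v <- two_step_closed_forms(c0)
    expect_equal(v$n, heterosexual_fraction(two_step(c0)), tolerance = 1e-6)
    expect_equal(v$s, trait_entropy(two_step(c0)), tolerance = 1e-6)
  }
  expect_error(two_step_closed_forms(1.2), "\\[0, 1\\]")
})

test_that("the optimal two-step amplitude vanishes at t >= 4 and grows as sqrt(4 - t)", {
  expect_lt(two_step_optimum(4)$c_exact, 1e-4)
  expect_identical(two_step_optimum(5)$c_exact, 0)

  sol <- two_step_optimum(3.9)
  expect_gt(sol$c_exact, 0)
  expect_lte(sol$c_exact, sol$c_quadratic)
  ratio <- two_step_optimum(3.9)$c_exact / two_step_optimum(3.96)$c_exact
  expect_lt(abs(ratio - sqrt(0.1 / 0.04)) / sqrt(0.1 / 0.04), 0.15)

  # sqrt scaling on log-log axes just below threshold
  ts <- seq(3.6, 3.99, by = 0.03)
  cs <- vapply(ts, function(t) two_step_optimum(t)$c_exact, numeric(1))
  slope <- coef(lm(log(cs) ~ log(4 - ts)))[2]
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("bisection finds the onset of trait sexualization at t = 4", {
  t_star <- critical_t_entropy()
  expect_lt(abs(t_star - 4), 0.01)
  expect_identical(two_step_optimum(t_star + 0.1)$c_exact, 0)
  expect_gt(two_step_optimum(t_star - 0.1)$c_exact, 0.05)
})

test_that("k-step family optima collapse and split where expected", {
  # at t = 3 only two classes: middle plateau collapses
  k3 <- k_step_family_optimum(3, 3)
  expect_lte(k3$parameters["mid_width"], 1e-3)

  # at t = 1.4 the third class is open and strictly favored
  k3 <- k_step_family_optimum(1.4, 3)
  f2 <- k_step_family_optimum(1.4, 2)$f
  expect_gt(k3$parameters["mid_width"], 0.01)
  expect_gt(k3$f, f2 + 1e-6)

  # k = 2 family equals the exact two-step optimum
  expect_equal(k_step_family_optimum(2, 2)$f, two_step_optimum(2)$f_at_opt,
               tolerance = 1e-9)
  expect_error(k_step_family_optimum(2, 5), "must be 2, 3 or 4")
})

test_that("the splitting cascade is located near its published points and ordered", {
  tr23 <- find_split_transition(2)
  tr34 <- find_split_transition(3)
  expect_lt(abs(tr23$t_star - 1.7), 0.15)
  expect_lt(abs(tr34$t_star - 1.17), 0.12)
  expect_gt(tr23$t_star, tr34$t_star)
  expect_identical(tr23$k_to, 3L)
})

test_that("optimal class count is non-increasing in t over the cascade", {
  count_at <- function(t) {
    f2 <- k_step_family_optimum(t, 2)
    f3 <- k_step_family_optimum(t, 3)
    f4 <- k_step_family_optimum(t, 4)
    if (f4$f > f3$f + 1e-9 && f4$parameters["c2"] > 1e-3) return(4L)
    if (f3$f > f2$f + 1e-9 && f3$parameters["mid_width"] > 1e-3) return(3L)
    if (f2$parameters["c"] > 1e-3) return(2L)
    1L
  }
  counts <- vapply(c(1.0, 1.4, 2, 3, 5), count_at, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[c(1, 5)], c(4L, 1L))
})

test_that("the Fermi-limit width follows the small-t relation", {
  expect_equal(fermi_limit(0.05)$Ttilde, 0.05 / (6 * (1 - 0.05 * log(2))),
               tolerance = 1e-12)
  expect_equal(fermi_limit(0.05)$Ttilde, 0.008633, tolerance = 1e-4)
  # leading order: Ttilde / t -> 1/6
  expect_equal(fermi_limit(1e-6)$Ttilde / 1e-6, 1 / 6, tolerance = 1e-4)
  # the published fit Ttilde ~ 0.09 corresponds to t ~ 0.4
  expect_equal(fermi_limit(0.4)$Ttilde, 0.09, tolerance = 0.03)
  expect_error(fermi_limit(1.5), "1/ln")

  sol <- fermi_limit(0.1)
  expect_equal(sol$theta_min + sol$theta_max, 1, tolerance = 1e-12)
  expect_equal(sol$theta_min, 1 / (1 + exp(1 / (2 * sol$Ttilde))))

  # cross-check against a numeric argmax of the quadrature fitness over
  # the Fermi family (independent of the expansion)
  spec <- fitness_spec(0.05)
  o <- optimize(function(Tt) fitness(make_fermi(g100, Tt), spec)$f,
                c(0.002, 0.05), maximum = TRUE, tol = 1e-8)
  expect_lt(abs(o$maximum - fermi_limit(0.05)$Ttilde) /
              fermi_limit(0.05)$Ttilde, 0.10)
})

test_that("width relation inverts consistently", {
  for (Tt in c(0.01, 0.09, 0.2))
    expect_equal(fermi_limit(ttilde_to_t(Tt))$Ttilde, Tt, tolerance = 1e-12)
})

test_that("variance-variant candidate crossing sits at t = 24 on the grid", {
  out <- variance_variant_critical_t()
  expect_lt(abs(out$t_c - 24), 0.1)
  expect_equal(out$sigma2_uniform, 1 / 12, tolerance = 1e-3)
  expect_equal(out$sigma2_step, 1 / 48, tolerance = 1e-3)
})
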