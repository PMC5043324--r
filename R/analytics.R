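#' Exact functionals of piecewise-constant trait densities
#'
#' For a piecewise-constant density the pairing double integral and the
#' entropy reduce to finite sums over segment pairs, evaluated here in
#' closed form (no grid). The partition is refined by its mirror image so
#' that both p(x) and p(1 - x) are constant on every segment.
#'
#' @param breakpoints increasing positions in (0, 1); may be empty.
#' @param levels nonnegative heights, one more than `length(breakpoints)`;
#'   must integrate to 1.
#' @return a list with elements `n` and `s`.
#' @keywords internal
piecewise_functionals <- function(breakpoints, levels) {
  edges <- sort(unique(round(c(0, breakpoints, 1 - breakpoints, 1), 12)))
  w <- diff(edges)
  keep <- w > 0
  w <- w[keep]
  mid <- ((utils::head(edges, -1) + edges[-1]) / 2)[keep]
  p <- levels[findInterval(mid, c(0, breakpoints, 1),
                           rightmost.closed = TRUE)]
  q <- rev(p)  # mirror-symmetric partition, so reversal is exact
  K <- length(w)
  n <- 0
  for (i in seq_len(K)) {
    A <- p[i] * q
    B <- q[i] * p
    den <- A + B
    ok <- den > 0
    n <- n + w[i] * sum(w[ok] * (A[ok]^2 + B[ok]^2) / den[ok])
  }
  s <- -sum(w * ifelse(p > 0, p * log(p), 0))
  list(n = n / 2, s = s)
}

#' Closed forms for the two-level step profile
#'
#' For p(x) = 1 + c below x = 1/2 and 1 - c above, the heterosexual
#' fraction and entropy are n(c) = 3/2 - 1/(1 + c^2) and
#' s(c) = -((1+c) ln(1+c) + (1-c) ln(1-c))/2 (the sign convention keeps
#' s <= 0, consistent with the small-t limit s ~ -ln 2 + pi^2 Ttilde / 3).
#'
#' @param c step amplitude in \[0, 1\].
#' @return a list with elements `n` and `s`.
#' @examples
#' two_step_closed_forms(0.5)  # n = 0.7, s = -0.1308...
#' @export
two_step_closed_forms <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1)
    stop("'c' must be a single number in [0, 1]")
  n <- 3 / 2 - 1 / (1 + c^2)
  s <- if (c >= 1) -log(2) else -((1 + c) * log1p(c) + (1 - c) * log1p(-c)) / 2
  list(n = n, s = s)
}

two_step_fitness <- function(c, t) {
  v <- two_step_closed_forms(c)
  v$n * (1 + t * v$s)
}

#' Optimal two-level step amplitude
#'
#' Maximizes f(c) = n(c)(1 + t s(c)) over c in \[0, 1\] by bounded scalar
#' optimization (`c_exact`), and reports alongside it the quadratic-
#' expansion amplitude c = sqrt((4 - t)/(4t)) for t < 4 (`c_quadratic`). The
#' exact quartic coefficient of f(c) is -(1 + 13t/24), not -t/2, so
#' `c_exact < c_quadratic` slightly below threshold; both vanish for t >= 4
#' and grow as sqrt(4 - t) below it.
#'
#' @param t positive entropy parameter.
#' @return an object of class `two_step_solution`: a list with `t`,
#'   `c_exact`, `c_quadratic`, `f_at_opt`.
#' @export
two_step_optimum <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0)
    stop("'t' must be a single positive number")
  o <- optimize(two_step_fitness, c(0, 1), t = t, maximum = TRUE,
                tol = 1e-10)
  c_exact <- if (o$objective > two_step_fitness(0, t) + 1e-13) o$maximum else 0
  c_quadratic <- if (t < 4) sqrt((4 - t) / (4 * t)) else 0
  structure(list(t = t, c_exact = c_exact, c_quadratic = c_quadratic,
                 f_at_opt = max(o$objective, two_step_fitness(0, t))),
            class = "two_step_solution")
}

#' Onset of trait sexualization (entropy measure)
#'
#' Locates the critical entropy parameter above which the optimal
#' distribution is exactly uniform, by bisection on the sign of the
#' optimal two-step amplitude over t in \[1, 8\]. Analytically the
#' quadratic coefficient of f(c) is 1 - t/4, so the threshold is t = 4.
#'
#' @param tol bisection resolution in t (default 1e-3).
#' @return the critical value t* (about 4).
#' @export
critical_t_entropy <- function(tol = 1e-3) {
  lo <- 1
  hi <- 8
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (two_step_optimum(mid)$c_exact > 1e-3) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# profile the three-level family over the middle-plateau width, with an
# exact 1-d inner optimization over the outer amplitude
k3_profile <- function(t, widths = c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1,
                                     0.15, 0.2, 0.3, 0.4, 0.5, 0.6)) {
  f_of <- function(w, c0) {
    a <- (1 - w) / 2
    v <- piecewise_functionals(c(a, 1 - a), c(1 + c0, 1, 1 - c0))
    v$n * (1 + t * v$s)
  }
  best <- list(f = -Inf, w = 0, c = 0)
  for (w in widths) {
    o <- optimize(function(c0) f_of(w, c0), c(0, 1), maximum = TRUE,
                  tol = 1e-12)
    if (o$objective > best$f)
      best <- list(f = o$objective, w = w, c = o$maximum)
  }
  best
}

# profile the four-level family over the inner amplitude c2, with inner
# multi-start optimization over (a, c1)
k4_profile <- function(t, c2_grid = c(0.005, 0.01, 0.02, 0.05, seq(0.1, 0.6,
                                                                   by = 0.05))) {
  f_of <- function(a, c1, c2) {
    a <- min(max(a, 1e-8), 0.5 - 1e-8)
    c1 <- min(max(c1, c2), 1)
    v <- piecewise_functionals(c(a, 0.5, 1 - a),
                               c(1 + c1, 1 + c2, 1 - c2, 1 - c1))
    v$n * (1 + t * v$s)
  }
  inner <- function(c2) {
    best <- list(value = Inf, par = c(0.3, max(0.7, c2)))
    for (a0 in c(0.2, 0.3, 0.4)) for (c10 in c(0.6, 0.8, 0.95)) {
      o <- optim(c(a0, max(c10, c2)),
                 function(par) -f_of(par[1], par[2], c2),
                 method = "L-BFGS-B", lower = c(1e-6, min(c2, 1)),
                 upper = c(0.5 - 1e-6, 1),
                 control = list(factr = 10))
      if (o$value < best$value) best <- o
    }
    list(f = -best$value, a = best$par[1], c1 = best$par[2])
  }
  base <- inner(0)
  best <- list(f = base$f, a = base$a, c1 = base$c1, c2 = 0)
  for (c2 in c2_grid) {
    r <- inner(c2)
    if (r$f > best$f) best <- c(r, list(c2 = c2))
  }
  list(best = best, base = base)
}

#' Family-restricted optimum with k step levels
#'
#' Maximizes f = n(1 + t s) over antisymmetric piecewise-constant
#' profiles (p(x) + p(1 - x) = 2, the symmetry obeyed by every optimal
#' solution observed): k = 2 is the two-level step 1 +- c split at 1/2;
#' k = 3 adds a middle plateau at height 1 (outer width a per side at
#' heights 1 +- c); k = 4 uses per-half widths (a, 1/2 - a) at heights
#' (1 + c1, 1 + c2), mirrored. Functionals are evaluated in closed form,
#' so the optimization is grid-free.
#'
#' @param t positive entropy parameter.
#' @param k number of levels: 2, 3 or 4.
#' @return a list with `k`, `t`, `parameters` (named vector), and `f`.
#' @export
k_step_family_optimum <- function(t, k) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be a single positive number")
  if (!k %in% c(2, 3, 4)) stop("'k' must be 2, 3 or 4")
  if (k == 2) {
    sol <- two_step_optimum(t)
    return(list(k = 2, t = t, parameters = c(c = sol$c_exact),
                f = sol$f_at_opt))
  }
  if (k == 3) {
    b <- k3_profile(t)
    f2 <- two_step_optimum(t)$f_at_opt
    if (b$f <= f2 + 1e-12) {
      sol <- two_step_optimum(t)
      return(list(k = 3, t = t,
                  parameters = c(a = 0.5, c = sol$c_exact, mid_width = 0),
                  f = sol$f_at_opt))
    }
    return(list(k = 3, t = t,
                parameters = c(a = (1 - b$w) / 2, c = b$c, mid_width = b$w),
                f = b$f))
  }
  r <- k4_profile(t)
  b <- r$best
  list(k = 4, t = t, parameters = c(a = b$a, c1 = b$c1, c2 = b$c2), f = b$f)
}

#' Locate a step-splitting transition of the cascade
#'
#' As t decreases below 4 the optimal profile first splits into two
#' levels, then the two-step structure splits into three classes and the
#' three-step into four. This routine bisects on t for the largest t at
#' which the (k+1)-level family strictly beats the k-level family (fitness
#' gain above 1e-9 and extra-structure parameter above 1e-3), using the
#' grid-free family optima.
#'
#' @param k_from 2 (locates the 2 to 3 split, near t = 1.7) or 3 (the
#'   3 to 4 split, near t = 1.17).
#' @param resolution bisection resolution in t (default 0.01).
#' @return an object of class `transition_report`: a list with `k_from`,
#'   `k_to`, `t_star`, `method`.
#' @export
find_split_transition <- function(k_from, resolution = 0.01) {
  if (!k_from %in% c(2, 3)) stop("'k_from' must be 2 or 3")
  indicator <- if (k_from == 2) {
    function(t) {
      b <- k3_profile(t)
      f2 <- two_step_optimum(t)$f_at_opt
      (b$f > f2 + 1e-9) && (b$w > 1e-3)
    }
  } else {
    function(t) {
      r <- k4_profile(t)
      (r$best$f > r$base$f + 1e-9) && (r$best$c2 > 1e-3)
    }
  }
  bracket <- if (k_from == 2) c(1.3, 2.2) else c(0.8, 1.5)
  lo <- bracket[1]
  hi <- bracket[2]
  if (!indicator(lo)) stop("no split detected at the lower bracket edge")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (indicator(mid)) lo <- mid else hi <- mid
  }
  k_from <- as.integer(k_from)
  structure(list(k_from = k_from, k_to = k_from + 1L,
                 t_star = (lo + hi) / 2, method = "family_opt"),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("<transition_report> %d -> %d classes at t* = %.3f (%s)\n",
              x$k_from, x$k_to, x$t_star, x$method))
  invisible(x)
}

#' Fermi-function limiting solution at small t
#'
#' At small entropy parameter the optimal profile approaches
#' p(x) = 2/(1 + exp((x - 1/2)/Ttilde)) with width
#' Ttilde = t / (6 (1 - t ln 2)), obtained by maximizing the small-Ttilde
#' expansions n ~ 1 - pi^2 Ttilde^2 and s ~ -ln 2 + pi^2 Ttilde / 3 to
#' leading order. The orientation bounds are theta_min =
#' 1/(1 + exp(1/(2 Ttilde))) and theta_max = 1/(1 + exp(-1/(2 Ttilde)));
#' they satisfy theta_min + theta_max = 1 exactly.
#'
#' @param t entropy parameter in (0, 1/ln 2); the expression diverges at
#'   t = 1/ln 2.
#' @return an object of class `fermi_solution`: a list with `t`, `Ttilde`,
#'   `theta_min`, `theta_max`.
#' @examples
#' fermi_limit(0.4)$Ttilde  # ~0.092
#' @export
fermi_limit <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0)
    stop("'t' must be a single positive number")
  if (t >= 1 / log(2))
    stop("'t' must be below 1/ln(2); the width expression diverges there")
  Ttilde <- t / (6 * (1 - t * log(2)))
  structure(list(t = t, Ttilde = Ttilde,
                 theta_min = 1 / (1 + exp(1 / (2 * Ttilde))),
                 theta_max = 1 / (1 + exp(-1 / (2 * Ttilde)))),
            class = "fermi_solution")
}

#' Invert the small-t width relation
#'
#' Solves Ttilde = t / (6 (1 - t ln 2)) for t: t = 6 Ttilde /
#' (1 + 6 Ttilde ln 2).
#'
#' @param Ttilde positive width parameter.
#' @return the entropy parameter t.
#' @export
ttilde_to_t <- function(Ttilde) {
  if (!is.numeric(Ttilde) || any(Ttilde <= 0))
    stop("'Ttilde' must be positive")
  6 * Ttilde / (1 + 6 * Ttilde * log(2))
}

#' Critical parameter of the variance-diversity variant
#'
#' Under f = n (1 + t sigma^2) the model is compared between the two
#' candidate profiles discussed for this variant: the uniform density
#' (n = 1/2, sigma^2 = 1/12) and the Heaviside step (n = 1, sigma^2 =
#' 1/48). This routine evaluates both candidates with the package's grid
#' functionals and bisects for the fitness crossing; with exact moments
#' the crossing is t = 24.
#'
#' A caution on interpretation, developed in the methods vignette: the
#' uniform profile is never a local maximum of the variance-variant
#' fitness (for the two-level family, sigma^2(c) = 1/12 - c^2/16 and the
#' quadratic coefficient of f(c) is 1 + 5t/96 > 0 for every t), so the
#' changeover is meaningful only as a comparison between these two named
#' candidates, not as a property of the unrestricted optimum.
#'
#' @param grid a [trait_grid()] used to evaluate the candidate functionals
#'   (default 100 cells).
#' @param resolution bisection resolution in t (default 0.01).
#' @return a list with `t_c`, `sigma2_uniform`, `sigma2_step`, `method`.
#' @export
variance_variant_critical_t <- function(grid = trait_grid(100),
                                        resolution = 0.01) {
  uni <- make_uniform(grid)
  step <- make_step_profile(grid, 0.5, c(2, 0))
  n_u <- heterosexual_fraction(uni)
  n_s <- heterosexual_fraction(step)
  v_u <- trait_variance(uni)
  v_s <- trait_variance(step)
  gap <- function(t) n_s * (1 + t * v_s) - n_u * (1 + t * v_u)
  lo <- 5
  hi <- 60
  if (gap(lo) <= 0 || gap(hi) >= 0)
    stop("candidate fitness curves do not cross inside the bracket")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  list(t_c = (lo + hi) / 2, sigma2_uniform = v_u, sigma2_step = v_s,
       method = "candidates")
}
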