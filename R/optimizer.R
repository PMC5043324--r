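#' Metropolis annealing configuration
#'
#' Settings for [optimize_distribution()]. The proposal moves a random
#' amount of probability mass (at most `step_size` in density units,
#' annealed down to `step_end`) between two random locations, deposited
#' and withdrawn as Gaussian bumps whose width in cells is annealed from
#' `kernel_width` down to `kernel_width_end` alongside the inverse
#' temperature (coarse-to-fine). Withdrawal bumps are capped at the mass
#' available per cell, and the deposit carries exactly the withdrawn
#' total, so normalization is conserved exactly by every move. Moves are
#' accepted with probability min(1, exp(beta * df)); beta is annealed
#' geometrically from `beta_start` to `beta_end`.
#'
#' The kernel floor `kernel_width_end` sets the smoothness scale of the
#' search space. It is deliberately kept at or above about one cell: the
#' midpoint-rule pairing quadrature admits degenerate cell-scale
#' "comb" microstates (anti-aligned alternation of p and its mirror) that
#' reach n = 1 with no diversity cost, and restricting proposals to
#' smooth bumps excludes them kinetically. See the methods vignette.
#'
#' After annealing, a deterministic quench polishes the profile:
#' for the entropy measure, damped fixed-point iteration of the mollified
#' stationarity condition p proportional to exp(K_sigma df/dp / (n t dx)),
#' with a continuation over mollifier widths `quench_sigmas`; for the
#' variance measure, golden-section line-search sweeps over the same
#' smoothed exchange moves ([cpp_quench] internally).
#'
#' @param n_iter total proposals (default 2e5).
#' @param beta_start,beta_end inverse-temperature schedule endpoints.
#' @param step_size,step_end proposal mass-move magnitude schedule
#'   (density units).
#' @param kernel_width,kernel_width_end proposal bump width schedule
#'   (cells).
#' @param seed RNG seed.
#' @param tol relative-change convergence tolerance on the best fitness.
#' @param window iterations per convergence check.
#' @param trace_every iterations between recorded (iteration, f)
#'   checkpoints; 0 disables tracing.
#' @param quench logical: run the deterministic quench after annealing.
#' @param quench_sigmas mollifier-width continuation for the entropy-
#'   measure quench (cells).
#' @param quench_gamma damping factor of the fixed-point iteration.
#' @param quench_iters,quench_tol iteration cap and sup-norm tolerance of
#'   the quench.
#' @return an object of class `metropolis_config`.
#' @export
metropolis_config <- function(n_iter = 2e5, beta_start = 1e2,
                              beta_end = 1e6, step_size = 0.3,
                              step_end = 0.1, kernel_width = 4,
                              kernel_width_end = 1.5, seed = 1L,
                              tol = 1e-6, window = 1e4, trace_every = 2000,
                              quench = TRUE,
                              quench_sigmas = c(2, 1.2, 0.6),
                              quench_gamma = 0.3, quench_iters = 6000,
                              quench_tol = 1e-12) {
  stopifnot(n_iter >= 1, beta_start > 0, beta_start <= beta_end,
            step_size > 0, step_end > 0, kernel_width >= 0,
            kernel_width_end >= 0)
  structure(list(n_iter = as.integer(n_iter), beta_start = beta_start,
                 beta_end = beta_end, step_size = step_size,
                 step_end = step_end, kernel_width = kernel_width,
                 kernel_width_end = kernel_width_end,
                 seed = as.integer(seed), tol = tol,
                 window = as.integer(window),
                 trace_every = as.integer(trace_every), quench = quench,
                 quench_sigmas = quench_sigmas,
                 quench_gamma = quench_gamma,
                 quench_iters = as.integer(quench_iters),
                 quench_tol = quench_tol),
            class = "metropolis_config")
}

# boundary-renormalized Gaussian smoothing matrix (sigma in cells)
smoothing_matrix <- function(M, sigma) {
  R <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-R:R) / sigma)^2)
  K <- matrix(0, M, M)
  for (i in seq_len(M)) {
    j <- (i - R):(i + R)
    ok <- j >= 1 & j <= M
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

# number of significant direction reversals of the density profile;
# monotone-interface (step or Fermi-like) profiles score 0-1, comb
# contamination scores high
oscillation_count <- function(p, thresh = 0.01) {
  d <- diff(p)
  d <- d[abs(d) > thresh]
  if (length(d) < 2) return(0L)
  sum(diff(sign(d)) != 0)
}

# damped fixed-point iteration of the mollified stationarity condition
# (entropy measure): at an interior optimum of f = n(1 + t s) on the
# simplex, ln p is proportional to the fitness gradient; iterating
# p <- (1-gamma) p + gamma * normalize(exp(K_sigma grad)) converges to the
# smooth stationary profile, and the mollifier K_sigma suppresses the
# cell-scale comb instability of the raw discretized functional.
quench_entropy <- function(p, dx, t, sigma, gamma, iters, tol) {
  M <- length(p)
  K <- smoothing_matrix(M, sigma)
  delta <- Inf
  for (it in seq_len(iters)) {
    n <- min(max(0.5 * cpp_het_sum(p) * dx^2, 0), 1)
    s <- -sum(ifelse(p > 0, p * log(p), 0)) * dx
    gn <- 0.5 * cpp_het_sum_grad(p) * dx^2
    tgt <- drop(K %*% (gn * (1 + t * s) / (n * t * dx)))
    q <- exp(tgt - max(tgt))
    q <- q / (sum(q) * dx)
    p_new <- (1 - gamma) * p + gamma * q
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  list(p = p, iters = it, delta = delta, converged = delta < tol)
}

#' Optimize a trait distribution by Metropolis simulated annealing
#'
#' Maximizes the fitness f over discretized trait densities on `grid` by
#' simulated annealing with smoothed mass-exchange proposals, followed by
#' a deterministic quench (see [metropolis_config()]). The best-so-far
#' distribution is tracked throughout and handed to the quench. Solutions
#' come in mirror pairs p(x) and p(1 - x); the returned profile is
#' oriented with the (male) mass concentrated at low x (mean x <= 1/2).
#'
#' @param spec a [fitness_spec()].
#' @param grid a [trait_grid()] (the conventional default is 100 cells).
#' @param config a [metropolis_config()].
#' @param init `"uniform"`, `"random"`, or a normalized [trait_dist()] to
#'   start from.
#' @return an object of class `optimization_result`: a list with
#'   `dist` (the optimized `trait_dist`), `values` ([fitness()] of the
#'   returned distribution), `trace` (data frame of best-so-far fitness
#'   checkpoints), `converged`, `accepted_fraction`, and `spec`.
#' @examples
#' \donttest{
#' g <- trait_grid(100)
#' cfg <- metropolis_config(n_iter = 5e4, seed = 1)
#' res <- optimize_distribution(fitness_spec(5), g, cfg)
#' max(abs(res$dist$p - 1))  # ~0: at t >= 4 the optimum is uniform
#' }
#' @export
optimize_distribution <- function(spec, grid, config = metropolis_config(),
                                  init = "uniform") {
  if (!inherits(spec, "fitness_spec")) stop("expected a 'fitness_spec'")
  stopifnot(is_trait_grid(grid))
  if (!inherits(config, "metropolis_config"))
    stop("expected a 'metropolis_config'")
  if (is.character(init)) {
    init <- match.arg(init, c("uniform", "random"))
    if (init == "uniform") {
      p0 <- rep(1, grid$M)
    } else {
      set.seed(config$seed)
      p0 <- runif(grid$M)
      p0 <- p0 / (sum(p0) * grid$dx)
    }
  } else {
    check_dist(init)
    if (init$grid$M != grid$M) stop("init grid does not match 'grid'")
    p0 <- init$p
  }

  measure <- if (spec$diversity_measure == "entropy") 0L else 1L
  set.seed(config$seed)
  ann <- cpp_metropolis(p0, grid$dx, spec$t, measure, config$n_iter,
                        config$beta_start, config$beta_end,
                        config$step_size, config$trace_every, config$tol,
                        config$window, -1L, config$kernel_width,
                        config$kernel_width_end, config$step_end)
  p <- ann$p
  converged <- ann$converged
  if (config$quench) {
    if (measure == 0L && spec$t > 0) {
      conv <- TRUE
      for (sg in config$quench_sigmas) {
        q <- quench_entropy(p, grid$dx, spec$t, sg, config$quench_gamma,
                            config$quench_iters, config$quench_tol)
        p <- q$p
        conv <- conv && q$converged
      }
      # continue the mollifier toward zero while the fixed point stays
      # smooth: at moderate t the sharp plateau corners are only
      # resolved by a narrow mollifier, while at small t a narrow
      # mollifier re-admits the cell-scale comb instability — the
      # oscillation count detects that and stops the continuation
      sg <- min(config$quench_sigmas) / 2
      while (sg >= 0.1) {
        q <- quench_entropy(p, grid$dx, spec$t, sg, config$quench_gamma,
                            4L * config$quench_iters, config$quench_tol)
        if (q$delta > 1e-7 ||
            oscillation_count(q$p) > oscillation_count(p)) break
        p <- q$p
        sg <- sg / 2
      }
      converged <- conv
    } else {
      q <- cpp_quench(p, grid$dx, spec$t, measure,
                      config$kernel_width_end, 0.5, 60L, 1e-14)
      p <- q$p
      converged <- q$converged
    }
  }
  dist <- trait_dist(grid, p / (sum(p) * grid$dx))
  if (sum(grid$x * dist$p) * grid$dx > 0.5) dist <- mirror_dist(dist)
  structure(list(
    dist = dist,
    values = fitness(dist, spec),
    trace = data.frame(iteration = ann$trace_iter, f = ann$trace_f),
    converged = converged,
    accepted_fraction = ann$accepted_fraction,
    spec = spec), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result> t = %g (%s): f = %.6f, accepted %.1f%%, %s\n",
    x$spec$t, x$spec$diversity_measure, x$values$f,
    100 * x$accepted_fraction,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Project an optimized profile onto a parametric family
#'
#' Least-squares fit of a named profile family to a (typically noisy
#' Monte Carlo) trait distribution, for compact reporting: the two-level
#' step (parameter c), the antisymmetric three- or four-level step
#' families, or the Fermi form (parameter Ttilde).
#'
#' @param result an `optimization_result` from [optimize_distribution()],
#'   or a bare [trait_dist()].
#' @param family `"two_step"`, `"k_step"`, or `"fermi"`.
#' @param k number of levels for `family = "k_step"` (3 or 4).
#' @return a list with `family`, `parameters` (named vector), `rms`
#'   (root-mean-square residual), and `converged`.
#' @export
polish_profile <- function(result, family = c("two_step", "k_step", "fermi"),
                           k = 3) {
  family <- match.arg(family)
  dist <- if (inherits(result, "optimization_result")) result$dist else result
  check_dist(dist)
  grid <- dist$grid
  p <- dist$p
  if (sum(grid$x * p) * grid$dx > 0.5) p <- rev(p)   # male mass at low x
  rms_of <- function(model) sqrt(mean((p - model$p)^2))

  out <- tryCatch({
    if (family == "two_step") {
      o <- optimize(function(c0)
        rms_of(make_step_profile(grid, 0.5, c(1 + c0, 1 - c0))),
        c(0, 1), tol = 1e-10)
      list(parameters = c(c = o$minimum), rms = o$objective)
    } else if (family == "fermi") {
      o <- optimize(function(Tt) rms_of(make_fermi(grid, Tt)),
                    c(1e-4, 1), tol = 1e-10)
      list(parameters = c(Ttilde = o$minimum), rms = o$objective)
    } else if (k == 3) {
      obj <- function(par) {
        a <- min(max(par[1], 1e-6), 0.5 - 1e-6)
        c0 <- min(max(par[2], 0), 1)
        rms_of(make_step_profile(grid, c(a, 1 - a), c(1 + c0, 1, 1 - c0)))
      }
      best <- NULL
      for (a0 in c(0.15, 0.3, 0.45)) for (c0 in c(0.3, 0.7)) {
        o <- optim(c(a0, c0), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000))
        if (is.null(best) || o$value < best$value) best <- o
      }
      list(parameters = c(a = min(max(best$par[1], 0), 0.5),
                          c = min(max(best$par[2], 0), 1)),
           rms = best$value)
    } else if (k == 4) {
      obj <- function(par) {
        a <- min(max(par[1], 1e-6), 0.5 - 1e-6)
        c1 <- min(max(par[2], 0), 1)
        c2 <- min(max(par[3], 0), c1)
        rms_of(make_step_profile(grid, c(a, 0.5, 1 - a),
                                 c(1 + c1, 1 + c2, 1 - c2, 1 - c1)))
      }
      best <- NULL
      for (a0 in c(0.15, 0.3)) for (c1 in c(0.5, 0.9)) for (c2 in c(0.1, 0.4)) {
        o <- optim(c(a0, c1, c2), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 3000))
        if (is.null(best) || o$value < best$value) best <- o
      }
      list(parameters = c(a = min(max(best$par[1], 0), 0.5),
                          c1 = min(max(best$par[2], 0), 1),
                          c2 = min(max(best$par[3], 0), 1)),
           rms = best$value)
    } else stop("'k' must be 3 or 4")
  }, error = function(e) NULL)

  if (is.null(out))
    return(list(family = family, parameters = NULL, rms = NA_real_,
                converged = FALSE))
  c(list(family = family), out, list(converged = TRUE))
}
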