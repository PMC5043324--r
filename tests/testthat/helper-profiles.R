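# Shared fixtures: the conventional 100-cell grid and named profiles,
# plus a per-file cache for expensive optimizer runs.

g100 <- trait_grid(100)

two_step <- function(c, grid = g100)
  make_step_profile(grid, 0.5, c(1 + c, 1 - c))

heaviside_low <- function(grid = g100)
  make_step_profile(grid, 0.5, c(2, 0))

.opt_cache <- new.env(parent = emptyenv())

opt_run <- function(t, measure = "entropy", seed = 1L,
                    n_iter = 2e5, quench = TRUE) {
  key <- paste(t, measure, seed, n_iter, quench, sep = "|")
  if (!is.null(.opt_cache[[key]])) return(.opt_cache[[key]])
  res <- optimize_distribution(
    fitness_spec(t, measure), g100,
    metropolis_config(n_iter = n_iter, seed = seed, quench = quench))
  .opt_cache[[key]] <- res
  res
}

# OLS of ln(2/p - 1) on (x - 1/2) over cells away from saturation,
# the standard diagnostic of the Fermi-function profile shape
fermi_slope_fit <- function(dist, lo = 0.05, hi = 1.95) {
  p <- dist$p
  x <- dist$grid$x
  if (sum(x * p) * dist$grid$dx > 0.5) p <- rev(p)
  keep <- p > lo & p < hi
  fit <- lm(log(2 / p[keep] - 1) ~ I(x[keep] - 0.5))
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       n_cells = sum(keep))
}
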