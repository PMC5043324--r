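#' Uniform discretization of the trait interval
#'
#' Divides the trait interval \[0, 1\] into `M` equal cells with midpoints
#' x_i = (i + 1/2)/M. An even `M` (the default elsewhere is 100) makes the
#' mirror map i <-> M - 1 - i exact on the grid, which the symmetry-based
#' functionals rely on: x_{M-1-i} = 1 - x_i holds to machine precision.
#'
#' @param M integer number of cells, at least 2.
#' @return An object of class `trait_grid` with elements `M`, `x`
#'   (cell midpoints), and `dx` (cell width, 1/M).
#' @examples
#' g <- trait_grid(100)
#' all.equal(rev(g$x), 1 - g$x)
#' @export
trait_grid <- function(M) {
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 2L)
    stop("'M' must be a single integer >= 2")
  structure(list(M = M, x = (seq_len(M) - 0.5) / M, dx = 1 / M),
            class = "trait_grid")
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("<trait_grid> M = %d cells, dx = %g\n", x$M, x$dx))
  invisible(x)
}

is_trait_grid <- function(x) inherits(x, "trait_grid")

#' Construct a discretized trait density
#'
#' Wraps nonnegative density values at the grid midpoints into a
#' `trait_dist` object, optionally renormalizing so that sum(p) * dx = 1.
#' `p` is the male trait density; the female density, and the two desire
#' densities, follow from the mirror symmetry q(x) = p(1 - x).
#'
#' @param grid a [trait_grid()].
#' @param p numeric vector of length `grid$M`, nonnegative density values.
#' @param normalize if `TRUE`, divide by `sum(p) * dx` instead of requiring
#'   normalization on input.
#' @return An object of class `trait_dist` with elements `grid` and `p`.
#' @export
trait_dist <- function(grid, p, normalize = FALSE) {
  stopifnot(is_trait_grid(grid))
  p <- as.numeric(p)
  if (length(p) != grid$M)
    stop("'p' must have length grid$M")
  if (anyNA(p) || any(p < 0))
    stop("density values must be nonnegative and non-missing")
  tot <- sum(p) * grid$dx
  if (normalize) {
    if (tot <= 0) stop("cannot normalize a zero density")
    p <- p / tot
  } else if (abs(tot - 1) > 1e-9) {
    stop(sprintf("density is not normalized: sum(p)*dx = %.12g", tot))
  }
  structure(list(grid = grid, p = p), class = "trait_dist")
}

#' @export
print.trait_dist <- function(x, ...) {
  cat(sprintf("<trait_dist> M = %d, mean x = %.4f, max p = %.4f\n",
              x$grid$M, sum(x$grid$x * x$p) * x$grid$dx, max(x$p)))
  invisible(x)
}

#' @export
plot.trait_dist <- function(x, ...) {
  graphics::plot(x$grid$x, x$p, type = "s", xlab = "trait x",
                 ylab = "density p(x)", ...)
  invisible(x)
}

check_dist <- function(dist) {
  if (!inherits(dist, "trait_dist"))
    stop("expected a 'trait_dist' object")
  tot <- sum(dist$p) * dist$grid$dx
  if (abs(tot - 1) > 1e-9)
    stop(sprintf("distribution is not normalized: sum(p)*dx = %.12g", tot))
  invisible(dist)
}

#' Mirror a trait distribution
#'
#' Returns the distribution with p(x) replaced by p(1 - x) (reversal of the
#' density vector). All functionals are invariant under this map.
#'
#' @param dist a [trait_dist()].
#' @return the mirrored `trait_dist`.
#' @export
mirror_dist <- function(dist) {
  check_dist(dist)
  trait_dist(dist$grid, rev(dist$p))
}

#' The uniform trait distribution p(x) = 1
#'
#' The diversity-maximizing density: every trait value equally likely for
#' each individual regardless of sex. This is the optimal distribution for
#' all t >= 4 under the entropy diversity measure.
#'
#' @param grid a [trait_grid()].
#' @return a `trait_dist` with all p_i = 1.
#' @export
make_uniform <- function(grid) {
  stopifnot(is_trait_grid(grid))
  trait_dist(grid, rep(1, grid$M))
}

#' Piecewise-constant (step) trait distributions
#'
#' Builds a step profile with the given breakpoints and level heights,
#' assigning cells by midpoint membership and renormalizing after
#' discretization. The two-level profile `make_step_profile(g, 0.5,
#' c(1 + c, 1 - c))` is the shape the optimal density takes just below the
#' t = 4 symmetry-breaking transition; `levels = c(2, 0)` gives the
#' Heaviside profile with all (male) mass below x = 1/2.
#'
#' @param grid a [trait_grid()].
#' @param breakpoints increasing positions strictly inside (0, 1); may be
#'   empty for a constant profile.
#' @param levels nonnegative heights, one more than `length(breakpoints)`.
#' @return a normalized `trait_dist`.
#' @examples
#' g <- trait_grid(100)
#' two_step <- make_step_profile(g, 0.5, c(1.5, 0.5))
#' heterosexual_fraction(two_step)  # 3/2 - 1/(1 + 0.25) = 0.7
#' @export
make_step_profile <- function(grid, breakpoints = numeric(0), levels = 1) {
  stopifnot(is_trait_grid(grid))
  breakpoints <- as.numeric(breakpoints)
  levels <- as.numeric(levels)
  if (length(levels) != length(breakpoints) + 1L)
    stop("need length(levels) == length(breakpoints) + 1")
  if (length(breakpoints) > 0 &&
      (any(diff(breakpoints) <= 0) || any(breakpoints <= 0) ||
       any(breakpoints >= 1)))
    stop("breakpoints must be strictly increasing and inside (0, 1)")
  if (any(levels < 0)) stop("levels must be nonnegative")
  idx <- findInterval(grid$x, c(0, breakpoints, 1), rightmost.closed = TRUE)
  trait_dist(grid, levels[idx], normalize = TRUE)
}

#' Fermi-function trait distribution
#'
#' The limiting shape of the optimal density at small entropy parameter:
#' p(x) = 2 / (1 + exp((x - 1/2)/Ttilde)), renormalized on the grid (the
#' analytic normalization is exact; the discretization correction is
#' O(dx^2)). Satisfies p(x) + p(1 - x) = 2.
#'
#' @param grid a [trait_grid()].
#' @param Ttilde positive width parameter (the effective temperature of the
#'   Fermi form); see [fermi_limit()] for its small-t relation to t.
#' @return a normalized `trait_dist`.
#' @export
make_fermi <- function(grid, Ttilde) {
  stopifnot(is_trait_grid(grid))
  if (!is.numeric(Ttilde) || length(Ttilde) != 1L || is.na(Ttilde) ||
      Ttilde <= 0)
    stop("'Ttilde' must be a single positive number")
  p <- 2 / (1 + exp((grid$x - 0.5) / Ttilde))
  trait_dist(grid, p, normalize = TRUE)
}

#' Read and write trait distributions as TSV
#'
#' The on-disk format is a two-column tab-separated table (x, p) preceded
#' by a `# M=<int>` header comment. The reader validates normalization.
#'
#' @param dist a [trait_dist()].
#' @param path file path.
#' @return `write_trait_dist` returns `path` invisibly; `read_trait_dist`
#'   returns a `trait_dist`.
#' @export
write_trait_dist <- function(dist, path) {
  check_dist(dist)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# M=%d", dist$grid$M), con)
  write.table(data.frame(x = dist$grid$x, p = dist$p), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trait_dist
#' @export
read_trait_dist <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexpr("(?<=# M=)[0-9]+", header, perl = TRUE))
  if (length(m) != 1L) stop("missing '# M=<int>' header in ", path)
  M <- as.integer(m)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (nrow(tab) != M) stop("row count does not match the M header")
  grid <- trait_grid(M)
  if (max(abs(tab$x - grid$x)) > 1e-8)
    stop("grid midpoints in file do not match a uniform M-cell grid")
  trait_dist(grid, tab$p)
}
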