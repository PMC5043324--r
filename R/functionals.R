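#' Fitness specification
#'
#' Bundles the dimensionless entropy parameter t (the relative weight of
#' trait diversity in the fitness; t plays the role of a temperature) with
#' the choice of diversity measure: the per-capita Shannon entropy s (the
#' model's default) or the trait variance sigma^2 (the alternative
#' discussed separately, with markedly different phenomenology).
#'
#' @param t nonnegative entropy parameter.
#' @param diversity_measure `"entropy"` or `"variance"`.
#' @return an object of class `fitness_spec`.
#' @export
fitness_spec <- function(t, diversity_measure = c("entropy", "variance")) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single nonnegative number")
  diversity_measure <- match.arg(diversity_measure)
  structure(list(t = t, diversity_measure = diversity_measure),
            class = "fitness_spec")
}

#' Heterosexual fraction of a trait distribution
#'
#' Midpoint-rule quadrature of the pairing double integral
#' \deqn{n = \frac12 \int_0^1\!\!\int_0^1
#'   \frac{[p(x_1)p(1-x_2)]^2 + [p(1-x_1)p(x_2)]^2}
#'        {p(x_1)p(1-x_2) + p(1-x_1)p(x_2)} \, dx_1 dx_2,}
#' the expected fraction of opposite-sex pairings when each reciprocal
#' preference group is matched at random against its counterpart. Cells
#' where the denominator vanishes hold no individuals and contribute 0.
#' The result is clamped to \[0, 1\] to absorb rounding at the 1e-12 level.
#'
#' Uniform p gives n = 1/2 (pairings equally likely to be same- or
#' opposite-sex); disjoint male/female supports give n = 1.
#'
#' @param dist a normalized [trait_dist()].
#' @return the heterosexual fraction, a number in \[0, 1\].
#' @export
heterosexual_fraction <- function(dist) {
  check_dist(dist)
  # disjoint male/female supports: all pairings heterosexual, exactly
  if (all(dist$p * rev(dist$p) == 0)) return(1)
  n <- 0.5 * cpp_het_sum(dist$p) * dist$grid$dx^2
  min(max(n, 0), 1)
}

#' Per-capita trait entropy
#'
#' The Shannon entropy s = -integral p ln p dx of the trait density, in
#' nats, by midpoint quadrature with the convention 0 ln 0 = 0. s <= 0
#' always, with equality exactly at the uniform density p = 1; the
#' two-level profile with disjoint supports has s = -ln 2.
#'
#' @param dist a normalized [trait_dist()].
#' @return the entropy in nats (a nonpositive number).
#' @export
trait_entropy <- function(dist) {
  check_dist(dist)
  p <- dist$p
  -sum(ifelse(p > 0, p * log(p), 0)) * dist$grid$dx
}

#' Trait variance
#'
#' The variance sigma^2 = integral (x - <x>)^2 p(x) dx of the trait
#' density, with <x> = integral x p(x) dx, by midpoint quadrature. Bounded
#' by 1/4 on \[0, 1\]; the uniform density has sigma^2 = 1/12 (up to an
#' O(dx^2) quadrature correction) and the Heaviside profile 1/48.
#'
#' @param dist a normalized [trait_dist()].
#' @return the variance, a number in \[0, 0.25\].
#' @export
trait_variance <- function(dist) {
  check_dist(dist)
  x <- dist$grid$x
  m <- sum(x * dist$p) * dist$grid$dx
  sum((x - m)^2 * dist$p) * dist$grid$dx
}

#' Fitness of a trait distribution
#'
#' Evaluates f = n (1 + t s) (entropy measure) or f = n (1 + t sigma^2)
#' (variance measure), reporting all four functionals.
#'
#' @param dist a normalized [trait_dist()].
#' @param spec a [fitness_spec()].
#' @return an object of class `functional_values`: a list with elements
#'   `n`, `s`, `sigma2`, `f`, `t`, `diversity_measure`.
#' @examples
#' g <- trait_grid(100)
#' fitness(make_uniform(g), fitness_spec(10))$f  # s = 0, so f = n = 1/2
#' @export
fitness <- function(dist, spec) {
  check_dist(dist)
  if (!inherits(spec, "fitness_spec")) stop("expected a 'fitness_spec'")
  n <- heterosexual_fraction(dist)
  s <- trait_entropy(dist)
  sigma2 <- trait_variance(dist)
  div <- if (spec$diversity_measure == "entropy") s else sigma2
  structure(list(n = n, s = s, sigma2 = sigma2, f = n * (1 + spec$t * div),
                 t = spec$t, diversity_measure = spec$diversity_measure),
            class = "functional_values")
}

#' @export
print.functional_values <- function(x, ...) {
  cat(sprintf(
    "<functional_values> t = %g (%s)\n  n = %.6f  s = %.6f  sigma2 = %.6f  f = %.6f\n",
    x$t, x$diversity_measure, x$n, x$s, x$sigma2, x$f))
  invisible(x)
}

#' Serialize functional values to JSON
#'
#' Writes a flat JSON record `{t, diversity_measure, n, s, sigma2, f}`.
#'
#' @param values a `functional_values` object from [fitness()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_functional_values <- function(values, path) {
  if (!inherits(values, "functional_values"))
    stop("expected a 'functional_values' object")
  jsonlite::write_json(
    values[c("t", "diversity_measure", "n", "s", "sigma2", "f")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_functional_values
#' @export
read_functional_values <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(v[c("n", "s", "sigma2", "f", "t", "diversity_measure")],
            class = "functional_values")
}
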