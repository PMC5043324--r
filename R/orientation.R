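#' Sexual orientation induced by a desired trait value
#'
#' The orientation of an individual desiring trait x_c is the proportion
#' of same-sex individuals among the group it is attracted to:
#' theta(x_c) = p(x_c) / (p(x_c) + p(1 - x_c)) for a male (and the mirror
#' for a female). Evaluated on the grid by nearest-cell lookup. Satisfies
#' theta(x) + theta(1 - x) = 1 wherever both are defined; where both
#' densities vanish no individual desires that trait from either side and
#' `NA` is returned.
#'
#' @param x_c desired trait value(s) in \[0, 1\].
#' @param dist a normalized [trait_dist()].
#' @return orientation value(s) in \[0, 1\], `NA` where undefined.
#' @examples
#' g <- trait_grid(100)
#' orientation_of(0.25, make_uniform(g))  # 0.5: no sexualization of traits
#' @export
orientation_of <- function(x_c, dist) {
  check_dist(dist)
  if (any(x_c < 0 | x_c > 1, na.rm = TRUE))
    stop("'x_c' must lie in [0, 1]")
  M <- dist$grid$M
  u <- x_c * M
  r <- round(u)
  idx <- floor(u) + 1L
  # values exactly on an interior cell boundary: tie-break away from
  # x = 1/2, so that x_c and 1 - x_c land on mirror cells and the
  # involution theta(x) + theta(1 - x) = 1 survives at boundaries
  on_edge <- abs(u - r) < 1e-9 & r >= 1 & r <= M - 1
  idx[on_edge] <- ifelse(x_c[on_edge] < 0.5, r[on_edge], r[on_edge] + 1L)
  idx <- pmin(pmax(idx, 1L), M)
  p1 <- dist$p[idx]
  p2 <- dist$p[M + 1L - idx]
  out <- ifelse(p1 + p2 > 0, p1 / (p1 + p2), NA_real_)
  out
}

#' Distribution of sexual orientation P(theta)
#'
#' Pushforward of the desire density p_c(x_c) = p(1 - x_c) through the
#' orientation map: P(theta) = integral p_c(x_c) delta(theta -
#' theta(x_c)) dx_c. For step-like profiles the result is a finite set of
#' atoms (theta_k, w_k); orientation values agreeing within `merge_tol`
#' are merged. When at least `continuum_from` distinct values remain (the
#' small-t continuum regime), the result is instead reported as a
#' tabulated density obtained by the change of variables on the sorted
#' (theta, weight) sequence.
#'
#' @param dist a normalized [trait_dist()].
#' @param merge_tol atoms closer than this are merged (default 1e-6).
#' @param continuum_from minimum number of distinct values for the
#'   continuous representation (default 25).
#' @return an object of class `orientation_dist`: a list with `kind`
#'   ("atomic" or "continuous"), `atoms` (data frame theta/weight), and,
#'   when continuous, `density` (data frame theta/P).
#' @export
orientation_distribution <- function(dist, merge_tol = 1e-6,
                                     continuum_from = 25) {
  check_dist(dist)
  M <- dist$grid$M
  w <- rev(dist$p) * dist$grid$dx          # p_c(x_i) dx
  p1 <- dist$p
  p2 <- rev(dist$p)
  theta <- ifelse(p1 + p2 > 0, p1 / (p1 + p2), NA_real_)
  keep <- !is.na(theta) & w > 0
  theta <- theta[keep]
  w <- w[keep]
  o <- order(theta)
  theta <- theta[o]
  w <- w[o]
  # single-pass merge of values agreeing within merge_tol
  mt <- numeric(0)
  mw <- numeric(0)
  for (i in seq_along(theta)) {
    if (length(mt) > 0 && theta[i] - mt[length(mt)] <= merge_tol) {
      j <- length(mt)
      mt[j] <- (mt[j] * mw[j] + theta[i] * w[i]) / (mw[j] + w[i])
      mw[j] <- mw[j] + w[i]
    } else {
      mt <- c(mt, theta[i])
      mw <- c(mw, w[i])
    }
  }
  atoms <- data.frame(theta = mt, weight = mw)
  if (nrow(atoms) < continuum_from) {
    return(structure(list(kind = "atomic", atoms = atoms),
                     class = "orientation_dist"))
  }
  # continuum regime: local change-of-variables density with a two-sided
  # bandwidth (one-sided at the ends)
  k <- nrow(atoms)
  bw <- numeric(k)
  bw[1] <- atoms$theta[2] - atoms$theta[1]
  bw[k] <- atoms$theta[k] - atoms$theta[k - 1]
  if (k > 2)
    bw[2:(k - 1)] <- (atoms$theta[3:k] - atoms$theta[1:(k - 2)]) / 2
  P <- atoms$weight / bw
  # renormalize so the trapezoid integral of the tabulated density is
  # exactly the total pushforward weight
  trapz <- sum(diff(atoms$theta) * (P[-k] + P[-1]) / 2)
  P <- P * sum(atoms$weight) / trapz
  dens <- data.frame(theta = atoms$theta, P = P)
  structure(list(kind = "continuous", atoms = atoms, density = dens),
            class = "orientation_dist")
}

#' @export
print.orientation_dist <- function(x, ...) {
  if (x$kind == "atomic") {
    cat(sprintf("<orientation_dist> atomic, %d class(es):\n", nrow(x$atoms)))
    print(round(x$atoms, 6))
  } else {
    cat(sprintf("<orientation_dist> continuous, %d support points on [%.4f, %.4f]\n",
                nrow(x$density), min(x$density$theta), max(x$density$theta)))
  }
  invisible(x)
}

#' Closed-form orientation density of the Fermi profile
#'
#' For the Fermi trait profile the orientation map is the logistic
#' theta(x_c) = 1/(1 + exp((x_c - 1/2)/Ttilde)) and the pushforward of
#' p_c has the closed form P(theta) = 2 Ttilde / theta on
#' \[theta_min, theta_max\], with theta_min = 1/(1 + exp(1/(2 Ttilde)))
#' and theta_max its mirror. The normalization
#' 2 Ttilde ln(theta_max/theta_min) = 1 is an exact identity, so there
#' are no strictly heterosexual (theta = 0) or homosexual (theta = 1)
#' individuals at any finite t.
#'
#' @param Ttilde positive width parameter.
#' @return an object of class `orientation_density`: a list with
#'   `Ttilde`, `theta_min`, `theta_max`, and `pdf` (a vectorized density
#'   function, zero outside the support).
#' @export
analytic_p_theta <- function(Ttilde) {
  if (!is.numeric(Ttilde) || length(Ttilde) != 1L || is.na(Ttilde) ||
      Ttilde <= 0)
    stop("'Ttilde' must be a single positive number")
  theta_min <- 1 / (1 + exp(1 / (2 * Ttilde)))
  theta_max <- 1 / (1 + exp(-1 / (2 * Ttilde)))
  pdf <- function(theta)
    ifelse(theta >= theta_min & theta <= theta_max, 2 * Ttilde / theta, 0)
  structure(list(Ttilde = Ttilde, theta_min = theta_min,
                 theta_max = theta_max, pdf = pdf),
            class = "orientation_density")
}

#' Bin an orientation distribution into categories
#'
#' Integrates an orientation distribution over consecutive bins, the
#' seven-category (Kinsey-style) equal-width partition of \[0, 1\] by
#' default. Atoms falling exactly on an interior edge are assigned to the
#' lower bin. For the closed-form continuum density the bin mass
#' 2 Ttilde ln(hi/lo) is integrated exactly; for a tabulated density the
#' integral is trapezoidal.
#'
#' @param pdist an `orientation_dist` (from [orientation_distribution()])
#'   or an `orientation_density` (from [analytic_p_theta()]).
#' @param edges increasing break points from 0 to 1 (default seven equal
#'   bins).
#' @return an object of class `binned_orientation`: a data frame with
#'   columns `bin_low`, `bin_high`, `proportion`.
#' @export
bin_orientation <- function(pdist, edges = seq(0, 1, length.out = 8)) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0) ||
      abs(edges[1]) > 1e-12 || abs(edges[length(edges)] - 1) > 1e-12)
    stop("'edges' must increase from 0 to 1")
  nb <- length(edges) - 1L
  prop <- numeric(nb)
  if (inherits(pdist, "orientation_density")) {
    lo <- pmax(edges[-length(edges)], pdist$theta_min)
    hi <- pmin(edges[-1], pdist$theta_max)
    prop <- ifelse(hi > lo, 2 * pdist$Ttilde * log(hi / lo), 0)
  } else if (inherits(pdist, "orientation_dist")) {
    if (pdist$kind == "atomic") {
      # interior edges go to the lower bin
      bin <- findInterval(pdist$atoms$theta, edges, left.open = TRUE)
      bin[bin == 0L] <- 1L
      bin[bin > nb] <- nb
      for (k in seq_len(nb)) prop[k] <- sum(pdist$atoms$weight[bin == k])
    } else {
      d <- pdist$density
      fine <- sort(unique(c(edges, seq(min(d$theta), max(d$theta),
                                       length.out = 2000))))
      fine <- fine[fine >= min(d$theta) & fine <= max(d$theta)]
      Pv <- stats::approx(d$theta, d$P, xout = fine, rule = 2)$y
      for (k in seq_len(nb)) {
        sel <- fine >= edges[k] & fine <= edges[k + 1]
        if (sum(sel) > 1) {
          xs <- fine[sel]
          ys <- Pv[sel]
          prop[k] <- sum(diff(xs) * (utils::head(ys, -1) + ys[-1]) / 2)
        }
      }
      prop <- prop / sum(prop)
    }
  } else stop("unsupported orientation distribution object")
  out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                    proportion = prop)
  class(out) <- c("binned_orientation", "data.frame")
  out
}

#' Read and write binned orientation proportions as TSV
#'
#' Three tab-separated columns: `bin_low`, `bin_high`, `proportion`.
#'
#' @param binned a `binned_orientation` data frame.
#' @param path file path.
#' @return `write_binned_orientation` returns `path` invisibly;
#'   `read_binned_orientation` returns a `binned_orientation`.
#' @export
write_binned_orientation <- function(binned, path) {
  write.table(as.data.frame(binned)[, c("bin_low", "bin_high", "proportion")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binned_orientation
#' @export
read_binned_orientation <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("bin_low", "bin_high", "proportion") %in% names(tab)))
  class(tab) <- c("binned_orientation", "data.frame")
  tab
}

#' Fit the continuum width to binned orientation proportions
#'
#' Least-squares fit, in log space, of the binned closed-form continuum
#' density P(theta) = 2 Ttilde / theta to observed bin proportions
#' (log residuals match the double-logarithmic presentation in which such
#' data are usually examined). The scalar search runs over Ttilde in
#' (0, 0.5\]; the corresponding entropy parameter is recovered by
#' inverting the small-t width relation ([ttilde_to_t()]).
#'
#' @param binned a `binned_orientation` data frame; at least 3 bins must
#'   have positive proportion.
#' @return a list with `Ttilde_hat`, `t_hat`, `rss` (residual sum of
#'   squares in log space), `n_bins_used`, `converged`.
#' @examples
#' b <- bin_orientation(analytic_p_theta(0.09))
#' fit_ttilde(b)$Ttilde_hat  # recovers 0.09
#' @export
fit_ttilde <- function(binned) {
  if (!inherits(binned, "binned_orientation"))
    stop("expected a 'binned_orientation'")
  obs <- binned$proportion
  if (sum(obs > 0) < 3)
    stop("fit failure: need at least 3 bins with positive proportion")
  obs <- obs / sum(obs)
  edges <- c(binned$bin_low, binned$bin_high[length(binned$bin_high)])
  objective <- function(Tt) {
    pred <- bin_orientation(analytic_p_theta(Tt), edges)$proportion
    use <- obs > 0 & pred > 0
    if (sum(use) < 3) return(1e10)
    sum((log(pred[use]) - log(obs[use]))^2)
  }
  o <- optimize(objective, c(1e-4, 0.5), tol = 1e-8)
  list(Ttilde_hat = o$minimum, t_hat = ttilde_to_t(o$minimum),
       rss = o$objective, n_bins_used = sum(obs > 0),
       converged = is.finite(o$objective) && o$objective < 1e10)
}
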