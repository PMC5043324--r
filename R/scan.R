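#' Count orientation classes of a trait distribution
#'
#' Clusters the population's orientation values into classes: the
#' weighted orientation atoms of `dist` are sorted and merged by single
#' linkage with gap threshold `merge_tol`; classes carrying less than
#' `min_weight` of the population are discarded. A uniform profile has a
#' single class at theta = 1/2; a two-level step has two classes at
#' (1 +- c)/2. When 25 or more distinct orientation values are present
#' (the small-t continuum regime, where separated classes degenerate
#' into an interval) the distinct-value count is reported directly and
#' no merging or weight filtering is applied.
#'
#' @param dist a normalized [trait_dist()].
#' @param merge_tol single-linkage gap threshold (default 0.02).
#' @param min_weight discard classes lighter than this (default 0.01).
#' @return a list with `class_count`, `levels` (weighted mean theta per
#'   class), `weights`.
#' @export
detect_classes <- function(dist, merge_tol = 0.02, min_weight = 0.01) {
  check_dist(dist)
  od <- orientation_distribution(dist, merge_tol = 1e-6,
                                 continuum_from = Inf)
  atoms <- od$atoms
  if (nrow(atoms) == 0)
    return(list(class_count = 0L, levels = numeric(0), weights = numeric(0)))
  if (nrow(atoms) >= 25) {
    # continuum regime: orientations fill out an interval and the notion
    # of separated classes degenerates; report the distinct values
    return(list(class_count = nrow(atoms), levels = atoms$theta,
                weights = atoms$weight))
  }
  gap <- diff(atoms$theta)
  cls <- cumsum(c(1, as.integer(gap > merge_tol)))
  levels <- tapply(atoms$theta * atoms$weight, cls, sum) /
    tapply(atoms$weight, cls, sum)
  weights <- tapply(atoms$weight, cls, sum)
  keep <- weights >= min_weight
  list(class_count = sum(keep), levels = as.numeric(levels[keep]),
       weights = as.numeric(weights[keep]))
}

#' Scan configuration
#'
#' @param t_values entropy parameters to scan (default covers all regimes
#'   of the cascade).
#' @param M grid cells (default 100).
#' @param metropolis a [metropolis_config()]; its seed is combined with
#'   `seed` and the scan index.
#' @param seed base RNG seed.
#' @param diversity_measure `"entropy"` or `"variance"`.
#' @param out_dir optional output directory; when non-`NULL`,
#'   [run_scan()] writes one TSV per optimized distribution and a master
#'   JSON summary there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(t_values = c(5, 4, 3.9, 3, 2, 1.7, 1.4, 1.17, 0.8,
                                    0.4, 0.2, 0.1),
                       M = 100, metropolis = metropolis_config(),
                       seed = 1L,
                       diversity_measure = c("entropy", "variance"),
                       out_dir = NULL) {
  stopifnot(all(t_values >= 0), M >= 10)
  structure(list(t_values = as.numeric(t_values), M = as.integer(M),
                 metropolis = metropolis, seed = as.integer(seed),
                 diversity_measure = match.arg(diversity_measure),
                 out_dir = out_dir),
            class = "run_config")
}

# choose the most parsimonious family whose projection fits the profile
best_family_fit <- function(dist, rms_ok = 0.05) {
  fits <- list(
    list(label = "two_step", fit = polish_profile(dist, "two_step"), k = 2),
    list(label = "k3", fit = polish_profile(dist, "k_step", k = 3), k = 3),
    list(label = "k4", fit = polish_profile(dist, "k_step", k = 4), k = 4),
    list(label = "fermi", fit = polish_profile(dist, "fermi"), k = Inf))
  ok <- Filter(function(z) isTRUE(z$fit$converged) && !is.na(z$fit$rms) &&
                 z$fit$rms <= rms_ok, fits)
  if (length(ok) == 0) return(NULL)
  ok[[which.min(vapply(ok, function(z) z$k + z$fit$rms, numeric(1)))]]
}

family_profile <- function(grid, choice) {
  par <- choice$fit$parameters
  switch(choice$label,
    two_step = make_step_profile(grid, 0.5, c(1 + par["c"], 1 - par["c"])),
    k3 = {
      a <- par["a"]
      if (a >= 0.5 - 1e-9)
        make_step_profile(grid, 0.5, c(1 + par["c"], 1 - par["c"]))
      else
        make_step_profile(grid, c(a, 1 - a),
                          c(1 + par["c"], 1, 1 - par["c"]))
    },
    k4 = {
      a <- par["a"]
      br <- unique(pmin(pmax(c(a, 0.5, 1 - a), 1e-9), 1 - 1e-9))
      make_step_profile(grid, c(a, 0.5, 1 - a),
                        c(1 + par["c1"], 1 + par["c2"],
                          1 - par["c2"], 1 - par["c1"]))
    },
    fermi = make_fermi(grid, par["Ttilde"]))
}

#' Bifurcation scan over the entropy parameter
#'
#' For each t in the configuration: optimize the trait distribution
#' (Metropolis annealing plus quench), project the result onto the
#' parametric step/Fermi families for reporting, compute the functionals,
#' and count orientation classes (on the projected profile when the
#' projection residual is small, which removes mollified-corner
#' artifacts). Deterministic for a fixed configuration.
#'
#' @param config a [run_config()].
#' @return an object of class `scan_result`: a list with `records` (one
#'   per t, each holding `t`, `dist`, `values`, `polish`, `class_count`,
#'   `theta_atoms`, `converged`) and `summary` (a data frame). When
#'   `config$out_dir` is set, distributions are written as TSV and the
#'   summary as `scan.json`.
#' @export
run_scan <- function(config) {
  if (!inherits(config, "run_config")) stop("expected a 'run_config'")
  grid <- trait_grid(config$M)
  records <- vector("list", length(config$t_values))
  for (i in seq_along(config$t_values)) {
    t <- config$t_values[i]
    cfg <- config$metropolis
    cfg$seed <- config$seed + 1000L * i
    rec <- tryCatch({
      res <- optimize_distribution(
        fitness_spec(t, config$diversity_measure), grid, cfg)
      choice <- best_family_fit(res$dist)
      class_dist <- res$dist
      polish <- NULL
      if (!is.null(choice)) {
        polish <- c(list(label = choice$label), choice$fit)
        class_dist <- family_profile(grid, choice)
      }
      cl <- detect_classes(class_dist)
      list(t = t, dist = res$dist, values = res$values, polish = polish,
           class_count = cl$class_count,
           theta_atoms = data.frame(theta = cl$levels, weight = cl$weights),
           converged = res$converged)
    }, error = function(e) {
      list(t = t, dist = NULL, values = NULL, polish = NULL,
           class_count = NA_integer_, theta_atoms = NULL, converged = FALSE)
    })
    records[[i]] <- rec
  }
  ord <- order(vapply(records, function(r) r$t, numeric(1)))
  records <- records[ord]
  summary <- data.frame(
    t = vapply(records, function(r) r$t, numeric(1)),
    f = vapply(records, function(r)
      if (is.null(r$values)) NA_real_ else r$values$f, numeric(1)),
    n = vapply(records, function(r)
      if (is.null(r$values)) NA_real_ else r$values$n, numeric(1)),
    s = vapply(records, function(r)
      if (is.null(r$values)) NA_real_ else r$values$s, numeric(1)),
    class_count = vapply(records, function(r)
      as.integer(r$class_count), integer(1)),
    converged = vapply(records, function(r) r$converged, logical(1)))
  out <- structure(list(records = records, summary = summary,
                        config = config), class = "scan_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in records) {
      if (!is.null(r$dist))
        write_trait_dist(r$dist, file.path(
          config$out_dir, sprintf("dist_t%s.tsv", format(r$t))))
    }
    master <- lapply(records, function(r) list(
      t = r$t, f = if (is.null(r$values)) NULL else r$values$f,
      n = if (is.null(r$values)) NULL else r$values$n,
      s = if (is.null(r$values)) NULL else r$values$s,
      class_count = r$class_count,
      theta = if (is.null(r$theta_atoms)) NULL else r$theta_atoms$theta,
      weight = if (is.null(r$theta_atoms)) NULL else r$theta_atoms$weight,
      converged = r$converged))
    jsonlite::write_json(master, file.path(config$out_dir, "scan.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Generate synthetic fixtures
#'
#' `"binned_survey"` draws a multinomial sample of `n_respondents` from
#' the binned closed-form orientation continuum P(theta) = 2 Ttilde /
#' theta (optionally with multiplicative noise on the proportions) — a
#' synthetic stand-in for published seven-category orientation tables.
#' `"distribution"` writes an exact family profile. Files are plain TSV.
#'
#' @param kind `"binned_survey"` or `"distribution"`.
#' @param params for `"binned_survey"`: `Ttilde` (or `t`), `n_respondents`
#'   (default 1e5), `noise` (multiplicative sd, default 0), `edges`
#'   (default 7 equal bins). For `"distribution"`: `profile` (one of
#'   "uniform", "two_step", "fermi"), plus `c` or `Ttilde`, and `M`
#'   (default 100).
#' @param seed RNG seed.
#' @param path output file path, or `NULL` to return the object without
#'   writing.
#' @return the generated `binned_orientation` or `trait_dist`
#'   (invisibly if written to `path`).
#' @export
generate_fixture <- function(kind = c("binned_survey", "distribution"),
                             params = list(), seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "binned_survey") {
    Ttilde <- params$Ttilde
    if (is.null(Ttilde) && !is.null(params$t))
      Ttilde <- fermi_limit(params$t)$Ttilde
    if (is.null(Ttilde)) stop("params must supply 'Ttilde' or 't'")
    if (Ttilde <= 0) stop("invalid 'Ttilde'")
    n_resp <- if (is.null(params$n_respondents)) 1e5 else params$n_respondents
    noise <- if (is.null(params$noise)) 0 else params$noise
    edges <- if (is.null(params$edges)) seq(0, 1, length.out = 8) else
      params$edges
    b <- bin_orientation(analytic_p_theta(Ttilde), edges)
    pr <- b$proportion
    if (noise > 0) pr <- pr * exp(stats::rnorm(length(pr), 0, noise))
    pr <- pr / sum(pr)
    counts <- as.numeric(rmultinom(1, size = n_resp, prob = pr))
    b$proportion <- counts / sum(counts)
    if (!is.null(path)) {
      write_binned_orientation(b, path)
      return(invisible(b))
    }
    return(b)
  }
  M <- if (is.null(params$M)) 100 else params$M
  grid <- trait_grid(M)
  profile <- if (is.null(params$profile)) "two_step" else params$profile
  dist <- switch(profile,
    uniform = make_uniform(grid),
    two_step = {
      c0 <- if (is.null(params$c)) 0.5 else params$c
      make_step_profile(grid, 0.5, c(1 + c0, 1 - c0))
    },
    fermi = {
      Tt <- if (is.null(params$Ttilde)) 0.1 else params$Ttilde
      make_fermi(grid, Tt)
    },
    stop("unknown profile kind"))
  if (!is.null(path)) {
    write_trait_dist(dist, path)
    return(invisible(dist))
  }
  dist
}
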