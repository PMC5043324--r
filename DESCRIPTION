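Package: traitcontinuum
Title: Trait Dimorphism and the Sexual-Orientation Continuum Under a
    Diversity-Reproduction Trade-Off
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a single-trait population model in which a fitness
    functional trades off the rate of opposite-sex pairing against the
    diversity of the trait distribution. Provides midpoint-rule quadrature
    of the pairing functional, Shannon-entropy and variance diversity
    measures, Metropolis simulated-annealing optimization of discretized
    trait densities with a deterministic mollified quench, closed-form and
    family-restricted analysis of the symmetry-breaking transition cascade,
    the Fermi-function limiting profile at small entropy parameter, the
    induced sexual-orientation distribution P(theta) and its 1/theta
    continuum form, an agent-based pairing simulator used as an independent
    oracle, and fitting of the continuum width parameter to binned
    (Kinsey-style) orientation proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
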