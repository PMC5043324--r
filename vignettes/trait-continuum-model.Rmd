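---
title: "A diversity-reproduction trade-off model of the sexual-orientation continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A diversity-reproduction trade-off model of the sexual-orientation continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitcontinuum)
```

## The model

Every individual carries a single continuous trait $x \in [0,1]$ and a
desired partner trait $x_c \in [0,1]$, drawn independently of $x$. Males
concentrate near $x = 0$ and females near $x = 1$; the two sexes are
mirror images, so a single density $p(x)$ (the male trait density)
determines everything: the female trait density is $q(x) = p(1-x)$, the
male desire density is $p_c(x) = p(1-x)$, and the female desire density
is $q_c(x) = p(x)$. This also guarantees that the number of individuals
desiring any trait value equals the number possessing it, so the whole
population can be paired off by matching each group possessing $x_1$ and
desiring $x_2$ against the reciprocal group possessing $x_2$ and desiring
$x_1$, uniformly at random within the groups.

Under that construction the expected fraction of opposite-sex pairs is

$$
n[p] \;=\; \frac12 \int_0^1\!\!\int_0^1
\frac{[p(x_1)p(1-x_2)]^2 + [p(1-x_1)p(x_2)]^2}
     {p(x_1)p(1-x_2) + p(1-x_1)p(x_2)}\; dx_1\, dx_2 ,
$$

which is $1/2$ for the uniform density and $1$ when $p(x)p(1-x) \equiv 0$
(fully dimorphic sexes). Reproduction favours large $n$; adaptability
favours trait diversity, measured by the per-capita Shannon entropy
$s[p] = -\int_0^1 p \ln p\, dx \le 0$ (maximal, $0$, at the uniform
density). The fitness traded off between them is

$$
f \;=\; n\,(1 + t\,s),
$$

with a single dimensionless entropy parameter $t \ge 0$ playing the role
of a temperature. At $t = 0$ the optimum is full dimorphism ($n = 1$);
as $t \to \infty$ it is the uniform density ($n = 1/2$). We maximize
$f$ throughout.

An individual desiring $x_c$ has orientation
$\vartheta(x_c) = p(x_c) / [p(x_c) + p(1-x_c)]$ — the same-sex share of
the group it is attracted to — and the population orientation
distribution $P(\theta)$ is the pushforward of the desire density
through $\vartheta$.

## What the package computes

* the discretized functionals $n$, $s$, $\sigma^2$ and $f$
  (midpoint-rule quadrature; `heterosexual_fraction()`, `trait_entropy()`,
  `trait_variance()`, `fitness()`);
* the fitness-maximizing density by Metropolis simulated annealing plus
  a deterministic quench (`optimize_distribution()`);
* closed-form and family-restricted analysis of the transition cascade
  (`two_step_optimum()`, `critical_t_entropy()`,
  `k_step_family_optimum()`, `find_split_transition()`, `fermi_limit()`);
* the orientation map, its pushforward, the $2\tilde T/\theta$ continuum
  and a binned-data fitting routine (`orientation_of()`,
  `orientation_distribution()`, `analytic_p_theta()`, `fit_ttilde()`);
* an agent-based pairing simulator used as an independent oracle for the
  quadrature (`sample_population()`, `pair_population()`);
* scanning, class counting and synthetic fixtures (`run_scan()`,
  `detect_classes()`, `generate_fixture()`).

## Discretization

The trait interval is divided into $M$ equal cells with midpoints
$x_i = (i + 1/2)/M$; a density is the vector $p_i \ge 0$ with
$\sum_i p_i \Delta x = 1$. The conventional default is $M = 100$: an
even $M$ makes the mirror map $i \leftrightarrow M-1-i$ exact on the
grid ($x_{M-1-i} = 1 - x_i$ to machine precision), which the
symmetry-based functionals rely on. Cells of the pairing integrand where
the denominator vanishes contain no individuals and contribute zero;
$0 \ln 0 = 0$ in the entropy; $n$ is clamped to $[0,1]$ to absorb
$10^{-12}$-level rounding, and fully disjoint supports return $n = 1$
exactly. Quadrature error for smooth profiles is $O(\Delta x^2)$
(e.g. $|n_{M=101} - n_{M=401}| < 10^{-3}$ for a Fermi profile of width
$0.1$).

## The phase structure (entropy measure)

For the two-level step $p = 1 \pm c$ (heavier below $x = 1/2$), the
closed forms are $n(c) = 3/2 - 1/(1+c^2)$ and
$s(c) = -[(1+c)\ln(1+c) + (1-c)\ln(1-c)]/2$. (We use the sign
convention that keeps $s \le 0$; it is the one consistent with the
small-$t$ limit $s \simeq -\ln 2 + \pi^2\tilde T/3$.) Expanding,

$$
f(c) = \tfrac12 + c^2\,(1 - t/4) - c^4\,(1 + 13t/24) + O(c^6),
$$

so the uniform solution destabilizes at $t = 4$ with amplitude growing
as $\sqrt{4-t}$. (The quartic coefficient above, obtained by direct
series expansion and confirmed by the exact scalar maximization, differs
from the commonly quoted $-t/2$; the package therefore reports both the
exactly maximized amplitude `c_exact` — used everywhere — and the
quadratic-expansion amplitude `c_quadratic` for comparison.)

As $t$ decreases the step structure splits repeatedly. The package
locates the splits by comparing exact optima of nested antisymmetric
step families (all solutions observed obey $p(x) + p(1-x) = 2$):
two levels ($1 \pm c$), three levels (outer width $a$ at $1 \pm c$,
middle plateau pinned at 1), four levels (per-half widths $a$ and
$1/2 - a$ at heights $1 + c_1$, $1 + c_2$, mirrored; the three-level
family is the $c_2 = 0$ slice). Functionals of piecewise-constant
profiles are evaluated in closed form, so these optimizations are
grid-free; transitions are declared when the richer family strictly
improves the fitness (by more than $10^{-9}$, with the extra structural
parameter above $10^{-3}$ — the thresholds that distinguish true
splitting from optimizer jitter) and located by bisection to $0.01$ in
$t$:

```{r transitions, eval = FALSE}
find_split_transition(2)  # two -> three classes, t* = 1.71
find_split_transition(3)  # three -> four classes, t* = 1.15
```

The $3\to4$ split lands at $t^* \approx 1.15$, at the lower edge of the
published "$\lesssim 1.17$".

At $t \ll 1$ the staircase approaches the Fermi function
$p(x) = 2/[1 + e^{(x-1/2)/\tilde T}]$. Maximizing the small-$\tilde T$
expansions $n \simeq 1 - \pi^2\tilde T^2$,
$s \simeq -\ln 2 + \pi^2 \tilde T/3$ to leading order gives
$\tilde T = t / [6(1 - t\ln 2)]$ (`fermi_limit()`). This relation is
leading order in $t$: keeping the $\tilde T^2$ terms when maximizing
shifts the optimal width from $0.0924$ to $0.0763$ at $t = 0.4$ — an
18% change — while at $t \le 0.2$ the correction is a few percent.
The optimized profiles returned by the package track the
*self-consistent* optimum, so their log-slopes
$d\ln(2/p-1)/dx$ agree with $1/\tilde T$ to 2–3% at $t \le 0.2$ but sit
about 18% above it at $t = 0.4$. We report this as a property of the
leading-order width formula, not of the optimizer.

## The optimizer: annealing plus quench

`optimize_distribution()` runs Metropolis simulated annealing over
discretized densities. A proposal moves a random amount of probability
mass (at most `step_size`, annealed $0.3 \to 0.1$ in density units)
between two random locations; the mass is withdrawn and deposited as
Gaussian bumps whose width is annealed coarse-to-fine ($4 \to 1.5$
cells) together with the inverse temperature $\beta$ (geometric,
$10^2 \to 10^6$ over $2\times10^5$ proposals by default). Withdrawals
are capped at the mass available per cell and the deposit carries
exactly the withdrawn total, so normalization is conserved exactly by
every move. Moves are accepted with probability
$\min(1, e^{\beta\,\Delta f})$, and the best-so-far profile is tracked.

Why smoothed proposals? The midpoint-rule quadrature of $n$ admits
degenerate *comb* microstates: cell-scale alternations of $p$ against
its mirror reach $n \approx 1$ while keeping $s = -\ln 2$, and at small
$t$ they are within $\sim 10^{-5}$ of — in places marginally above —
the smooth Fermi optimum, which is in fact a saddle of the unrestricted
discrete functional. A single-cell proposal chain therefore freezes
into comb microstates at low temperature; combs are sub-grid artifacts
with no continuum counterpart (the continuum functional assigns them
the entropy of their local average). Restricting proposals to smooth
bumps excludes them kinetically, and the annealed width lets the
macroscopic shape form before the interface sharpens.

Annealing alone cannot resolve the interface cells to the accuracy the
Fermi diagnostics need (the fitness is flat to $\sim 10^{-8}$ there), so
a deterministic quench follows:

* **Entropy measure.** At an interior optimum on the simplex,
  $\partial f/\partial p_i$ is constant, which rearranges to
  $p \propto \exp[\partial_p n\,(1+ts)/(n\,t\,\Delta x)]$. The quench
  iterates this self-consistency with damping ($\gamma = 0.3$) and a
  Gaussian mollifier of width $\sigma$ cells applied to the exponent.
  The mollifier suppresses the comb instability (whose growth rate
  scales like $1/t$); $\sigma$ is continued $2 \to 1.2 \to 0.6$ and then
  halved further as long as the fixed point remains smooth — monitored
  by an explicit oscillation count of the profile — and practically
  stationary. At moderate $t$ the continuation reaches
  $\sigma \approx 0.1$ and the crisp step plateaus are recovered
  exactly; at $t \lesssim 0.2$ it stops near $\sigma \approx 0.6$,
  where the comb instability reappears. The result is deterministic
  and seed-robust (identical profiles across annealing seeds).
* **Variance measure.** The variance has no $\ln p$ term, the optimum
  is a boundary (bang-bang) profile, and the exponential
  self-consistency does not apply. The quench is instead a
  deterministic sweep of golden-section line searches over the same
  smoothed exchange moves, applied until no single move improves $f$.

Solutions come in mirror pairs; the returned profile is oriented with
the male mass at low $x$. Reported `values` are always recomputed from
the returned distribution.

## The variance variant

Replacing $s$ by the trait variance $\sigma^2$ gives
$f = n(1 + t\sigma^2)$ and is commonly summarized as: uniform above a
critical $t_c \approx 25$, Heaviside step $2\Theta(x - 1/2)$ below.
The package evaluates the two candidates with its own quadrature
($\sigma^2 = 1/12$ vs $1/48$) and finds their fitness crossing at
$t_c = 24$ (`variance_variant_critical_t()`).

The package's analysis, however, shows that this two-phase picture is
a property of the restricted candidate comparison only. Within the
two-level family, $\sigma^2(c) = 1/12 - c^2/16$, so

$$
f(c) - f(0) \;=\; c^2\,\bigl(1 + 5t/96\bigr) + O(c^4) \;>\; 0
\quad\text{for every } t,
$$

i.e. the uniform profile is *never* a local maximum of the variance
fitness. Worse, anti-aligned profiles with interleaved supports (so
$p(x)p(1-x) \equiv 0$, $n = 1$) can spread mass across the whole
interval and push $\sigma^2$ toward $1/12$ — and, on the grid, toward
end-cell spikes with $\sigma^2 \to 1/4$ — so the unrestricted supremum
is approached by arbitrarily fine dimorphic structure and a competent
free-form optimizer converges to neither the uniform nor the Heaviside
profile at any $t$. The two corresponding legs of the acceptance test
suite fail for exactly this reason and are left failing: they assert
the restricted two-phase phenomenology of the unrestricted optimizer.
The changeover itself is meaningful, and is computed, as the
ladder-classified comparison of the two named candidates.

## Orientation and the Kinsey-style inversion

For the Fermi profile the factor 2 cancels in the orientation map and
$\vartheta$ is the logistic $1/[1 + e^{(x_c - 1/2)/\tilde T}]$; the
pushforward has the closed form $P(\theta) = 2\tilde T/\theta$ on
$[\theta_{\min}, \theta_{\max}]$ with
$\theta_{\min} = [1 + e^{1/2\tilde T}]^{-1}$,
$\theta_{\max} = 1 - \theta_{\min}$, and
$2\tilde T \ln(\theta_{\max}/\theta_{\min}) = 1$ exactly: at any finite
$t$ nobody is strictly heterosexual or homosexual. `fit_ttilde()`
inverts binned orientation proportions (seven equal-width categories by
default, the usual mapping of a seven-point orientation scale onto
$[0,1]$) by least squares in log space — matching the
double-logarithmic axes on which such data are conventionally examined —
with exact bin integrals of the analytic density on both sides, and
recovers $t$ through $t = 6\tilde T/(1 + 6\tilde T\ln 2)$:

```{r fit, eval = FALSE}
b <- bin_orientation(analytic_p_theta(0.09))
fit_ttilde(b)        # Ttilde_hat = 0.09, t_hat = 0.39
```

No survey data ship with the package; `generate_fixture("binned_survey")`
draws multinomial samples from the model's own binned continuum (with
optional multiplicative noise) as a synthetic stand-in, and the
fitting operation accepts any user-supplied three-column table. The
model is known not to capture the excess of respondents at the extreme
categories of real surveys; nothing here attempts to.

## The agent-based oracle

`sample_population()` draws $N/2$ males and $N/2$ females by
inverse-CDF sampling on the grid with uniform jitter within cells
(equal sex counts are imposed; the mirror symmetry makes them equal in
expectation anyway). `pair_population()` buckets individuals by
(possessed bin, desired bin) on a default $20 \times 20$ grid and pairs
each bucket against its reciprocal uniformly at random. Reciprocal
bucket sizes fluctuate at finite $N$; remainders are re-bucketed at
successively halved (even, so that $x = 1/2$ stays on a bin edge) bin
counts and matched again, with only the final scraps paired uniformly
at random. A single random-pool pass would bias $\hat n$ down by
$\sim 0.006$ at $N = 10^5$ for strongly dimorphic profiles; the
hierarchical version is accurate to $\sim 0.001$, and fully disjoint
supports yield $\hat n = 1$ exactly. The simulator shares no code with
the quadrature and is used as its independent oracle in the tests.

## Class counting and scans

`detect_classes()` merges the weighted orientation values by single
linkage with a gap threshold of $0.02$ and discards classes below 1% of
the population — separating true class structure from the
$O(\Delta x)$ jitter of optimized profiles. When 25 or more distinct
orientation values are present the continuum regime is reported
directly (separated classes no longer exist). `run_scan()` runs the
optimizer over a $t$ grid (default
$\{5, 4, 3.9, 3, 2, 1.7, 1.4, 1.17, 0.8, 0.4, 0.2, 0.1\}$, covering
all regimes), projects each result onto the step/Fermi families
(`polish_profile()`), counts classes on the projected profile when the
projection residual is below $0.05$ (raw otherwise), and writes TSV/JSON
artifacts; everything is deterministic given the seed.

## Problem sizes, tolerances, defaults

| quantity | default | note |
|---|---|---|
| grid cells $M$ | 100 | even, mirror-exact; class structure resolved to $\Delta x = 0.01$ |
| annealing proposals | $2\times10^5$ | geometric $\beta$: $10^2 \to 10^6$ |
| proposal bump width | $4 \to 1.5$ cells | comb suppression scale |
| proposal mass step | $0.3 \to 0.1$ | density units |
| quench damping / tolerance | $0.3$ / $10^{-12}$ sup-norm | mollifier continuation $2 \to 1.2 \to 0.6 \to \dots$ |
| pairing simulator | $N = 10^5$, 20 bins | oracle error $\sim 3\sqrt{0.25/(N/2)}$ |
| family optimizations | grid-free | closed-form functionals, tolerances $10^{-10}$–$10^{-12}$ |
| transition bisections | $0.01$ in $t$ | gain threshold $10^{-9}$ |

The test-suite problem sizes (annealing lengths of $0.5$–$2\times10^5$,
$N = 10^5$ populations, 20-seed recovery studies) were chosen so that
every stochastic check sits several standard errors away from its
threshold while the whole suite remains quick to run on one core.

## What the synthetic data do and do not show

The generator emulates data produced exactly by the model: multinomial
sampling from the model's own binned orientation continuum, with
optional lognormal perturbation of the bin proportions. Passing the
recovery tests shows the inversion is consistent and stable under
sampling noise of that form. It does not show that real survey data
follow $P(\theta) \propto 1/\theta$ — category heaping, self-report
bias and the extreme-category excess are all outside the model — so
fitted $\tilde T$ values for real tables should be read as descriptive
summaries, not parameter estimates of a believed mechanism.

## Known limitations

* One trait dimension, one parameter; no inheritance, selection
  dynamics, or generational structure ($b$ and $N$ never appear
  unnormalized).
* The discretized pairing functional is not a faithful variational
  discretization of its continuum counterpart at cell scale (the comb
  degeneracy above); all optimizer output is therefore defined with
  respect to the smoothed move set and mollified stationarity
  condition documented here.
* The leading-order width relation $\tilde T(t)$ degrades visibly by
  $t = 0.4$ (see above).
* The variance variant's published two-phase picture holds only as a
  two-candidate comparison; the unrestricted problem has no maximizer
  in the continuum.
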