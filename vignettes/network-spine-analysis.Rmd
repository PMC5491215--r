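---
title: "Spatial analysis of spine patterns on 3D dendritic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial analysis of spine patterns on 3D dendritic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdendro)
```

## The statistical problem

Dendritic spines can only sit on the dendritic shaft, so a spine map is a
*point pattern on a linear network*: a set of events constrained to a union of
line segments embedded in 3D. Classical spatial statistics with Euclidean
distances is misleading here — events concentrated on a thin, curved, branched
domain look "clustered" at short range and "regular" at long range purely
because of the geometry of the domain. netdendro therefore works exclusively
with the shortest-path (geodesic) distance $d_L(u, v)$ along the network, and
every estimator in the package reduces to arc-length arithmetic, which is why
the same code handles planar networks as the special case $z$ = constant.

Networks are restricted to **trees**. Dendritic arborisations are acyclic, and
the restriction buys exactness: on a tree the path between two locations is
unique, the distance-to-root covariate is linear along every segment, and the
circumradius is half the continuum diameter. Cyclic or disconnected inputs are
rejected at construction rather than half-supported (on a disconnected network
some distances would be infinite).

## Summary functions

Three cumulative second-order summaries are provided, all exact step functions
evaluated at the requested grid distances:

* `k_net()`: the network analogue of Ripley's K,
  $\hat K_{net}(d) = \frac{|L|}{n(n-1)}\sum_i\sum_{j\neq i} 1\{d_L(x_i,x_j)\le d\}$.
  Its value depends on the geometry of the network, so it cannot be compared
  across dendrites.
* `k_corrected()`: the geometrically corrected version, in which every ordered
  pair is down-weighted by $m(x_i, d_L(x_i,x_j))$, the number of network
  points at *exactly* that distance from $x_i$. Under a homogeneous Poisson
  process $K_L(d) = d$ for $d$ up to the circumradius $R$, independent of the
  network, which is what makes corrected curves from different dendrites
  comparable.
* `k_inhom()`: the inhomogeneous extension, with each pair additionally
  weighted by $1/(\hat\lambda(x_i)\hat\lambda(x_j))$.

The exact-distance count $m(u,t)$ is computed combinatorially, not by
discretization. From a location $u$ on a tree, the distance function is
monotone along every edge (splitting the edge containing $u$ into two
half-edges), so $m(u,t)$ is the number of edges whose open distance interval
contains $t$, plus the number of vertices at exactly distance $t$. A vertex at
distance $t$ counts **once**, as set cardinality, regardless of its degree;
this matters only on a measure-zero set of distances but keeps the definition
literal. Ties between inter-event distances are summed, never jittered.
Floating-point equality at vertices uses a relative tolerance of $10^{-8}$ —
within that tolerance of a vertex the point is attributed to the vertex, not
to its incident edges, so the count stays a set cardinality.

The default evaluation grid is 512 equispaced distances on $[0, 0.98R]$. The
2% pull-back from the circumradius mirrors the convention used when several
networks are compared over a common interval; single-network analyses may pass
any grid up to $R$.

## Intensity modelling

The intensity covariate is the distance to the tree root (the soma
attachment). Two complementary tools:

* `rho_of_covariate()` estimates $\rho$ in $\lambda(u) = \rho(d(u))$ as a
  ratio of a Gaussian kernel sum over event covariate values to the
  kernel-smoothed length density of the covariate,
  $\hat\rho(z) = \sum_i \kappa_h(z - z_i) / \int_L \kappa_h(z - d(u))\,du$.
  The denominator is integrated per segment by the trapezoidal rule at node
  spacing $\min(0.5\,\mu m, h/10)$, which keeps the quadrature error well
  below $10^{-3}$ relative for any usable bandwidth. The default bandwidth is
  the normal-reference (Scott) rule on the event covariate values; no
  published value exists for this choice, and the estimate is used
  descriptively, so a standard rule-of-thumb is appropriate. Because the
  numerator and denominator lose kernel mass identically at the domain ends,
  the ratio is boundary-unbiased for flat intensities.
* `cdf_test()` is the Kolmogorov–Smirnov covariate test: it compares the
  empirical distribution of the covariate at the events with the *exact* null
  CDF $F_0(z) = |\{u \in L: d(u) \le z\}| / |L|$, assembled in closed form
  from the per-segment covariate ranges (distance-to-root is linear along
  each segment of a tree). The p-value uses the asymptotic one-sample KS
  distribution; spine counts per dendrite are in the hundreds to thousands,
  where the asymptotic approximation is excellent, so no Monte Carlo option
  is provided.

`fit_log_quadratic()` fits $\lambda(u) = \exp(\theta_0 + \theta_1 d(u) +
\theta_2 d(u)^2)$ by direct maximisation of the Poisson process likelihood
$\ell(\theta)=\sum_i \log\lambda(x_i) - \int_L \lambda(u)\,du$, a deliberate
choice over lattice-GLM approximations: the integral is cheap on a tree
(trapezoidal quadrature, node spacing $\le \min(1\,\mu m,\ \text{segment
length}/10)$), and the damped Newton iteration with analytic gradient and
Hessian converges in a handful of steps from the homogeneous start
$(\log(n/|L|), 0, 0)$. The covariate is standardised internally — raw
distances reach hundreds of micrometres, so the raw-scale Hessian is badly
conditioned and an absolute gradient tolerance would be meaningless — and the
$10^{-8}$ gradient-norm stopping rule is applied on the standardised scale.
Coefficients and the observed-information variance matrix are mapped back to
the raw scale. Halving the quadrature step moves fitted coefficients by less
than $10^{-4}$ relative on test fixtures (verified in the suite). The fit
warns below 10 events (a quadratic on a handful of points is weakly
identified) and errors with the full iteration trajectory attached if Newton
fails to converge in 200 iterations.

Simulation of the fitted model uses Lewis–Shedler thinning with the envelope
rate $\lambda_{max}$ computed *exactly*: the covariate is linear on each
segment, so the per-segment maximum of the quadratic is at an endpoint or at
the stationary point $-\theta_1/(2\theta_2)$.

## Monte Carlo inference

`global_envelope_test()` implements the constant-width global envelope: with
`n_sim` simulations of the null model, $w_{max}$ is the largest absolute
deviation of any simulated summary from the Poisson reference $K(d)=d$ over
the whole grid, the band is $d \pm w_{max}$, and the null is rejected when
the empirical curve leaves the band. The default `n_sim = 19` gives exact
level $1/(1+19) = 0.05$ under exchangeability. For the inhomogeneous summary
the log-quadratic intensity is **re-fitted to every simulated pattern** (and
to the observed one); the alternative — reusing the observed fit — ignores
estimation error and makes the band anti-conservative, so refitting is the
default and only behaviour.

`studentized_permutation_test()` compares groups of replicated patterns, each
on its own network, through the studentized statistic
$$H = \sum_{i<j} \int_{d_0}^{d_1} \frac{(\bar T_i(d) - \bar T_j(d))^2}
{\bar s_i^2/m_i + \bar s_j^2/m_j}\, dd,$$
with the within-group variances time-averaged over $[d_0, d_1]$. The observed
$H$ is ranked among `n_perm` random relabellings (group sizes preserved), with
$p = (1 + \#\{H^* \ge H_{obs}\})/(1 + n_{perm})$. The +1 convention is the
standard exact-valid choice; "ranking" alone does not pin down tie handling,
and this version can never report $p = 0$. Degenerate variances follow the
convention $0/0 = 0$ (identical groups contribute nothing) and $x/0 = \infty$
for $x > 0$ (the permutation ranking remains well defined). The default upper
limit $d_1$ is 98% of the smallest circumradius across all networks in the
test; patterns whose circumradius falls below a requested $d_1$ are reported
by name rather than silently truncated, since their corrected K is undefined
there. Summaries are computed directly on a common 256-point grid on
$[d_0, d_1]$ (they are exact step functions, so no interpolation error is
introduced; curves supplied to `h_statistic()` on other grids are
interpolated linearly).

Each group must contain at least two patterns for the variance to exist; with
fewer than three the variance estimate is poor and the test warns.

## The synthetic dendrite generator

No raw reconstructions ship with the package, so `generate_dendrite()` grows
trees by a branching random walk: tips advance in 2 µm polyline steps with
Gaussian direction noise (SD 12°), bifurcate at 0.007/µm outside an initial
20–60 µm unbranched trunk, and growth stops at a target total length drawn
uniformly from 600–2400 µm. These defaults were chosen once to land inside
the published morphology envelope for human temporal-cortex pyramidal
dendrites — total length roughly 330–3250 µm, 2–23 branch points,
circumradius in the 140–330 µm range — and generated trees fall in those
ranges in well over 90% of draws. Binary branching only: reported
morphometrics count branch points, not branching order, so higher-order
branching would add parameters without adding realism the tests could see.

What the generator does **not** emulate: dendrite diameter and taper (the
network has zero volume), spine attachment geometry (events are points on the
axis), systematic apical/basal asymmetries, and any dependence between
branching and spine density. Tests passing on synthetic trees therefore
validate the estimators' mathematics and calibration, not biological claims
about real dendrites.

`generate_replicated_groups()` assembles the permutation-test fixture: `g`
groups of independent trees, each pattern simulated from its group's
log-quadratic model, fully reproducible from one seed.

## Problem sizes used in the test suite

Monte Carlo checks are sized for stable estimates at desk scale: envelope
calibration uses 200 CSR-vs-CSR tests (nominal level 0.05, binomial SE
0.015); the Poisson benchmark $E[\hat K_L(d)] = d$ uses 200 simulations of
100 events; parameter recovery uses 100 fits at roughly 2000 events per
pattern (matching the per-dendrite spine counts of the motivating data);
permutation calibration uses 200 replicates of a two-group, five-per-group
null design at 199 permutations, on smaller trees (250–400 µm, ~150 events)
than the generator default — the test's level does not depend on pattern
size, only on exchangeability, so the smaller fixture buys replicates where
they matter. Geometry is cross-checked against brute-force oracles (a
hand-written Dijkstra on a densified graph, and discretization oracles for
$m(u,t)$ and the circumradius) on dozens of random trees.

## Known limitations

* Trees only; cyclic networks (e.g. vasculature) are out of scope.
* The ratio estimator in `rho_of_covariate()` has no edge-corrected variants,
  and bandwidths are global, not adaptive.
* No variance approximation for $\hat K_L$; inference goes through envelopes
  or permutation.
* Marked patterns (spine volume, length, type) are not supported; SWC has no
  standard slot for per-event marks, and a sidecar format is deliberately
  deferred.
* Events are snapped to the axis by nearest-point projection; if the true
  attachment mapping is known upstream, supply `segment,offset` events
  instead of coordinates.
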