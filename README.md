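# netdendro

Spatial point-pattern analysis on 3D linear networks, built for dendritic
trees with spines as events.

## The problem

Dendritic spines — the main postsynaptic targets of excitatory synapses — can
only sit on the dendritic shaft, so a spine map is a point pattern living on a
branched 1D domain embedded in 3D. Analysing such patterns with ordinary
Euclidean-distance spatial statistics produces spurious short-range
"clustering" (events share a thin shaft) and long-range "regularity"
(branches are separated in space). netdendro works along the network instead:
every statistic is built from the shortest-path distance
`d_L(u, v)` on the tree.

The package is aimed at quantitative neuroanatomists (and anyone else with
events on geodesic trees) who want to ask: is spine density uniform? how does
it vary with distance to the soma? is the pattern Poisson once the intensity
trend is accounted for? and do groups of dendrites — different neurons, or
apical versus basal arbors — share the same spatial organisation?

## What it computes

* **Network geometry** (`build_network`, `read_swc`): rooted continuum trees
  from SWC morphologies or vertex/edge tables; exact shortest-path distances,
  the exact-distance count `m(u, t)`, circumradius `R`, snapping of 3D spine
  coordinates onto the axis.
* **Network K functions** (`k_net`, `k_corrected`, `k_inhom`):

      K_net(d) = |L|/(n(n-1)) * sum_{i != j} 1{d_L(x_i, x_j) <= d}

  plus the geometrically corrected `K_L` in which each ordered pair is
  weighted by `1/m(x_i, d_L(x_i, x_j))` — under a homogeneous Poisson process
  `K_L(d) = d` for `0 <= d <= R` on *any* network, making curves comparable
  across dendrites — and the inhomogeneous `K_LI` with additional
  `1/(lambda(x_i) lambda(x_j))` weights.
* **Intensity analysis** (`rho_of_covariate`, `cdf_test`,
  `fit_log_quadratic`): kernel estimate of intensity versus distance to the
  soma, the Kolmogorov–Smirnov CDF test of covariate dependence with the
  exact length-weighted null CDF, and maximum-likelihood fitting of the
  log-quadratic Poisson intensity
  `lambda(u) = exp(theta0 + theta1 d(u) + theta2 d(u)^2)`.
* **Monte Carlo inference** (`global_envelope_test`,
  `studentized_permutation_test`): constant-width global envelopes (19
  simulations = exact level 0.05) and the studentized permutation test of the
  `H` statistic for replicated grouped patterns on different networks.
* **Simulation** (`simulate_csr`, `simulate_inhom`, `generate_dendrite`,
  `generate_replicated_groups`): CSR and Lewis–Shedler thinning on networks,
  and a calibrated synthetic dendrite generator used throughout the tests.

A command-line interface (`exec/netdendro`) exposes `describe`, `kfun`,
`cdftest`, `envelope`, `permtest` and `simulate` over SWC + CSV inputs.

## Worked example

Generate a synthetic dendrite, put an inhomogeneous spine pattern on it, and
run the full single-pattern analysis:

```r
library(netdendro)

net <- generate_dendrite(seed = 42)
model <- log_quadratic(log(2.5), 0.012, -6e-5)   # rise-then-fall profile
spines <- simulate_inhom(net, model, seed = 43)

describe(net, spines)
#> n = 1615, |L| = 2248.00 um, n/|L| = 0.72 events/um, R = 289.00 um, #BP = 18

cdf_test(spines)
#> CDF (Kolmogorov-Smirnov) test of intensity dependence on the covariate
#>   D = 0.58949, n = 1615, p-value = < 2.2e-16

rho_of_covariate(spines)
#> <rho_estimate: 128 grid points on [0, 466.00] um, bandwidth 22.366 um>
#>   peak rho = 4.6156 events/um at z = 88.06 um

fit <- fit_log_quadratic(spines)
fit
#> Log-quadratic intensity model: lambda(u) = exp(theta0 + theta1 d + theta2 d^2)
#>           estimate         se
#> theta0  9.4862e-01 8.2126e-02
#> theta1  1.2074e-02 9.9237e-04
#> theta2 -6.0128e-05 2.6945e-06
#> log-likelihood -536.970 (1615 events, converged in 9 Newton steps)

global_envelope_test(spines, fit, summary = "KLI", n_sim = 19, seed = 44)
#> Global envelope test (KLI, 19 simulations, level 0.050)
#>   w_max = 21.3991 um; null model not rejected
```

Reading the output: the tree carries 1615 spines at 0.72 spines/µm overall,
but the CDF test rejects uniformity decisively — density rises to a peak of
about 4.6 spines/µm some 88 µm from the soma and falls off beyond it. The
fitted log-quadratic coefficients recover the generating model (true values
0.916, 0.012, −6e−5) within one standard error, and the inhomogeneous
corrected K function stays inside its 19-simulation global envelope, i.e. the
pattern is consistent with an inhomogeneous Poisson process once the radial
intensity trend is modelled.

Group comparisons work on replicated patterns:

```r
gp <- generate_replicated_groups(c(5, 5),
                                 list(model, model),
                                 dendrite_spec(), seed = 1)
studentized_permutation_test(gp, summary = "KL", n_perm = 1000, seed = 2)
```

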