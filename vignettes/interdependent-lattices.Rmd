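---
title: "Evolutionary games on interdependent lattices: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary games on interdependent lattices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`duplexgames` simulates evolutionary social-dilemma games on two periodic
lattices (layers A and B) of equal size L × L that are coupled through
utility, not through strategy flow. Each player holds a pure strategy,
cooperate (C) or defect (D), initialized independently with probability 1/2.
A fraction ρ of sites per layer is *distinguished*: such a site owns an
external link to the coordinate-identical partner site on the other layer.

Payoffs come from the nearest-neighbour game rounds on a player's own layer:

* **Prisoner's dilemma (PD)**: T = b, R = 1, P = S = 0, with 1 < b ≤ 2. The
  temptation b is the only dilemma parameter; S can be overridden for
  sensitivity runs.
* **Snowdrift (SD)**: T = β, R = β − 1/2, S = β − 1, P = 0, parameterized by
  the cost-to-benefit ratio r = 1/(2β − 1), 0 < r ≤ 1.

The fitness-relevant quantity is the utility

U_x = π_x + α · π_x′  (distinguished),  U_x = π_x  (ordinary),

where π_x is the accumulated nearest-neighbour payoff, x′ is the partner site
on the other layer, and α ∈ [0, 1] is the coupling strength. Strategies never
cross between layers: the only inter-layer interaction is through π_x′ in the
utility of distinguished players.

### Update rules

One *elementary step* draws a focal player uniformly from the union of both
layers (the `pooled` interleave) and applies one of three update rules
against its own layer:

* **Fermi** (default): against a uniformly random neighbour y, the focal
  player adopts s_y with probability w_y / (1 + exp((U_x − U_y)/K)). The
  selection noise is K = 0.1 throughout; w_y ∈ (0, 1] is the *teaching
  activity* of the role model — its ability to pass on a strategy — and can
  differ between distinguished (`w_dist`) and ordinary (`w_ord`) players.
* **Best-takes-over**: the focal player adopts the strategy of the
  highest-utility member of its closed neighbourhood; exact utility ties are
  broken uniformly at random among the maximizers.
* **Proportional imitation**: against a random neighbour y, adopt with
  probability max(0, U_y − U_x)/Φ, never imitating a weaker player. The
  normalization Φ = (1 + α) · degree · (max payoff − min payoff) is the
  largest admissible utility difference, which keeps the probability in
  [0, 1] for every state; it is exposed as the `phi` config key.

A *full Monte Carlo step* (MCS) is 2L² elementary steps, so each player on
both layers is selected once on average. Observables are recorded once per
MCS. When both layers are homogeneous the dynamics cannot change any more;
the run is flagged absorbed and stepping stops (a single homogeneous layer is
already individually absorbing because strategies cannot re-invade from the
other layer, but both-homogeneous is the conservative global stop).

### Topologies and link modes

Lattices are periodic and regular: the square lattice with the 4-neighbour
von Neumann neighbourhood (zero clustering), and the triangular lattice
realized as the square lattice plus one consistent diagonal pair,
(+1, +1) and (−1, −1), giving degree 6 and a local clustering coefficient of
2/5 at every site. Sites are indexed row-major with modular wrap; for L = 2
the wrap duplicates neighbour slots, which is deliberate (4 interaction
channels per round).

The distinguished sets are drawn as exact counts, round(ρL²) sites without
replacement, which removes the run-to-run variance a per-site Bernoulli draw
would add. Three link modes are supported: `bilateral_paired` (default, the
same coordinates distinguished on both layers), `bilateral_independent`
(independent draws per layer, so partners are typically ordinary), and
`unilateral_A` (only layer A collects extra utility). The paired/independent
distinction matters little for the cooperation level — what matters is that
*both* layers contain distinguished players — whereas unilateral coupling
fails to shift the extinction threshold, which is exactly the contrast the
`coupling` variant set probes.

## Random-number design

All randomness derives from one master seed. Named streams (link selection,
initial strategies per layer, the update sequence per layer and segment, the
layer picker, sweep cells, bootstrap) are derived by hashing the master seed
with a text tag (splitmix64). The compiled engine carries one xoshiro256++
stream per layer plus a layer-picker stream, so runs are bit-reproducible
across platforms and independent of R's global RNG state.

The per-layer streams also give the α = 0 limit an exact meaning: under the
`alternating` interleave (layers visited round-robin) a duplex run with
α = 0 is *bit-identical*, site for site and MCS for MCS, to two isolated
single-lattice runs that use the same layer ids. Under the default `pooled`
interleave the number of elementary steps a layer receives per MCS is
binomial rather than fixed, so the equivalence there is distributional, not
bitwise; the exactness test uses the alternating mode. Statistically the two
interleaves are indistinguishable.

Sweep cells are seeded as hash(master seed, ρ, α, b, variant, replicate), so
grid results are independent of evaluation order and individual cells can be
reproduced in isolation.

## Observables

`measure()` counts, exactly, the fraction of cooperators overall (f_C), among
distinguished players (f_C^int) and among ordinary players (f_C^no), per
layer and pooled. The identity
f_C = [n_int · f_C^int + n_no · f_C^no]/(n_int + n_no) holds at every record
by construction and is asserted in the tests. Empty classes (ρ = 0 or ρ = 1)
are reported as `NA`.

Stationary values are time averages over the final sampling window
(`mcs_sample` records). The critical temptation b_c where cooperators die out
is estimated by bisection: cooperators "survive" at b when the mean
stationary f_C exceeds ε = 10⁻³ in at least half of the replicate runs. On a
finite lattice extinction is absorbing, so any ε below the single-site
resolution 1/L² identifies the same event; ε and the replicate count are
config keys.

## Problem sizes and numerical choices

The package's presets run at desk scale: L = 60 for ρ–α sweeps, L = 50 for
b-scans, 4000–5000 relaxation MCS, 1000 sampling MCS, 3 replicates per cell,
roughly 2–3 s per run with the compiled engine. These sizes resolve all the
qualitative structure of the full-scale study (which uses L = 200–800 and up
to 30 runs); they are not meant to deliver publication-grade error bars.
Finite-size effects to be aware of at this scale:

* close to an extinction threshold, single replicates can absorb to all-D
  where the infinite system would retain a small cooperator density, which
  widens replicate spread;
* the teaching-activity factor w multiplies every adoption probability, so
  w = 0.05 stretches the relaxation clock by roughly 1/w; runs with
  depreciated classes therefore relax for 20000 MCS;
* with w_dist = 0.05 the coupled system retains a small genuine α-gain near
  its own extinction threshold (b ≈ 1.08 at L = 50, stable under 40000-MCS
  relaxation), while the gain is clearly reversed at b ≤ 1.05; the
  "interdependence gain is eliminated" statement holds for the aggregate
  over the mixed phase, and is tested that way.

Other numerical choices: the Fermi exponent is clamped at ±700 before
exponentiation (probabilities saturate instead of overflowing); best-takes-
over ties are resolved by reservoir sampling, uniform over all maximizers;
utilities within one elementary step are evaluated synchronously against the
same instantaneous configuration.

## The RSA bound on useful link densities

Cooperation collapses at high temptation when distinguished players are too
sparse to percolate their influence, no matter how large α is. The relevant
density scale is the jamming coverage of random sequential adsorption on the
square lattice when nearest and next-nearest neighbours are excluded: ρ_c ≈
0.1869. `rsa_fill()` implements the process exactly — each deposited particle
blocks its 3 × 3 footprint, sampling stays uniform over the unblocked sites
via a swap-removal list, and deposition stops at jamming. Note that the
*maximum* admissible packing is 1/4 (one particle per 2 × 2 block), which
small even lattices occasionally approach; 0.1869 is the large-L mean of the
random process, reproduced to ±0.003 by 20 runs at L = 200.

## What the simulations show — and what they do not

The test suite and `scripts/acceptance.R` verify, at desk scale: the interior
optimum of f_C in ρ (argmax adjacent to 0.5 at b = 1.05, α = 0.8, clearing
both grid endpoints by more than twice the pooled standard error); the class
ordering f_C^int > f_C > f_C^no; the teaching-activity reversal; the
bilateral > unilateral ≥ isolated ordering with an unshifted unilateral
extinction threshold; the RSA jamming coverage; and exact invariants
(decomposition identity, α = 0 decoupling, absorbing homogeneous states,
Fermi symmetry, and χ² agreement of single elementary steps with exhaustive
enumeration on a 3 × 3 duplex).

These are statements about the model, not about any empirical social system:
the lattices are regular, strategies are pure, the partner map is the
coordinate identity, and ρ, α are constant in time. Heavy-tailed degree
distributions, strategy mutation, payoff-averaged utilities, more than two
layers, and coevolving links are all outside the package's scope.

## A worked example

```{r, eval = FALSE}
library(duplexgames)

cfg <- sim_config(L = 60, b = 1.05, rho = 0.3, alpha = 0.8,
                  mcs_relax = 4000, mcs_sample = 1000, seed = 1)
res <- run_duplex(cfg)
res$summary

opt <- find_optimal_rho(
  sim_config(L = 60, b = 1.05, alpha = 0.8,
             mcs_relax = 4000, mcs_sample = 1000, seed = 1),
  rho_grid = seq(0.1, 0.9, by = 0.1), replicates = 3
)
opt$rho_opt
opt$certificate
```

The same scans are available from the shell through the installed script,
e.g. `duplexgames sweep --preset fig1 --seed 1 --out results/`.
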