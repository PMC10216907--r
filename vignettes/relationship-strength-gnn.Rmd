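---
title: "Ranking spreading influence with a relationship-strength GNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking spreading influence with a relationship-strength GNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsgnn)
```

## The problem

Given an undirected contact network, which nodes would seed the largest
outbreaks? The ground truth used throughout this package is the
susceptible–infected–recovered (SIR) process itself: node `u`'s influence is
the expected fraction of the network that ends up recovered when an epidemic
starts at `u` alone. Computing that label by Monte Carlo for every node is
expensive, so the package trains a small graph neural network to regress the
label from cheap structural features, on synthetic networks where labels can
be simulated freely, and then transfers the trained model to new networks.

## The model

**Features.** Two indicators describe a node: its degree `k(u)` and the mean
degree of its neighbours `kbar(u)`. They are fused by the entropy weight
method: each indicator is min-max normalised over nodes, converted to
probability shares, and scored by its Shannon entropy on the `log n` scale;
the weight of an indicator is proportional to `1 - H`, so the indicator that
varies more across nodes (lower entropy) gets more weight:

\[
\omega_1 = \frac{1 - H_k}{2 - H_k - H_{\bar k}},\qquad
\omega_2 = \frac{1 - H_{\bar k}}{2 - H_k - H_{\bar k}},\qquad
B(u) = \omega_1 k(u) + \omega_2 \bar k(u).
\]

The model input for `u` is the 24-vector `[B(u), B(u_1), ..., B(u_23)]` over
`u`'s neighbours sorted by degree (descending; ties by internal index),
zero-padded or truncated to 23 neighbours. `B` uses *raw* degrees: the
min-max step exists only to make the two entropies comparable, and the
network input is batch-normalised anyway, so normalising twice would only
discard scale information.

**Propagation operator.** Message passing is weighted by *relationship
strength*, the degree of neighbourhood overlap:

\[
R = (A + I)^2 \quad\Longleftrightarrow\quad
R_{ij} = \begin{cases} k(i) + 1 & i = j\\ C_{ij} + 2 & (i,j) \in E\\
C_{ij} & \text{otherwise,}\end{cases}
\]

with `C_ij` the number of common neighbours. Adjacent pairs get a +2 boost
so first-order neighbours are never dropped, and non-adjacent 2-hop pairs
with shared neighbours also exchange messages. With row sums
`S_i = sum_j R_ij` and `D = diag(S)`, the propagation operator is the
symmetric normalisation `L = D^{-1/2} R D^{-1/2}`. `R` is integer-valued and
stored sparse (its fill is the closed 2-hop neighbourhood; a dense `n^2`
matrix is deliberately never materialised).

**Network.** Input batch norm over the 24 columns, then two message-passing
layers

\[
e^{(l)} = \mathrm{BatchNorm}\!\left(e^{(l-1)} W_1 + L\, e^{(l-1)} W_2\right),
\]

then a fully connected map to one score per node. The layer update uses
batch normalisation *only* — no activation function — matching the update
rule literally; a ReLU is available behind `relu = TRUE` but is off by
default. Loss is MSE against SIR labels; the optimiser is NAdam at learning
rate 0.001, one full-graph step per training network per epoch.

## SIR labels

The simulator is discrete-time with recovery probability fixed at 1: at each
synchronous generation every infected node tries each susceptible neighbour
independently with probability `beta`, then recovers. A node is therefore
infectious for exactly one generation, which makes the final recovered set
equal in distribution to the bond-percolation cluster of the seed — the fact
exploited by `enumerate_sir_expectation()`, the exact oracle used in the
tests. Labels are `t(u) = mean(N_r)/N` over `Sn = 500` independent runs.

`beta` defaults to the epidemic threshold `beta_th = <k>/<k^2>`, rounded to
two decimals (half away from zero) and floored at 0.01; evaluation sweeps
multiples 1.0–2.0 of it. Training labels use ratio 1.0 of the training
network's own threshold; this is a package choice (the choice of training
`beta` is otherwise open) exposed via `beta_ratio`.

Randomness: every node's label uses an RNG substream derived from
`(master seed, node index)` by a Lehmer-style integer hash, so labels do not
depend on iteration order or parallel scheduling, and any label can be
reproduced in isolation. The epidemic inner loop is compiled (Rcpp) and
draws from R's own RNG stream, so `set.seed()` reproducibility carries
through; labelling a 1000-node graph at 500 runs per node takes about two
seconds on one core.

## Synthetic training data

Training uses two generators, one scale-free and one community-structured:

* `generate_ba(n, m)` — preferential attachment from an `m`-node edgeless
  seed; each new node attaches `m` edges to distinct nodes with probability
  proportional to degree (uniform while all degrees are zero), giving
  exactly `m(n - m)` edges.
* `generate_lfr(...)` — an **LFR-style** benchmark: truncated power-law
  degrees (exponent `tau1`), power-law community sizes (`tau2`), each node
  placing a `1 - mu` fraction of its stubs inside its community,
  configuration-model wiring, self-loops/multi-edges dropped, reduced to the
  largest connected component. This reproduces the features that matter for
  training (heavy-tailed degrees inside communities, tunable mixing) but is
  not the reference LFR implementation: degree sequences are matched in
  expectation, not exactly, and mixing is a target fraction rather than an
  exact per-node constraint. No reference implementation exists in the
  supported R stack, and the generator is training scaffolding, not the
  method itself.

Defaults — BA(1000, 4), LFR(1000, tau1 = 3, tau2 = 1.5, mu = 0.1,
avg_deg = 8, max_deg = 50) — are sizes a typical transfer experiment in this
area uses: large enough for a heavy tail and for stable entropy weights,
small enough to label by Monte Carlo in seconds.

What a green transfer test does *not* establish: synthetic BA/LFR graphs
have no meaningful clustering at these densities, no degree correlations,
and no attribute structure. Transfer to real networks with strong assortativity
or very flat degree distributions (power grids, road networks) is exactly
where degree-based features carry the least signal, and the tests make no
claim there.

## Numerical choices

* **Entropy degenerate cases.** A constant indicator (min = max) gets
  entropy 1, hence weight 0; if both are constant (regular graphs),
  `omega = (0.5, 0.5)`. `0 log 0 = 0`, no epsilon inflation.
* **Neighbour sort order.** Descending degree with ascending-index
  tie-break. The sort direction is not forced by the feature definition;
  descending keeps the best-connected neighbours under the 23-neighbour
  truncation and is fixed here once. A consequence of any deterministic
  tie-break: when two neighbours tie in degree but differ in `B`, their
  positions in the fixed-width row depend on the label ordering, so feature
  rows (and hence scores) are permutation-equivariant only up to the
  ordering of tied neighbours. The tests assert exact equivariance on
  tie-free structures and multiset row equality in general.
* **Batch norm.** Biased variance in normalisation, eps `1e-5`, running
  statistics with momentum 0.1; evaluation uses running statistics.
* **Epochs default 1000.** Raw labels live in `[1/N, 1]` with variance of
  order `1e-6`; the first few hundred NAdam steps are spent collapsing the
  output scale, and at 200 epochs the training MSE is still above the label
  variance (the model has learned the mean, not the ranking). At 1000
  epochs the held-out Kendall tau clearly exceeds degree centrality in the
  transfer test the suite runs; the package treats 1000 as the default and
  exposes it.
* **Label scale.** Labels are z-scored per training network before
  regression. Although the infection ratio is already a fraction, its scale
  is network-specific (it depends on the threshold and the outbreak sizes
  there), and joint training on networks with conflicting raw scales proved
  badly unstable: at some seeds the held-out tau collapsed to near zero
  while degree centrality scored 0.5+. Standardising each network's labels
  removes the conflict without touching anything the rank-based evaluation
  can see; the transfer test in the suite measures the resulting margin
  over degree centrality directly.
* **Ranking ties.** All rankings (model and baselines) break score ties by
  ascending internal index, so output orderings are total and reproducible.
* **Kendall tau.** The default is tau-a — concordant minus discordant over
  all `n(n-1)/2` pairs, tied pairs counting zero in the numerator only —
  because that is the definition used for evaluation in this line of work; a
  tie-adjusted tau-b is available (`variant = "b"`) since SIR labels at
  small `Sn` contain ties. P-values use the normal approximation with
  continuity correction.
* **Seeds.** One master seed fans out to generator/label/training sub-seeds
  through `derive_seed()` (Lehmer hash, exact in doubles, result < 2^31).

## Known limitations

* Undirected, unweighted, static graphs only.
* The regressor is linear in its (batch-normalised) features when
  `relu = FALSE`; it can reweight 1- and 2-hop degree information but cannot
  express non-monotone interactions. That follows the layer definition
  literally and is intentional.
* Training labels at `Sn` well below 500 are noise-dominated near the
  epidemic threshold; the model will overfit that noise (the training MSE
  happily drops below the label noise floor) and transfer degrades. Keep
  `Sn = 500` for labels used in training.
* The LFR-style generator above is not the reference algorithm; exact
  degree-sequence and mixing guarantees are out of scope.
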