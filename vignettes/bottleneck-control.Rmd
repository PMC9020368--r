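---
title: "Modeling behavioral control through an information bottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling behavioral control through an information bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

In most animals, commands selected in the brain reach the motor periphery
through a comparatively tiny population of descending neurons — in the fruit
fly, a few hundred pairs bridge the brain and the ventral nerve cord.  This
package implements an abstraction of that constraint: a repertoire of `N`
behaviors, each requiring a specific subset of `M` binary motor units, must
be relayed through a hidden layer of `R` "descending" units with `R < N, M`.
The questions the package answers are quantitative: how small can the
bottleneck be before the repertoire can no longer be reproduced, how does
that critical size depend on the sparsity and modularity of the
behavior-to-motor mapping, how robust is the trained network to forced
activation or silencing of single hidden units, and how predictable
(state-dependent) are the perturbed outputs.

## The behavioral matrix

The study's only "data" is the behavioral matrix: an `N x M` binary matrix
whose row `i` lists the motor units active during behavior `i`.  Two
ensembles are provided.

* `random_behaviors(N, M, k)` places exactly `k` ones per row, uniformly at
  random without replacement.  `k` is the sparsity; because the code is
  binary, `k` and `M - k` are statistically equivalent and sparsity
  increases as `k` moves away from `M/2`.
* `modular_behaviors(N, M, k, m, sigma)` splits behaviors and motor units
  into `m` contiguous equal blocks.  Each behavior activates `k - sigma`
  units inside its home block and `sigma` outside.  `sigma = 0` is perfect
  modularity; raising `sigma` interpolates toward the random ensemble while
  preserving row sums.  The placement distribution within the allowed
  column sets is uniform — the minimal assumption, since nothing finer is
  specified by the construction.

Two descriptors summarize a matrix.  `newman_modularity()` treats the
matrix as the adjacency of a graph on `max(N, M)` nodes (node `i` is row
`i` and column `i` at once, so block `i`'s behaviors and motor units share
a community) and evaluates Newman's score

$$\mu = \frac{1}{2m}\sum_{ij}\Bigl(A_{ij} - \frac{k_i k_j}{2m}\Bigr)\,
  \delta(c_i, c_j).$$

For `m` equal non-overlapping blocks this is exactly `(m - 1)/m` — `0.8`
for five blocks — and a single all-inclusive community scores exactly `0`.
Because the behavioral matrix is asymmetric, a convention is needed: the
default symmetrizes the adjacency as a weighted graph (`w = A + t(A)`);
`directed = TRUE` evaluates the directed variant instead.  Both give
exactly `(m-1)/m` on perfect block structure; realized scores for noisy
matrices can differ slightly between conventions, which is why the
convention is an explicit argument rather than a buried choice.  The sum is
evaluated in its per-community grouped form, which cancels exactly for the
single-community case instead of leaving float residue.

`behavior_entropy()` gives the log2 count of equiprobable matrices in the
generating ensemble: `N log2 C(M, k)` for the random ensemble and
`N log2 [C(m_size, k - sigma) C(M - m_size, sigma)]` for the modular one,
with `m_size = M/m`.  The binomials enter through `lchoose()`, which is
exact to double precision even at `C(100, 50)`, so no big-integer
arithmetic is needed before taking logs.

## The network and its training

`bottleneck_net()` fits the model: a fully connected
`N -> R -> M` network evaluated on the `N` one-hot commands,

$$a^{(1)} = W^{(1)\top}x - B^{(1)}, \qquad
  a^{(2)} = W^{(2)\top}\rho(a^{(1)}) - B^{(2)},$$

with logistic `rho`.  Training minimizes the mean-squared error against the
target rows by gradient descent with momentum for a fixed number of epochs
(default `1e5`), full-batch by default; `batch_size` enables shuffled
mini-batches, whose noise turns out not to change any conclusion here.
There is no early stopping: the epoch budget is part of the protocol, and
the loss curve has flattened well before it at the default scale.  Outputs
are binarized at `0.5` and a behavior counts as learned only when its whole
binarized row matches the target — per-entry accuracy is never substituted.

Three numerical choices deserve explanation.

* **Output nonlinearity.**  The logistic function is applied to the output
  layer as well (`sigmoid_output = TRUE`, the default).  With a *linear*
  output layer the squared error keeps penalizing confidently correct
  entries (an output of 1.3 for a target 1 binarizes correctly but still
  carries loss), and gradient descent settles on plateaus where a quarter
  of the behaviors stay wrong no matter the learning rate or batch size.
  With a sigmoid output the loss can vanish by saturation, optimization is
  well behaved near the bottleneck, and the critical sizes and robustness
  levels land where the repertoire statistics put them.  The linear-output
  variant is kept behind the flag for comparison.
* **Step size.**  The loss is mean-reduced over all `N x M` entries, so raw
  gradients are small; the default `learning_rate = 1` with
  `momentum = 0.9` makes the loss flatten comfortably within the epoch
  budget at the default scale (`N = M = 100`).  The defaults were chosen on
  convergence behavior — the loss trace, and full learning of
  unbottlenecked instances — at fixed targets.
* **Initialization and ties.**  Weights start uniform in
  `[-1, 1]/sqrt(fan-in)`, biases at zero, all drawn reproducibly from
  `seed`; a training run is bit-for-bit reproducible.  An output of exactly
  `0.5` binarizes to `1`; such ties have measure zero and never decide a
  result.

The training loop itself is compiled (RcppArmadillo): one epoch is a
handful of dense `100 x 100`-scale matrix products, and a full `1e5`-epoch
fit at `R = 35` takes on the order of half a minute on one core.

## Critical bottleneck size

`capacity_sweep()` trains one network per (hidden size, matrix) cell over
an ensemble of replicate matrices and averages the fraction of behaviors
learned.  The critical bottleneck size `R_c` is the smallest grid value
whose *mean* fraction reaches the 98% threshold.  Averaging conventions
differ in the literature between thresholding the mean curve and averaging
per-matrix thresholds; both are computed (`R_c` and `R_c_per_matrix`), the
mean-curve value being primary.  `R_c` is grid-valued by design — no
interpolation — so grids should be step 1 near the expected crossing if
that resolution matters.  An information-theoretically ideal encoder would
need only `ceil(log2 N)` binary units (7 for 100 behaviors); the gap
between that bound and `R_c` is the phenomenon of interest, not an error.

## Perturbations and robustness

`perturb()` emulates optogenetic manipulation of single descending
neurons: a hidden unit (or a pair) is forced on or off for every command
while all trained parameters stay fixed.  Two mechanisms are provided and
tested for agreement on every binarized output: clamping the activation to
its saturated value (exact, the default) and injecting an arbitrarily
large value (`1e3`) into the unit's column of `W1` (the asymptotic
version).  Forced *silencing* is the symmetric clamp to zero.

A behavior is *conserved* when its entire binarized output row is
unchanged by the perturbation; robustness is the conserved fraction,
averaged over all single units (or pairs) by `network_robustness()` and
over ensembles by `robustness_curve()`.  A narrower criterion — only the
target-active motor units must be unchanged, spurious activations ignored —
is reported alongside as `robustness_active`, since the verbal definition
admits both readings; the strict row criterion is the primary statistic.
`R_robust`, by analogy with `R_c`, is the smallest hidden size whose mean
robustness reaches 98%.  `affected_distribution()` histograms how many
behaviors each perturbation alters; its total always equals the number of
perturbations applied.

## State-dependency as mutual information

Forcing a unit on maps each intended behavior to some perturbed output.
With uniform priors over the `N` inputs and the `M` original outputs
(`M = N` distinct rows here — the number of original outputs, not of motor
units), the mutual information between input and perturbed output reduces
to

$$I(X;Y) = \frac{1}{M}\sum_{y_i\,:\,n_i>0} \log_2\frac{N}{n_i},$$

where `n_i` counts the inputs landing on original output `y_i`
(`mapping_census()` tallies these).  Inputs mapped to *novel* rows outside
the original output set carry no information about the input and contribute
nothing; they are deliberately not pooled into an extra output symbol,
which would change the generic double-sum value.  Without stereotypy
(`n_i` in {0, 1}) the expression collapses to `(m/M) log2 N` with `m` the
number of conserved outputs — mutual information proportional to
robustness — and an unperturbed perfect mapping carries `log2 N` bits.
The census requires the original rows to be distinct; this perfect-learning
premise fails by construction for tiny modular blocks (when
`C(m_size, k - sigma)` is small relative to the rows per block), which
bounds how far the MI analysis can be miniaturized.

## What the generators do and do not emulate

The synthetic ensembles are the study's entire input distribution, so
passing tests demonstrate properties of *these* ensembles: exact row
sparsity, equal-sized non-overlapping modules, uniform placement, one-hot
commands, and a static mapping.  Real descending systems differ in ways the
model deliberately ignores: graded and temporally structured activity,
recurrence in the ventral nerve cord, unequal module sizes, correlated
behaviors, and non-binary motor control.  Conclusions transfer as intuition
about information constraints, not as quantitative predictions for any
measured circuit.

## Problem sizes and reproducibility

Default parameters reproduce the study conditions: `N = M = 100`,
`1e5` epochs, 30 replicate matrices for sparsity sweeps, 10 for modular
ensembles, and 5 for perturbation averages.  The test suite exercises the
same pipelines at reduced scale — `N = M` between 10 and 50, epochs between
800 and 3e4, 3–5 replicates — sizes chosen so each comparison retains a
decisive effect (the reduced-scale orderings pass one-sided tests at
`alpha = 0.05` with complete separation in most runs).  Every stochastic
step — matrix generation, weight initialization, mini-batch shuffling, pair
subsampling — is seeded, and sweep cells derive their seeds deterministically
from a master seed, so `capacity_sweep()`, `run_experiment()` and the rest
are bit-reproducible; `run_experiment()` writes a manifest from which its
whole bundle can be regenerated.

```{r, eval = FALSE}
library(bottlenet)

# a reduced-scale end-to-end pass
ens <- lapply(1:3, function(s) modular_behaviors(50, 50, 6, m = 5,
                                                 sigma = 0, seed = s))
sw <- capacity_sweep(ens, R_grid = c(6, 8, 10, 12, 14, 16),
                     epochs = 3e4, seed = 1)
sw$R_c

fit <- bottleneck_net(ens[[1]], R = sw$R_c, epochs = 3e4, seed = 1)
network_robustness(fit)$robustness
```

## Known limitations

* The fitted object stores dense weight matrices; memory scales as
  `O(N R + R M)`, which is trivial at study scale but the implementation
  makes no attempt at sparsity.
* `R_c` inherits the grid resolution, and near-threshold cells are
  sensitive to the epoch budget: undertraining biases `R_c` upward.  The
  package reports the full mean curve so that sensitivity is visible.
* Mutual information is defined only when the original outputs are
  distinct; `state_dependency_curve()` falls back from the network's
  outputs to the target matrix and flags the cell as failed when both
  contain duplicates.
* Pair activation enumerates `choose(R, 2)` perturbations; use `max_pairs`
  for large `R`.
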