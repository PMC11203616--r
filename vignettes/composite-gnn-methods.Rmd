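---
title: "Composite recurrent GNNs: models, training protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite recurrent GNNs: models, training protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compgnn)
```

## The models

`compgnn` implements two recurrent message-passing models for graph-level
molecular property prediction.

Both associate a state vector `x_n` of dimension `d_x` (`state_dim`) with
every node and refine it for `K` synchronous iterations. In the **standard
GNN**, one weight-shared single-hidden-layer MLP `f_w` (the
*state-updating network*) computes

    x_n^t = f_w( x_n^{t-1}, l_n, sum_{m in Ne(n)} (x_m^{t-1}, l_m, e_{m,n}) )

where `l_n` is the node's feature vector, `e_{m,n}` the edge's feature
vector and the sum runs over the neighbours of `n`, aggregating the
*concatenated* message `(neighbour state, neighbour features, edge
features)`. Because concatenation distributes over the sum, each block is
aggregated separately; a node with no neighbours receives the zero message.

The **composite model (CGNN)** targets heterogeneous graphs: each node is
assigned one of the eight element-group types (see below) and its update is
dispatched to the state-updating network dedicated to that type:

    x_n^t = f_{w,T(n)}( x_n^{t-1}, l_n, sum_{m in Ne(n)} (x_m^{t-1}, e_{m,n}) )

All per-type networks share the output dimension `d_x`, so differently
typed nodes exchange messages without adapters. Note the two printed
formulations differ in one detail: the standard GNN's message repeats the
neighbour's features `l_m`, the composite one does not. The implementation
exposes this as `include_neighbor_label` (default `TRUE` for `gnn_model()`,
`FALSE` for `cgnn_model()`, mirroring the formulations exactly); the
single-type equivalence test aligns the flag explicitly when comparing the
two models.

After `K` iterations a single output MLP `g_w` with a logistic-sigmoid
head is applied to every node's `(x_n^K, l_n)` and the per-node outputs are
*averaged* over the graph — a mean, not a sum, so the readout is
size-normalized and permutation invariant. One output network suffices even
in the heterogeneous case because all states share `d_x`.

### Atom grouping

Elements are collapsed into eight groups, in fixed order: Metals,
Metalloids, Halogens, Carbon, Nitrogen, Oxygen, Phosphorus, Sulfur. The
five organochemical workhorses keep singleton groups; everything else is
classed by the standard periodic-table families. Grouping keeps the number
of node types (and the length of one-hot encodings) small, and pools rare
species that would otherwise be unlearnable. The shipped table
(`compgnn_element_table`) covers the heavy atoms of common
medicinal-chemistry datasets; it classes Se and At with the metalloids and
halogens respectively (both standard classifications) and deliberately
omits hydrogen — heavy-atom graphs have no H nodes, and a user whose
encoding keeps explicit hydrogens must extend the table via
`element_grouping()`.

`heterogenize()` produces the typed representation the CGNN consumes (the
type carries the species; node features stay species-free);
`homogenize()` produces the homogeneous representation the GNN consumes
(the original features concatenated with the 8-long one-hot of the group).

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `K` | message-passing iterations | 6 | the reference protocol's fixed value; information propagates 6 hops |
| `state_dim` (`sd`) | node-state dimension | grid: 3/5/10/15/30 | capacity of the per-node memory |
| `hidden_state` (`hs`) | hidden units of `f_w` | grid: 10/20/30/50 | capacity of the state update |
| `hidden_output` (`ho`) | hidden units of `g_w` | grid: 20/40/70/100 | capacity of the readout |
| `activation` (`af`) | relu / tanh / selu | grid axis | shared by both hidden layers and the state-updater's output layer |
| `initial_learning_rate` (`ilr`) | Adam step size | grid: 1e-2..1e-5 | the only searched optimizer setting |
| `max_epochs` | epoch cap | 300 | protocol constant |
| `patience` | early-stopping patience (epochs) | 10 | protocol constant |
| `init_scale` | initial-state half-width | 0 | see "Numerical choices" |

The full grid is `enumerate_grid()`: 4 x 4 x 4 x 5 x 3 = 960 configurations
per model kind, in deterministic order with `config_id` as tie-break.
Adam's secondary constants are the textbook values (beta1 = 0.9,
beta2 = 0.999, eps = 1e-8).

## Training protocol

`fit_gnn()` trains full batch: one Adam update per epoch from the exact
gradient over the whole training split. Desk-scale datasets (hundreds to a
few thousand graphs) fit comfortably in memory, and full-batch gradients
make runs bit-reproducible from `(data, config, seed)`; a mini-batch
regime was left out deliberately as the protocol does not specify one.
After every epoch the validation loss is evaluated; a *strict* decrease
counts as improvement (ties do not — the simplest reading of "stops when
validation loss starts to increase"), and after `patience` consecutive
non-improvements training stops and the weights of the best epoch are
restored. The early-stopping controller is a pure function
(state machine) exercised directly by the tests on scripted loss
trajectories.

Losses: binary and multi-task problems use mean binary cross-entropy over
the *observed* entries only — `NA` targets contribute nothing to the value
or the gradient, which non-mutually-exclusive multi-task label sets
require. Regression trains on targets min–max-normalized to [0, 1] using
training-split statistics (the sigmoid head bounds outputs to (0, 1));
RMSE is always evaluated on the original scale through the stored inverse
transform.

Model selection in `run_sweep()` is by the dataset's *metric* on the
validation split (maximize AUROC/AP, minimize RMSE; ties break to the
earliest configuration), while early stopping inside each fit remains
loss-based — metrics are not differentiable proxies and the protocol
separates the two roles. Configurations that abort (e.g. divergence under
an aggressive learning rate) are recorded as failed and excluded without
stopping the sweep; each configuration derives its own seed from the base
seed and its `config_id`, so sweeps are reproducible and can be resumed or
parallelized.

## Evaluation metrics

`auroc()` is the rank-based (Mann–Whitney) estimator: the probability that
a random positive outscores a random negative, tied pairs counted half.
The multi-task variant averages per-task AUROC over tasks whose labels
contain both classes; single-class tasks are dropped with a warning, which
mirrors common benchmark-evaluator behaviour. `average_precision()`
averages precision at each positive's rank, then across tasks with at
least one positive. `rmse()` is reported in raw target units.
`metric_for_dataset()` encodes the benchmark assignment: AUROC everywhere
except the heavily imbalanced MUV (AP) and the regression set FreeSolv
(RMSE).

## Numerical choices

- **Initial states.** `init_states()` samples i.i.d. uniform
  `[-init_scale, +init_scale]` coordinates under a seed. Models default to
  `init_scale = 0` — the degenerate limit where every state starts at the
  origin. Reason: per-node random draws are indexed by batch position, so
  any nonzero draw makes `y_G` depend (at machine precision) on node
  numbering and on which other graphs share the batch; zero initialization
  makes graph outputs exactly invariant under node relabeling and batch
  composition, which we treat as a correctness property of a graph-level
  model. Symmetry between nodes is broken from iteration 1 by features,
  types and structure, not by the initial state. Users wanting randomized
  starts set `init_scale > 0`.
- **Message composition order** is fixed and documented:
  `(x_m, [l_m], e_{m,n})`; the empty sum is the zero vector.
- **Loss clamping.** Cross-entropy probabilities are clamped to
  `[1e-12, 1 - 1e-12]` before the log; the analytic gradient uses the same
  clamp and is verified against central finite differences at relative
  tolerance 1e-4 (observed error is orders of magnitude smaller).
- **Weight initialization** is fan-scaled uniform (Glorot) with zero
  biases, fully determined by `(spec, seed)`; every sub-network's seed is
  derived from the model seed by a fixed integer chain kept inside 32-bit
  range.
- **Degenerate inputs** fail fast with named errors: unknown elements,
  self-loops and duplicate edges, mismatched feature dimensions or task
  counts, all-missing target batches, constant regression targets,
  unregistered node types, non-finite losses.
- **Indexing.** Node indices are 1-based in R; the on-disk JSON dialect is
  0-based and converted at the boundary.

## The synthetic generator

`generate_graphs()` emulates the *shape* of heavy-atom molecular data:
small sparse connected graphs (2–40 nodes by default; a uniform spanning
tree plus uniformly sampled extra edges up to `edge_density`, default
0.15), node types drawn from a carbon-dominated mixture over the eight
groups (default 55% C, 15% O, 12% N, 6% halogens, 5% S, 3% P, 2% + 2%
metals/metalloids), and graph-level targets computed by a planted,
type-dependent rule: `type-fraction` (binary: is one group's node fraction
above a threshold?) or `type-weighted-sum` (regression: sum of a per-group
weight over nodes). Noise is label-flipping (binary) or Gaussian
(regression) at `noise_level` (default 0.1). Splits are 80/10/10 by graph,
and everything is a deterministic function of the spec seed.

What it does *not* emulate: chemistry. There are no valence limits, no
bond orders, no aromaticity, no realistic substructures — the models under
test are indifferent to chemical validity and react only to typed-graph
structure. Passing tests on these fixtures therefore demonstrate that the
machinery (representations, propagation, gradients, protocol, metrics)
behaves as specified, not that the models reach any particular accuracy on
real molecular benchmarks.

Problem sizes used by the test suite were chosen to make every property
checkable on a single CPU in minutes: oracle comparisons use all graphs up
to 4 nodes with `d_x <= 2`; training checks use tens of graphs; the
GNN-versus-CGNN comparison uses 500-graph fixtures with 4–12-node graphs,
five seeded replicates, and one fixed small configuration
(`sd = 5, hs = 20, ho = 20, tanh, ilr = 1e-2`) under the full protocol.

## Known limitations

- **Desk-scale direction of the GNN/CGNN comparison.** On the shipped
  `type-weighted-sum` fixture the composite model does *not* beat the
  homogeneous GNN: the planted rule is additive in group counts, which the
  homogeneous model represents directly through its one-hot labels with
  full parameter sharing, while each composite sub-network must learn its
  group's contribution from that group's nodes alone — and the rare groups
  (2–3% of nodes) give their networks very little data. This is the same
  sparse-type pathology that motivates grouping rare elements in the first
  place, reproduced in miniature. The corresponding directional test
  encodes the expected superiority of the composite model and currently
  fails; we keep it as an honest record rather than weakening the check.
  Heterogeneity is expected to pay off when types differ in *dynamics*
  (how messages transform), not merely in additive contribution.
- Node- and edge-focused output heads are out of scope (the readout is
  always the graph-level mean), as are stacked/layered variants,
  convergence-based stopping, learning-rate schedules and weight decay.
- The OGB adapter reads the on-disk CSV layout and maps the first atom
  feature (atomic number − 1) to an element symbol; it is a convenience
  for users with local OGB downloads and is exercised only on hand-built
  miniatures in the tests.
- `aggregation` supports `"sum"` only — the aggregation used throughout
  the reference protocol.
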