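---
title: "Learning population genetics from tree sequences: model and methods"
author: "tsgcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning population genetics from tree sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

A recombining chromosome does not have one genealogy: it has an ordered
sequence of marginal genealogical trees, adjacent trees separated by the
breakpoints of historical recombination events. Modern inference tools
(Relate, tsinfer) estimate this *tree sequence* directly from phased
haplotypes, and the sequence in principle carries everything a population
geneticist wants to know about the sample's history: coalescence times
respond to population size changes, tree shape and branch-length profiles
respond to selection, tree density along the chromosome responds to the
recombination rate, and the clustering of lineages across populations
responds to admixture.

`tsgcn` implements a neural architecture that consumes tree sequences
directly, without converting them back into a genotype alignment: each
marginal tree is processed as a graph by attention-based graph convolution
layers, the nodes of each tree are then compressed into a single vector by
a recurrent unit, the sequence of per-tree vectors is compressed again by a
second recurrent unit, and a fully connected head emits class scores or
standardized parameter estimates. The package also implements the
alignment-side comparison pipeline (seriation sorting of genotype matrices
and an exact parameter inventory of a ResNet34-shape image network) so that
tree-sequence inference can be benchmarked against the established
alignment-CNN approach on equal terms.

## Data model

A `marginal_tree` is a rooted, strictly binary genealogy of `n` present-day
haploid samples: `2n - 1` nodes, `2n - 2` child-to-parent edges, leaf times
exactly 0, internal times strictly positive, and strictly increasing time
along every edge. A `tree_sequence_record` is an ordered list of such trees
whose half-open intervals `[left, right)` tile the locus `[0, L)` exactly.
Coordinates are 0-based half-open throughout. Population labels live on
leaves (`0..k-1`); internal nodes are "population unknown".

Two deliberate strictness choices:

* **Non-binary trees are rejected, not resolved.** Every upstream source in
  scope (coalescent simulators, Relate-style inference) emits binary trees;
  silently resolving polytomies would hide upstream errors.
* **Exact parent/child time ties are forbidden.** Loaders nudge a tying
  parent upward by `time_epsilon = 1e-6` generations (reported via a
  message). The log-age node feature and the time-based canonical node
  ordering both need strictly positive, strictly ordered internal times;
  1e-6 generations is far below any meaningful time resolution of either
  simulated or inferred genealogies.

Succinct tree-sequence input is read as a text table dump (`#nodes`,
`#edges`, `#mutations` sections; `inst/python/dump_trees.py` produces the
dump losslessly from a binary `.trees` file). Marginal trees are
reconstructed by the standard sweep over edge insertions and removals
sorted by genomic coordinate, which reproduces the simulator's tree count
exactly — a property the test suite checks replicate by replicate.

## Featurization

Each node carries `F = 2 + (k + 1)` features:

1. the natural-log node age, standardized by the training-set mean and
   standard deviation of **internal-node** log-ages, with leaves fixed at 0
   *after* standardization (leaf zeros are a conventional constant, not a
   measurement, so they are kept out of the normalization pool);
2. the number of mutations on the branch to the parent, standardized over
   all nodes (the root, which has no parent branch, enters with count 0);
3. a one-hot role block over {internal, population 1, ..., population k}.

Edges are directed child to parent, so a node's graph-convolution
neighborhood is its children and a leaf's update reduces to its self term.

The **tree summary vector** holds 12 statistics: TMRCA; mean, median and
standard deviation of the `n - 1` coalescence times; mean, median, standard
deviation, skew and maximum of the `2n - 2` branch lengths; interval
midpoint scaled to (0, 1); spanned locus fraction; and total branch length.
The twelfth slot (total branch length) completes the set to the width the
architecture's shape accounting requires; it is the most natural
single-number summary of tree size not already in the list, and it is a
configurable design point of the package rather than a law of nature. The
**sequence summary vector** holds the elementwise mean, standard deviation
and median of the tree summary vectors plus the tree count of the original
(pre-downsampling) sequence: `3 x 12 + 1 = 37` values.

Numerical conventions, fixed once and used everywhere: population
(divisor-`n`) standard deviations, the Fisher-Pearson moment skew
`g1 = m3 / m2^{3/2}` (defined as 0 when `m2 = 0`), medians of even counts
as the mean of the two central order statistics. All summary dimensions —
including the integer tree-count slot — are z-scored with training-set
statistics; a dimension whose training standard deviation falls below
1e-12 gets its divisor replaced by 1 and is flagged, so constant
dimensions map to exactly 0 instead of NaN. Normalization statistics are
fitted on the training split only and serialized as versioned JSON;
validation and test data are always standardized with training statistics,
so no information leaks across the split boundary.

**Downsampling.** Sequences longer than `cap` trees (default 128) are
reduced before featurization. The default `"window"` mode keeps a
contiguous run of `cap` trees with the start uniform over valid positions.
The `"span_weighted"` mode draws `cap` trees with replacement with
probability proportional to spanned locus fraction and restores the
original ordering, duplicates retained; it is the right choice when the
signal can sit anywhere in the window (sweep classification), because a
contiguous window would often miss the selected region entirely. Both modes
preserve the original tree count for the sequence summary.

## Architecture

For a batch of featurized sequences the forward pass is:

1. node embedding: affine `F -> 26`, concatenated with the raw features
   (width `26 + F`);
2. six attention graph-convolution layers at constant width with an
   additive skip, per-node layer normalization, and ReLU:
   `x'_i = alpha_ii Theta_s x_i + sum_{j in N(i)} alpha_ij Theta_t x_j + b`,
   with attention coefficients
   `alpha_ij = softmax_{j in N(i) + {i}} a^T LeakyReLU(Theta_s x_i + Theta_t x_j)`
   (negative slope 0.2, a single head);
3. a second skip concatenation with the raw features (width `26 + 2F`);
4. a gated recurrent unit over each tree's nodes in canonical order
   (leaves in sample order, then internals by ascending time); its final
   hidden state is the tree's learned embedding;
5. concatenation with the normalized 12-dim tree summary, then a second
   gated recurrent unit along the tree sequence. Sequences in a batch are
   padded to the batch maximum, and each sequence's output is read at its
   true length, so padding provably cannot influence the result (an
   invariant the tests assert to 1e-5);
6. concatenation with the 37-dim sequence summary passed through an affine
   `37 -> 37` embedding (the width is pinned by the head's declared input
   shape);
7. two fully connected layers (width 256) with batch normalization and
   ReLU, then a linear output of size `M` — class logits for
   classification, standardized target estimates for regression.

The degree-normalized spectral convolution
`x'_i = Theta^T sum_{j in N(i)+{i}} x_j / sqrt(dhat_j dhat_i)` is kept as
an executable reference (`gcn_conv_reference`, in both matrix and node-wise
form); the learned attention replaces its fixed `1/sqrt(dhat dhat)`
weights, and the two implementations cross-check each other in the tests.

Ablation switches mirror the architecture study supported by the package:
`use_graph_conv = FALSE` routes raw node features straight into the
per-tree recurrence (topology is then ignored — asserted by edge-shuffle
invariance), and `use_tree_summary` / `use_global_summary` drop the
hand-crafted feature concatenations.

Choices worth recording because they were genuinely open:

* **Cross-entropy sign.** The loss is the conventional *negative*
  cross-entropy (a positive quantity to minimize), `-1/N sum_i log p_{i,y_i}`.
* **Attention flavor.** The implemented scoring applies the projection
  vector after the LeakyReLU of the summed transformed features (the
  "v2"-style attention); one head, biases enabled on the convolution
  output.
* **Leaf semantics.** Leaves get `Theta_s x_i + b`; with learnable
  `Theta_s` this subsumes the "no update for leaves" reading.
* **Head normalization order.** `Linear -> BatchNorm -> ReLU`, the common
  torch idiom; conv-block normalization is per-node LayerNorm (batch-size
  independent). Both use running statistics in evaluation mode, which is
  why evaluation outputs are independent of batch composition.
* **Recurrent hidden widths** default to 256 but are configuration-exposed;
  the desk-scale preset (below) uses 64.
* **Initialization.** Uniform fan-in for affine/convolution weights,
  orthogonal recurrent (hidden-to-hidden) blocks, zero biases, identity
  normalization layers; a single integer seed makes initialization,
  shuffling and downsampling bit-reproducible.
* **No dropout** anywhere.

### Implementation

There is no autograd: forward and backward passes are written explicitly,
with the gated recurrent unit, the attention convolution and layer
normalization as compiled (RcppArmadillo) kernels that keep their
intermediates on the C++ side between the forward and backward calls.
Every gradient path is verified against central finite differences in the
test suite (relative error below 1e-4 across all ablation
configurations). The optimizer is ADAM (default learning rate 1e-5, betas
0.9/0.999) with per-task default batch sizes (recombination 16,
introgression 36, sweeps 20, demography 30), up to 100 epochs, and early
stopping after 10 consecutive epochs without strict improvement of the
validation criterion — classification accuracy for classification tasks;
for regression, where "accuracy" is not defined, the negative validation
loss. The best-validation parameters are restored at the end.

## Benchmark generators

The synthetic module drives msprime (through the system `python`; there is
no R-native coalescent-with-recombination simulator) and converts its
tables into records. Population sizes in all configurations are diploid
`N`; simulations run with haploid lineages at size `2N`, so the pairwise
coalescence expectation is `2N` generations and `rho = 4NrL` — the test
suite checks the `n = 2` closed form against simulation.

* **Recombination-rate regression.** `N` uniform on {1000, 2000, 5000,
  10000, 20000, 50000}; `L = 20` kb; `mu = 1.5e-8`; per-bp crossover rate
  `r` from an exponential truncated to `[1e-8, 1e-6]`; 50 haploids; target
  `ln r`, z-scored with training statistics. The pre-truncation mean of the
  exponential is not pinned by anything external; the default `1e-7` is the
  geometric midpoint of the bounds, configuration-exposed and recorded in
  run manifests.
* **Demographic inference.** Three epochs, five targets in fixed order
  `(N0, T1, N1, T2, N2)` with `N0 ~ U[100, 4e4]`, `T1 ~ U[100, 3500]`,
  `N1 ~ U[100, 5000]`, `T2 = T1 + U[1, 3500]`, `N2 ~ U[100, 2e4]`; targets
  log-scaled then z-scored. Locus length, mutation and recombination rate
  (100 kb, 1.5e-8, 1e-8) are package defaults chosen as typical
  short-locus values, and are configuration-exposed.
* **Introgression.** Two populations split `T` generations ago with a
  single pulse at `U(0.3, 0.5) x T` into one of the two directions, or no
  pulse: three classes, balanced round-robin. The shipped parameterization
  is a generic isolation-with-migration model (equal diploid sizes `1e5`,
  split `4e5` generations, pulse proportion 0.25, 20 + 14 haploids) —
  deliberately generic, since species-fitted parameter sets belong to the
  user's configuration, not the package.
* **Sweeps.** Selection simulators are external tools, so sweep data are
  *ingested*, not generated: ms-format files plus a five-class manifest
  (hard, hard-linked, soft, soft-linked, neutral). When the manifest
  carries selected-site positions, labels are validated against the
  central-subwindow rule (site within the central 1/11 of the locus =>
  sweep class, outside => linked class); span-weighted downsampling is the
  task's default.

Per-replicate seeds derive from the dataset seed by a fixed counter
formula, so datasets are reproducible and extensible without re-simulating
earlier replicates.

**What the generators do and do not emulate.** They reproduce the
*statistical structure* of the benchmark tasks — parameter distributions,
class balance, sample layouts, true marginal trees with per-branch mutation
counts. They do not emulate genealogy-inference error: a model trained on
true trees and applied to Relate-inferred trees faces a distribution shift
(inference is biased toward far fewer topology changes than truly
occurred). The adapter (`infer_trees_adapter`) exists precisely so that
training sets can be rebuilt from inferred trees when the external tool is
installed; it refuses loudly when the tool is absent rather than silently
substituting true trees. Passing tests on generated data therefore
demonstrate that the learning pipeline works end to end, not that any
particular accuracy transfers to inferred genealogies or real data.

## The alignment-CNN comparison path

The comparison pipeline's bespoke preprocessing is implemented exactly:
zero-padding (or left-aligned cropping) of genotype matrices to a fixed
polymorphism count; seriation of rows under cosine distance (an open-path
ordering approximately minimizing total adjacent-row distance:
nearest-neighbor construction from every start plus 2-opt refinement, with
an exhaustive exact solver for up to 8 rows — the contract is "approximate
minimal path", not bit-compatibility with any particular routing solver);
and for two-population tasks, optimal one-to-one row assignment of the
second block to the seriated first block by an exact Hungarian solver
(written in the package; no linear-assignment solver is available in the
dependency stack), with surplus rows appended in seriated order. Cosine
distance involving an all-zero row is undefined mathematically and is
fixed at 1, deterministically. The ResNet34-shape parameter inventory
(`baseline_param_count`) enumerates the stem, all basic-block convolutions
and batch normalizations, projection shortcuts and the classifier head;
with one input channel and five outputs it totals 21,280,965 learnable
scalars, which the acceptance script recomputes from scratch.

## Desk-scale study sizes

Full-scale training of this architecture is a GPU workload (hundreds of
thousands of replicates, tens of epochs). The package's self-contained
evaluation uses a reduced recombination study chosen to exercise every
stage on a single CPU: true trees, 16 haploids, 20 kb, 3,000 training and
500 validation replicates, tree cap 64, hidden widths 64, batch size 16,
learning rate 3e-4 (scaled up from the full-scale 1e-5 in proportion to
the much smaller data volume, so that learning is visible within a few
passes), at most 2 epochs. The check asks for Spearman rank correlation of
at least 0.5 between predicted and true `ln r` on validation — a deliberate
floor that verifies the pipeline learns the right ordering, not a claim of
matching full-scale error rates.

## Known limitations

* Single attention head, unidirectional recurrences, no hierarchical
  pooling; these match the implemented design, and alternatives are out of
  scope.
* Ancient (non-contemporaneous) samples are unsupported; all leaves sit at
  time 0.
* VCF ingestion and unphased data are out of scope; genotype input is
  ms-format text.
* The published per-task grand totals of the graph network's learnable
  parameters cannot be reproduced from the published layer widths (the two
  recurrent layers alone exceed those totals at width 256), so the
  package treats recurrent widths as free hyperparameters and anchors its
  architecture-fidelity check on the alignment-CNN inventory instead,
  which *is* exactly reproducible.
* Training on 1 CPU is compute-bound; the compiled kernels are tuned for
  the desk-scale preset, and full-scale runs would need a GPU
  implementation outside this package's scope.
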