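---
title: "Dual-view modelling of drug-combination synergy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view modelling of drug-combination synergy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem

A drug-combination screen measures, for a triplet (drug1, drug2, cell line),
a synergy score: the deviation of the observed combined effect from the
additive expectation (Loewe additivity), positive for synergy and negative
for antagonism.  `dualsyn` learns to predict this score — or a
synergistic/antagonistic class — from two inputs that are cheap to obtain
for new drugs and new cell lines: the drugs' structures (SMILES) and the
cell line's bulk expression profile.  The practical questions the package is
built around are the ones screening labs actually face: how well can synergy
be predicted for unseen combinations, unseen cell lines and unseen drugs;
and how many measurements of a new cell line or combination are needed
before predictions on the remainder become reliable.

# The model

The network embeds each training example through two complementary views and
fuses them.

**View 1 — the combination on the cell.**  Each drug is parsed into a
heavy-atom molecular graph whose nodes carry a 78-dimensional feature vector
(documented below).  The two graphs are joined into a single *joint graph*
so that message passing can cross the drug boundary; four constructions are
implemented:

* `super_edge` (default): one virtual edge between the two atoms with the
  highest betweenness centrality in their respective molecules.  Betweenness
  (sum over unordered node pairs of the fraction of shortest paths through a
  node; unweighted, endpoints excluded, unnormalised) picks the most
  topologically central atom of each drug as the contact point.
* `all_nodes`: the full bipartite product between the two atom sets.
* `one_super_node`: a virtual node connected to every atom of both drugs.
* `three_super_nodes`: one virtual node per drug plus an aggregator node.

The joint graph is processed by a three-layer graph attention network
(GAT).  In each layer and head, the attention logit for neighbour j of node
i is a LeakyReLU (slope 0.2) of a learned linear function of the two
transformed node vectors; coefficients are softmax-normalised over the
in-neighbourhood of i, which includes i itself via an explicit self-loop
(the neighbourhood definition is silent on self-inclusion; self-attention is
the standard choice and keeps single-atom graphs well-defined).  Head
outputs are concatenated, in every layer including the last, and passed
through ReLU.  A global pooling layer (max by default, mean available) over
all nodes yields the combination embedding `z_AB`.  Pooling over nodes makes
the embedding invariant to node relabelling, which the tests assert
directly.  The cell line's expression vector passes through a two-layer ReLU
MLP to give `z_cell`; `z_ec = ReLU(W [z_AB || z_cell] + b)` is the view-1
embedding.

**View 2 — the combination of per-drug embeddings on the cell.**  Each
drug's circular fingerprint is concatenated with `z_cell` and passed through
a single shared drug-on-cell encoder (one weight matrix for both drugs —
the defining symmetry of this view); the two resulting vectors are
concatenated in drug order and encoded once more to give `z_ce`.

**Prediction net.**  `[z_ec || z_ce]` passes through three ReLU layers and a
final linear (regression) or two-class softmax (classification) output
layer.

**Drug-order symmetry.**  Both the joint graph's node indexing and view 2's
concatenation order distinguish drug A from drug B, but synergy of (A, B)
must equal that of (B, A).  The package therefore trains on every record in
both orders and averages the two orders at prediction time, which makes
`predictTriplet()` exactly symmetric (asserted as an identity in the test
suite), rather than approximately symmetric through augmentation alone.

# Featurisation choices

**78-dimensional atom features.**  The layout follows the convention
established by graph-based drug-response models: a 44-symbol one-hot (last
slot catches out-of-vocabulary elements), degree 0–10 one-hot, total
hydrogen count 0–10 one-hot, implicit valence 0–10 one-hot, and an aromatic
flag — 44 + 11 + 11 + 11 + 1 = 78.  The exact recipe is an assumption
(adopted and documented here as the package's convention); the tests pin the
layout down by construction (block row-sums, aromatic flag position) and
verify atom/bond/hydrogen counts against an independent cheminformatics
toolkit on a 20-molecule reference set.  Hydrogens are implicit: the graph
contains heavy atoms only.  Molecule parsing, formal charges, ring and
aromaticity perception go through OpenBabel (via ChemmineR/ChemmineOB);
hydrogen counts derive from standard valence rules with charge adjustment.

**Circular fingerprints.**  Morgan-style fingerprints with radius 6 and a
configurable length (default 1024 bits) are computed by an ECFP-type
iteration implemented in the package: initial atom invariants (symbol,
degree, hydrogen count, charge, ring membership) are hashed, then
iteratively combined with sorted (bond order, neighbour id) pairs; aromatic
bonds carry their own bond-order code so the result does not depend on the
kekulisation openly chosen by the parser.  Environments covering an
identical bond set collapse to one bit (the smallest identifier), making the
fingerprint invariant to atom reordering of the input SMILES — a property
the tests check, along with the single-atom case (exactly one bit).  Bit
values are implementation-defined; only the contracts (determinism,
invariance, binary range) are promised.

**Expression features.**  TPM values are transformed as `log2(TPM + 1)` and
z-scored per gene.  Whether to normalise per gene or per cell is an open
choice; per-gene scaling was chosen because the cell encoder consumes genes
as features and per-gene location/scale differences would otherwise dominate
the input.  Centre and scale are computed on the *training* cells only and
frozen into an `ExpressionScaler` that travels with the model, fixing both
the statistics and the panel order at prediction time.  Zero-variance genes
map to 0; panel genes missing from the matrix are dropped with a warning.
The gene panel is an input file, not a constant: real use would supply a
drug-sensitivity-related panel of ~2000 genes, the synthetic benchmark uses
a 64-gene panel.

# Screen preprocessing

Replicate measurements of the same unordered (drug1, drug2, cell) triplet
are collapsed to their median, unless the triplet is unreliable: any two
replicates with strictly opposite signs, or a coefficient of variation
(sample sd / |mean|, computed when there are at least two replicates) above
0.5, exclude it.  Two boundary conventions are documented rather than
guessed silently: a zero replicate is sign-compatible with either sign (the
sign rule fires only on strict sign opposition), and a near-zero mean with
unequal replicates is treated as infinite CV (excluded) because the ratio is
undefined there — note that for small replicate sets any zero replicate
already forces CV > 0.5, so the zero-sign convention is not separately
observable in the output.  Classification labels use a dead band: scores
above +10 are synergistic, below −10 antagonistic, and the additive middle
is dropped from the classification task.  The thresholds are configurable;
±10 on the Loewe scale is the package's default, chosen as common field
practice since no canonical value exists.

# Split strategies and the leave-drug-out contract

Four cross-validation strategies are provided: `random` over triplets,
`pair_out` over unordered drug pairs, `cell_out` over cell lines and
`drug_out` over drugs.  For `drug_out` the package's default (`both` mode)
requires both drugs of a test triplet to be held out and drops triplets
pairing a held-out drug with a seen drug from that fold entirely — this is
the only materialisation under which *no drug seen in the test set occurs
anywhere in training*, which is the point of the scenario.  A laxer `any`
mode (one held-out drug suffices for test membership; train still excludes
all held-out drugs; nothing is dropped) is available for comparison.
Record conservation (train + test = all, disjoint) holds for every strategy
except `drug_out` in `both` mode, where the dropped middle is reported
explicitly by `splitFold()`.

# k-shot fine-tuning

For a held-out cell line (CellOut) or drug pair (PairOut),
`kshotAugment()` moves k measurements of that entity from the fold's test
set into training, seeded and without replacement.  `fineTuneModel()` then
continues optimisation of *all* layers at a reduced learning rate on the
augmented training set.  Two protocol details matter and are deliberate:

* The shots are added to the training records rather than trained on alone;
  fine-tuning on k records in isolation overwrites the base signal
  (catastrophic forgetting) and reliably hurt held-out accuracy in
  development experiments at desk scale.
* When a validation subset of the shots is supplied (`valRecords`),
  fine-tuning early-stops on it and the *initial* weights compete as the
  epoch-0 candidate.  Fine-tuning that never improves the shot-validation
  loss therefore returns the model unchanged instead of degraded, which
  makes the k-shot curve non-decreasing in expectation — the behaviour one
  wants from a protocol whose selling point is "add a few measurements,
  never get worse".

With k = 0 fine-tuning is a weight-identical no-op.

# Training

Optimisation is Adam (beta1 0.9, beta2 0.999) on mean squared error
(regression) or cross-entropy (classification).  The published source of
the architecture's hyperparameters is not available, so the package
documents its own defaults and marks them as assumptions: learning rate
1e-4 (1e-5 for fine-tuning), batch size 128, dropout 0.2 on hidden MLP
activations, early stopping with patience 10 on a 10% validation split
carved from the training records, best-validation weights retained.  All of
them are settings of `trainControl()`/`synergyConfig()`, and the
experiments below deliberately use larger learning rates and batches — the
package treats hyperparameters as tunable per dataset, as any grid search
would.  Every stochastic element (weight init, shuffling, dropout,
validation split) is seeded; the same seed reproduces the same weights
bit-for-bit on one CPU.  The full forward and backward passes are
implemented in vectorised base R; the gradients are hand-derived and
verified against central finite differences for every weight tensor in the
test suite (relative error below 1e-4 at epsilon 1e-5, typically 1e-8).
Unique drug pairs in a batch are embedded once through the GAT and their
gradients accumulated across the records that share them, which is what
makes CPU training practical: cost scales with distinct pairs, not with
triplets.

# The synthetic benchmark

Everything is testable offline because the package ships a generator with
the statistical structure the model assumes:

* **Drugs** — real small-molecule SMILES from a curated in-package list of
  99 (validated against an independent parser during development), extended
  with generated alkanes/alcohols when more are requested.
* **Expression** — log-normal TPM with 4 correlated gene blocks
  (within-block correlation 0.7), emulating co-expression modules.
* **Synergy** — a planted function of exactly the two information sources
  the dual views consume: a sparse linear function of the AND of the two
  drugs' fingerprints (symmetric in the pair by construction) plus a
  pair-by-cell interaction between per-pair coefficients and the cell's
  block means, plus Gaussian noise.  Component scales default to sd 8.5
  (drug term), 5.3 (cell interaction) and 3 (noise) on the score scale —
  roughly 70/25/5 percent of variance — reflecting the field's experience
  that synergy is mostly pair-driven with a meaningful cell-line
  modulation; replicate noise sd 1 and 3 replicates per triplet mimic a
  screen's technical replication.  A configurable fraction of triplets
  receives deliberately unreliable replicates (half sign conflicts, half CV
  0.75) to exercise the filter; note the filter also removes genuinely
  near-zero-score triplets whose replicate noise straddles zero, so the
  observed exclusion rate exceeds the planted fraction — that is the
  filter working as specified, not a generator defect.
* **Domain shift** — for fine-tuning experiments, the last 20% of cell
  lines receive an additional pair-specific score offset that is itself a
  sparse function of the fingerprint AND (strength `domainShift`, 8 in the
  shipped experiments).  Linking the shift to substructure is what makes
  k-shot adaptation *generalise* across the pairs of the shifted cell
  rather than only memorising the k shots.

What the generator does not emulate: dose–response surfaces and the
computation of synergy from raw viability, assay plate effects, non-linear
structure–activity relationships beyond the planted linear terms, mutation
features, and the chemical diversity of a real screening library.  Passing
the benchmark therefore demonstrates that the architecture, optimiser and
protocol can recover a fingerprint-by-expression signal end to end — not
that real-screen accuracy will match the benchmark's.

# Problem sizes in the shipped experiments

The test suite and the acceptance script run, on one CPU in a few minutes:
an overfit check (64 triplets to < 1% of the initial loss), a learnability
benchmark (2000 triplets from 14 drugs x 30 cells, random split, held-out
PCC above 0.8), and a 3-seed CellOut fine-tuning comparison (14 drugs x 20
cells, shift 8, k = 50).  The compact architecture used there (2 heads x 16
hidden, 64-dim embeddings) was chosen once for these data sizes; the
package defaults mirror the larger architecture appropriate for real
screens (4 x 64, 256-dim embeddings, 2087-gene panel).

# Numerical notes and degenerate inputs

* Attention softmax is computed with per-neighbourhood max subtraction;
  coefficient rows sum to 1 within 1e-5 by test.
* Max pooling breaks ties by first index; permutation invariance is
  unaffected because the pooled *value* is order-free.
* Disconnected molecules (salts): centrality is computed per component
  (unreachable pairs contribute zero) and the argmax runs over all atoms;
  centrality argmax ties break to the lowest atom index.
* Single-atom drugs, zero-variance genes, empty fine-tuning sets, constant
  predictions (PCC reported as 0 with a warning), NaN losses (training
  aborts with a diagnostic naming the epoch and learning rate) are all
  handled and tested.
* Validation-based early stopping restores the best epoch's weights; with
  no validation split the final weights are returned.

# Known limitations

* The GAT runs on CPU in R; wall-clock cost grows with the number of
  distinct drug pairs per batch.  Hundreds of drugs and thousands of pairs
  are feasible; proteome-scale libraries are not the target.
* Bond types are not edge features; cross-drug virtual edges are ordinary
  undirected edges (whether they should carry a distinct type is an open
  modelling question; the plain-edge reading was implemented).
* The fingerprint hasher is this package's own ECFP-style variant: bit
  positions are not interchangeable with other toolkits' Morgan bits,
  though all contracted invariances hold.
* Classification assumes two classes with a dead band; ordinal or
  multi-class readouts are out of scope.
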