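---
title: "Methods: dual-view contrastive pretraining and functional-group prompts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-view contrastive pretraining and functional-group prompts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Molecular property prediction is starved for labels: assay datasets hold
hundreds to a few thousand molecules, while unlabeled chemical space is
effectively unlimited. A now-standard remedy is contrastive pretraining of a
graph encoder on unlabeled molecules, followed by fine-tuning. The catch is
that popular graph augmentations (atom masking, bond deletion, subgraph
removal) mutilate the chemistry: the "augmented" molecule is no longer a
molecule, and near-identical structures with very different activities
(activity cliffs) make such perturbations risky.

`fragprompt` implements an alternative built on two ideas:

1. **A chemistry-preserving second view.** Instead of corrupting the graph,
   the second view of each molecule is its BRICS fragment-reaction graph:
   retrosynthetically meaningful bonds are cleaved, every resulting
   fragment becomes a node, and every cleaved bond becomes an edge labelled
   with its pair of BRICS link classes. Nothing chemical is invented or
   destroyed; the two views describe the same molecule at atomic and
   fragment resolution.
2. **Functional-group prompts at fine-tuning time.** A learnable embedding
   table over 82 named functional groups (SMARTS patterns), fused with the
   atomic embeddings of each group's match sites and attended over by a
   learnable task token, yields a per-molecule prompt vector. The task
   token's attention weights double as a per-group interpretability report.

# Model

## Featurization

Atoms carry eight attribute groups (element one-hot over 13 symbols +
other, degree 0–5, formal charge −2..2, chirality tag, attached hydrogens
0–4, hybridization, aromaticity flag, atomic mass / 100), 42 channels in
total. Bonds carry four groups (bond type, conjugation flag, ring flag,
stereo tag; 12 channels). Fragments carry seven groups: the 167-bit MACCS
structural keys, per-element heavy-atom counts (C, N, O, S, P, halogen,
other), topological polar surface area / 100, heavy-atom count, ring
count, and hydrogen-bond donor and acceptor counts — 179 channels.
Fragment descriptors are computed on the fragment as its own molecule with
cut bonds capped by hydrogens. Reaction edges are encoded as the unordered
pair of BRICS link labels L1..L16, two concatenated one-hots sorted by
label index. Hydrogens are never explicit nodes.

The exact composition of the atom/bond/fragment groups is a documented
convention of this package (the families of encoders we follow use
essentially this set); the group counts (8/4/7) are fixed so that feature
dimensionality — and therefore every weight shape — is reproducible.
Chemistry primitives (SMILES parsing, BRICS, SMARTS matching, MACCS, TPSA,
Murcko scaffolds) are delegated to RDKit through a bundled, batched Python
helper; one subprocess call featurizes an entire corpus and results are
memoised per session.

## Encoders

The original-graph encoder is a communicative directed-edge
message-passing network: each directed bond holds a hidden state; per
node, incoming edge states are aggregated by both sum and elementwise max,
combined by a learnable map, and fed back into the edge updates (K = 3
rounds by default); node states are read out by summation. Sum readout is
deliberate — molecule size is informative for property tasks. The
fragment-graph encoder embeds fragment features, folds reaction-edge
features into messages over the fragment graph, and finishes with
multi-head self-attention across the fragments of a molecule before sum
readout. Both encoders are permutation-invariant at the graph level
(property-tested to 1e-5 under random reindexing) and deterministic given
parameters. Initialization is uniform Glorot everywhere, seeded; two
constructions from the same seed are bit-identical.

Both encoders sit behind one interface (`encode_original()`,
`encode_augmented()`), so alternatives can be swapped without touching the
contrastive or prompt machinery.

## Contrastive objective

Projection heads (two-layer ReLU MLPs) map both graph embeddings to a
latent space. For a batch of N molecules all 2N projected embeddings are
anchors; the positive of an anchor is its counterpart view and the
denominator runs over the other 2N−1 embeddings (cross-view and
within-view negatives), with cosine similarity scaled by temperature
τ = 0.1. The loss is the mean of the 2N per-anchor terms. Two forced
consequences are tested: with N = 1 the loss is exactly zero, and the loss
is invariant to any common rescaling of the embeddings. `nt_xent_loss()`
is verified against a brute-force enumeration oracle to 1e-6.

## Functional-group prompt

For a molecule with matches V₁..V_m (every distinct atom set of every
table SMARTS counts, one row per occurrence), each match's table embedding
is concatenated with the sum and the elementwise max of its member atoms'
final encoder embeddings and passed through a learnable linear map and
rectifier. A learnable task token is prepended and single-block
self-attention (independent query/key/value maps, output projection,
layer normalization) is run over the m+1 rows; row 0 is the molecule's
prompt vector. The printed form of the attention block reuses the query
weights for the value projection; we read that as a typo and default to an
independent value map, keeping the literal tied variant behind
`tie_value_to_query = TRUE` — the attention pattern is identical either
way, only the mixed values differ.

The prompt is scaled by a learnable scalar α (initialized at 1),
concatenated to the graph embedding, and passed to a two-layer
Xavier-initialized prediction head. The fine-tuning objective adds
γ‖Ftable‖² (γ = 1e-4 by default; the value is a package default, exposed
in the configuration). The prompt width defaults to the encoder width so
the concatenation is balanced.

With m = 0 the prompt is a deterministic function of the task token alone;
the prompt is permutation-invariant in the group ordering; attention rows
are exact probability vectors. All three are tested.

# Training procedure

**Pretraining** iterates shuffled batches of dual-view pairs and minimizes
the mean contrastive loss with Adam. Desk-scale defaults (batch 32, 20
epochs, lr 1e-3) are sized for the packaged 240-molecule corpus on one
CPU; for large corpora the regime this objective is typically run at is
batch 1024, 50 epochs, lr 3e-5, available by configuration.

**Fine-tuning** shares the pretrained original-graph encoder, then trains
encoder, prompt table, task token, attention parameters, α and head
jointly (binary cross-entropy with logits, or MSE), with missing labels
masked out of loss and metrics. Early stopping watches the validation
metric (ROC-AUC maximized / RMSE minimized, patience 8 by default) — with
one refinement worth spelling out: epochs that *tie* the best validation
metric refresh the parameter snapshot without resetting patience. On easy
tasks the validation metric saturates within a couple of epochs; a strict
"first best wins" rule would then freeze the attention block in a
near-initialization state and the interpretability weights would be noise
even though predictions are perfect. Keeping the most-trained among
equally good snapshots costs nothing on the metric and lets the attention
continue to organize.

Fine-tuning runs once per requested seed (three by default); test metrics
are reported per run and aggregated as mean ± sd. `explain()` reports, per
molecule, every functional-group match whose task-token attention weight
clears a threshold (0.1 by default, matching the reporting convention for
such weights; 0.15 is the stricter variant). By default the reported
weight is the average of the task-token attention over the independent
runs — a single run's attention can concentrate on a correlated group
(e.g. phenyl where hydroxyl is the causal one) by accident of
initialization, and averaging over runs suppresses exactly that
run-to-run arbitrariness, in the same spirit as reporting mean ± sd
metrics. A single run's raw weights remain available via `run =`.

Ablations are configuration flags: `no_pretrain` (seed-initialized
encoder), `no_atom_message` (zeroed atom-signal channels in the fusion
step), `no_fg_prompt` (zero vector in the prompt slot, head shape
unchanged).

# Dataset handling

Datasets are tibbles with a `smiles` column and one label column per task;
empty cells are missing labels, masked everywhere. Scaffold splitting
groups molecules by Bemis–Murcko scaffold and assigns whole groups —
largest first, ties broken by byte-order scaffold string so the split is
locale-independent — to train, then validation, then test (0.8/0.1/0.1 by
default). Acyclic molecules share the empty scaffold and travel together;
this is the standard convention. Classification is scored by per-task
ROC-AUC (single-class tasks are skipped with a warning, never silent NaN);
regression by RMSE and MAE.

# Synthetic benchmarks

The packaged fixture corpus holds 240 curated molecules (drugs plus
enumerated substituted scaffolds), spanning 95 Murcko scaffolds and 53 of
the 82 functional-group classes; every entry parses and BRICS-processes.
`generate_dataset()` builds labelled tasks whose ground truth is defined
through the same SMARTS table the model consumes — deliberately, so that
learning experiments isolate the training machinery rather than chemistry
disagreements. Rules: presence of a named group, AND/XOR of two groups, or
a linear combination of match counts with Gaussian noise. When the
requested size exceeds the corpus, the pool is expanded by BRICS
recombination (fragments rejoined only at compatible link pairs; every
generated SMILES re-parses). Classification datasets are rebalanced to
30–70% positives by stratified sampling. Everything is exactly
reproducible from the task-spec seed.

What these synthetic tasks do **not** emulate: assay noise, activity
cliffs, label correlations between tasks, and realistic property value
distributions. A model that recovers the hydroxyl rule here demonstrates
that the pipeline can learn and attribute a substructure-determined
property; it does not demonstrate benchmark-level accuracy on real ADMET
data, which requires pretraining at a scale (hundreds of thousands of
molecules) deliberately out of scope for this package's test suite.

# Numerical choices and problem sizes

All learning runs through a small reverse-mode tape over dense matrices
written for this package (no automatic-differentiation library is
assumed); gradients are finite-difference-checked in the test suite.
Masked softmax uses additive −Inf block masks with row-max subtraction;
layer normalization uses ε = 1e-5; Adam uses the conventional
(0.9, 0.999, 1e-8). Segment max routes gradients to argmax entries; empty
segments (atoms with no incoming edges, molecules with no matches)
contribute zeros by construction, which makes single-atom molecules and
match-free molecules well-defined rather than special-cased errors.

The shipped test and acceptance configurations use hidden size 64, depth
3, batch 32 (pretraining) / 64 (fine-tuning), 20 pretraining epochs and up
to 10 fine-tuning epochs on an 800-molecule synthetic task — sizes chosen
so the full suite runs comfortably on one CPU while still exercising every
code path end to end. Checkpoints record a hash of the featurization
configuration and refuse to load against a different one.

# Known limitations

- Molecules outside the BRICS rules yield a single-fragment view, so the
  contrastive pair degenerates to (graph, whole-molecule-as-fragment);
  pretraining tolerates this but learns less from such molecules.
- The fragment encoder is a fragment-level attention message-passing
  network; the augmented view does not retain atom-level nodes inside
  fragments. The heterogeneous alternative would be a drop-in replacement
  behind `encode_augmented()`.
- The prompt table is fine-tune-only; no pretraining signal reaches it.
- Attention weights are attributions, not causal claims; the run-averaged
  report mitigates but does not eliminate attention's freedom to attend to
  correlated groups.
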