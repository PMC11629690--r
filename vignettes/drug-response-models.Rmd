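---
title: "Modelling drug response from structures and omics profiles"
author: "drpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug response from structures and omics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpred)
```

## The modelling problem

A pharmacogenomic screen measures a sensitivity summary — the natural log
of the half-maximal inhibitory concentration (ln-IC50), the area under the
dose–response curve (AUC), or the activity area (ActArea) — for pairs of
cancer cell lines and drugs. The regression task is to predict that value
for a new pair from (i) the drug's molecular structure, given as a SMILES
string, and (ii) the cell line's omics profile. `drpred` treats the model
as a triple of exchangeable parts: a *drug encoder* mapping a structure to
one vector or a sequence of per-token/per-atom vectors, a *cell encoder*
compressing one omics profile into a vector, and a *fusion module* that
combines the two and feeds a small prediction head. Nine drug encoders,
nine cell encoders, and two fusion modules yield 135 valid combinations
(attention fusion needs a sequence-valued drug encoding, which six of the
nine drug encoders provide: 9×9 + 6×9).

## Featurization

**Drugs.** Three modalities are derived from SMILES via OpenBabel
(ChemmineOB):

- *Circular fingerprints.* Atom-centred substructure environments up to a
  radius (default 2 bonds) are enumerated ECFP-style — an atom-invariant
  hash refined by iterating over the sorted multiset of
  (bond order, neighbour identifier) pairs — and folded into `L` bits
  (default 1024). Inputs are canonicalised first and the hash is
  order-invariant, so any spelling of a molecule gives identical bits.
- *Token sequences.* A character-level tokenizer with a two-character
  element pass (`Cl`, `Br` are single tokens); the vocabulary is built from
  the training corpus, id 0 is padding, the last id is UNK for unseen
  characters. Sequences longer than `max_len` (default 200) are truncated
  with a warning rather than dropped, which would silently change dataset
  composition.
- *Molecular graphs.* Heavy atoms are nodes (hydrogens implicit), each bond
  appears as two directed edges. Atom features: one-hot element over the
  nine most common organic elements plus "other", one-hot degree (1–4, 5+),
  formal charge, aromatic flag, one-hot hybridisation (from MOL2 atom
  types). Bond features: one-hot order (single/double/triple/aromatic/
  other), conjugation flag, ring flag (a bond is in a ring iff it is not a
  bridge of the bond graph). The schema is versioned
  (`atom_feature_schema()`) so encoders can assert input widths.

**Cells.** Four modalities: expression (EXP), pathway enrichment scores
(PES), binary mutation status (MUT), and continuous copy-number values
(CNV, log-ratio scale, passed through unchanged with an optional
discretisation threshold). PES uses a deliberately simple single-sample
score: expression is z-scored across genes *within* each cell and a
pathway's score is the mean z over its member genes present in the
profile — cheap, deterministic, order-invariant, and checkable by hand. A
rank-based scorer is a possible extension point, not the default.
Model-input normalisation (per-gene z-score) is fitted on training-split
cells only and reused unchanged for validation/test profiles, so no
held-out information leaks into the inputs; the fitted statistics, gene
order, and token vocabulary travel inside the checkpoint.

## Encoders and fusion

Cell encoders are feed-forward (`DNN_*`, hidden sizes default 512→128) or
convolutional (`CNN_*`, two kernel-9 stride-2 layers over the frozen gene
order — order-sensitive by construction, hence the gene order is serialized
with the checkpoint) per modality, plus `DAE_EXP`: a denoising autoencoder
pre-trained to reconstruct clean expression from corrupted inputs (masking
noise, each entry zeroed with probability 0.2 by default; Gaussian noise is
an option). Pretraining runs on training-split cells only; evaluation of
reconstruction quality always uses clean inputs. The hidden width equals
the fusion width `d`, asserted when the model is built.

Drug encoders follow their published structures at desk scale: a two-layer
perceptron over fingerprints; a three-layer kernel-7 convolution stack and
one-layer bidirectional GRU/LSTM over embedded tokens; and five graph
networks — spectral-normalised graph convolution (GCN), additive graph
attention (GAT, 2 heads), an edge-conditioned message-passing network
(`GRAPH_MPG`, architecture only, with `load_mpg_weights()` as a hook for
externally pre-trained weights), and two attention-readout networks
(AttentiveFP-style neighbour attention with GRU state updates; and a
TrimNet-style triplet-message network whose per-edge attention is a softmax
over each atom's incoming edges). The two readout networks condense atoms
into a single vector through two GRU-attention steps over a summary node;
for the TrimNet-style encoder this attentive readout stands in for the
original Set2Set readout, keeping the parameter count small without
changing the output contract. Encoders that emit sequences carry a mask;
padded positions are stripped before encoding, so padding values can never
influence outputs.

`DNN_FUSION` pools sequences by masked mean or max and then adds (equal
widths required) or concatenates drug and cell vectors. `MHA_FUSION`
computes scaled dot-product attention with the cell vector as the query
over the drug sequence as keys and values, default 4 heads of width `d/4`
with a learned output projection. Masking is additive −10⁹ on the logits,
which underflows to an exactly-zero softmax weight on padded positions.
The prediction head is two linear layers with a ReLU between and no output
activation, since the response scales are unbounded.

## Splitting and leakage control

Four strategies, all pure functions of (records, strategy, fractions,
seed). Fractions (default 8:1:1) apply to *entities* for the
leave-one-kind-out splits: cells (or drugs) are partitioned, and records
follow their entity, so the three parts share no cell (drug) and all
records are preserved. The `strict` split partitions cells and drugs
independently and keeps a record only when its cell and drug fall in the
same part; cross-part pairs are discarded (and counted), the only treatment
that guarantees test pairs are simultaneously novel-cell and novel-drug.
Part sizes are floor(fraction × n) with the remainder assigned to
training. Duplicate (cell, drug) records are collapsed to their mean
response during cleaning — an order-independent rule.

## Training, evaluation, benchmark

Training minimises MSE with Adam (optionally AdamW-style decoupled weight
decay); every source of randomness — weight initialisation, batch
shuffling, autoencoder noise — is derived from explicit seeds, and the same
seed reproduces a loss history bitwise. Validation MSE is computed every
epoch and the checkpoint keeps the best-validation-epoch weights (the
selection rule is the package's choice). Metrics are MSE, R² = 1 −
SS_res/SS_tot, and the Pearson correlation; a zero-variance truth or
prediction vector makes the correlation undefined and is reported as an
explicit flag, never a silent NaN.

The benchmark harness trains each configuration over a learning-rate grid
(default {1e-3, 1e-4, 1e-5}), picks the rate with the best validation MSE,
and reports the winner's test metrics as mean ± SD across seeds (default
three), with failed runs recorded as failed rows. `benchmark_suite()`
names 16 configurations: three literature-style pairings (SMILES-CNN over
mutations, fingerprints over pathway scores, fingerprints over an
expression autoencoder) and thirteen further factory picks covering every
encoder family and both fusion modules.

## The synthetic screen

`generate_fixture()` emulates a small screen: per-gene standard-normal
expression, Bernoulli(0.1) mutations, N(0, 0.5) copy numbers, eight real
small molecules (ethanol through ibuprofen) with known graph and token
shapes, and a full cells × drugs response grid

    response = w · EXP_subset + offset_drug (+ b_drug · (w₂ · EXP_subset)) + ε,

with the planted parameters returned so tests can verify recovery. It
deliberately omits realistic pharmacogenomic correlation structure, batch
effects, and missingness — passing tests demonstrate that the machinery
learns a learnable signal without leakage, not that any architecture is
state of the art on real screens. Thirty overlapping gene sets are
emitted; a PES profile needs at least ~25 features for the convolutional
cell encoder's stacked receptive field, and real collections have dozens to
thousands of sets.

## Numerical and scale choices

All networks run on a small tape-based reverse-mode automatic
differentiation engine over base R matrices (gradients verified against
finite differences to 1e-10 in the tests). Problem sizes in tests and the
acceptance script are desk-scale by design: encoder width `d` 16, the
20-cell × 8-drug grid for splitting properties, ten records for overfit
checks, and 500-epoch caps with early stopping once training MSE falls
below threshold.

Two sizing decisions deserve explanation. First, the splitting and
featurization properties use the 20-cell default grid, but the
leave-cell-out *benchmark* runs on a 60-cell fixture: with 16 training
cells and 50 genes the cell-direction regression is underdetermined for
any estimator (a ridge oracle is equally unstable there), whereas 48
training cells make the planted signal recoverable — and real screens have
hundreds of lines. Second, benchmark training uses decoupled weight decay
(coefficient 5 at learning rate 1e-3): with few cells the cell branch
memorises profiles instead of learning the linear map, and the decay
supplies the same capacity control that ridge regression provides for the
oracle.

## Limitations

No stereochemistry beyond what SMILES encodes, no 3D conformers, no
proteomics/methylation modalities, no batch correction or imputation. The
message-passing drug encoder ships without pre-trained weights. The
public-screen loader (`load_public_dataset()`) normalises pre-placed files
and performs no downloads. Training is CPU-bound R; the engine is meant
for method development and teaching-scale experiments, not
GPU-scale screens.
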