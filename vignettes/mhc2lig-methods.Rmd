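---
title: "Modelling MHC class II ligands with binding-core alignment and processing context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MHC class II ligands with binding-core alignment and processing context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MHC class II molecules present peptide fragments of exogenous proteins to
CD4+ T cells. Their binding groove is open at both ends: a nine-residue
*binding core* sits in the groove (anchor positions P1, P4, P6 and P9),
while the remaining ligand residues protrude as *peptide flanking regions*
(PFRs). Naturally presented ligands, observed by mass-spectrometry elution
(EL data), are therefore variable in length — typically 11 to 19 residues
with a preference around 14–16 — and their termini carry traces of the
proteolytic machinery that produced them. In vitro binding-affinity
measurements (BA data) quantify the same core–groove interaction on a
continuous scale but know nothing about antigen processing.

`mhc2lig` models both data types jointly and asks whether signals of
antigen processing, read from the residues around each ligand terminus,
improve the prediction of natural ligands.

## The model

The predictor is a shallow feed-forward network with one logistic hidden
layer and **two logistic output neurons**, one per data type. The
input-to-hidden weights are shared between the data types; each output head
owns its hidden-to-output weights. Training on one instance touches the
shared weights and the matching head only, so information transfers between
the data types through the shared representation while their output scales
stay calibrated separately.

Because the groove-bound core is not annotated in the data, every training
step first *aligns* the peptide: the forward pass is evaluated at every
9mer window and the arg-max window (ties to the smallest offset) is taken
as the current core. One online gradient step on the squared error of the
matching head is then back-propagated through the encoding of that window.
During the first training iteration (the *burn-in*), the search is
restricted to windows whose P1 residue is hydrophobic (default set
F, I, L, M, V, W, Y, A), reflecting the conserved hydrophobic P1 pocket;
if a peptide has no such window, all of its windows are admitted rather
than silently dropping the peptide. From the second iteration on, all
offsets compete.

An *iteration* performs N stochastic updates (N = training-set size). With
both data types present, each update first draws the data type uniformly at
random, then an instance uniformly within that type — so both types
contribute the same expected number of updates per iteration regardless of
their sizes (EL sets are an order of magnitude larger than BA sets once
random negatives are added).

### Input encoding

Each candidate core window is encoded as:

* **Core block** (9 × 20): BLOSUM50 row of each core residue, divided
  by 5. The wildcard `X` encodes as the zero vector.
* **PFR features** (2 × 21): mean encoded composition of the up-to-3 flank
  residues adjacent to the core on each side, plus the flank length as
  min(len, 3)/3.
* **Length bins** (9): one-hot over lengths 11–19. Prediction-time
  peptides outside that range (the epitope benchmark scores 13–21mers) map
  to the nearest bin; at the R API level this logs a warning.
* **Context block** (12 × 20, optional): the 3 upstream source-protein
  residues, the 3 N-terminal peptide residues, the 3 downstream protein
  residues and the 3 C-terminal peptide residues. BA instances carry an
  all-zero context block (wildcard `XXX`), since their source protein is
  unknown. This block is independent of the core offset.

The residue encoding, its scale, and the PFR feature set are package
design choices (config-overridable in `encoder_config()`): the BLOSUM50/5
convention follows the alignment-network lineage this package builds on.

### Training hyper-parameters

| parameter | default | notes |
|---|---|---|
| hidden units | 2, 10, 20, 40, 60 | one ensemble member per size |
| seeds | 10 | weight init and draw order |
| folds | 5 | common-motif partitions |
| iterations | 400 | no early stopping |
| burn-in iterations | 1 | hydrophobic-P1 restriction |
| learning rate | 0.05 | online SGD, squared error |
| initial weights | ±0.1 uniform | |

The full conventional ensemble is therefore 10 × 5 × 5 = 250 networks;
`predict_ensemble()` averages member predictions (each member at its own
selected core) and reports the core of the maximal-scoring member — a
mode-like choice, since averaging offsets is meaningless. The activation,
loss, learning rate and initialisation are not dictated by the modelling
problem; they are exposed in `network_config()` and the defaults were
chosen once as ordinary values for online logistic networks.

### Data preparation

* **BA targets**: measured IC50 (nM) map to `1 − log(IC50)/log(50000)`,
  clamped to [0, 1] (`ba_transform()`).
* **Random negatives** (`sample_negatives()`): for each length 11–19 the
  same count — five times the most represented positive length — of random
  proteome subsequences, labelled 0. With context mode on they carry their
  true flanking residues, padded with `X` at protein boundaries.
* **Partitioning** (`common_motif_partition()`): single-linkage clusters
  where two peptides link iff they share an identical 9mer; clusters are
  assigned largest-first to the currently smallest partition. After
  assignment no 9mer occurs in two partitions, which is the leakage
  guarantee the evaluation relies on. Cluster ordering and tie-breaks are
  deterministic (descending size, then smallest member index).

## Processing footprints

`annotate_pfr()` derives both PFR lengths from each ligand's core offset —
in analysis runs, the out-of-fold core selected by the EL head of the
cross-validated model, so that the footprint statistics are not inflated by
training-set memorisation. `terminal_matrix()` then pools, per terminus,
the three terminal ligand residues and the three adjacent source-protein
context residues of every ligand whose PFR on that side is at least 3
(shorter PFRs sit against the MHC, which shields them from the trimming
proteases, so they cannot carry a cleavage signal). The result is a
6 × 20 table of counts, frequencies, and log2 odds against the background
composition of the ligands' source proteins. Two such matrices are compared
by the Pearson correlation of their flattened 120-vectors
(`matrix_pcc()`).

Numerical choices: counts receive an add-one pseudocount before the
log-odds (the frequencies field stays raw, so a forced residue reads as
frequency 1); `X` padding is excluded from counts rather than dropping the
ligand; a ligand occurring several times in its protein takes its first
occurrence's context. Whether the correlation is taken on log-odds or raw
frequencies is genuinely open; log-odds is the default and both are
exposed (`space =`). Frequency-space correlations run noticeably higher
because the log transform amplifies sampling noise in rare cells.

`pcc_permutation_test()` offers two distinct nulls, because two distinct
questions arise. Shuffling ligand-set *membership labels* (`null =
"labels"`) tests whether two sets carry different signals; it is uniform
under exchangeability and is the calibration property the test suite
checks. Permuting the 120 *entries* of one flattened matrix (`null =
"entries"`) tests whether an observed correlation differs from no
correlation at all — the right null when asking whether two data sets share
a common processing signal, and the one used in the acceptance run. With a
signal present in both sets, membership shuffling cannot detect it (both
permuted halves inherit it), which is why the two nulls must not be
conflated.

## Epitope benchmarks

Two protocols are implemented over a source protein and one epitope of
length 14–19:

1. **Direct** (`epitope_auc_direct()`): all windows of the epitope's
   length are scored by the EL head; windows identical to the epitope are
   positives; negatives exclude windows sharing a 9mer with the epitope.
2. **Ligand preference** (`epitope_auc_ligand_preference()`): every
   13–21mer window is scored first, and each epitope-length window
   receives the *mean* score of the 13–21mers overlapping it by at least
   nine positions before the same AUC is computed. Mean (not max)
   aggregation is used: the max variant consistently scores worse. This
   protocol rewards windows covered by strong natural-ligand candidates
   instead of requiring the epitope's own termini to look processed —
   epitope boundaries come from synthetic peptide screens, not from
   processing.

The 9mer-sharing exclusion applies to negatives only; the positive window
is always scored. Sharing is substring identity for the exclusion rule and
positional overlap for the aggregation rule.

## Metrics

`auc()` is the Mann–Whitney probability of correct ranking (ties one
half); `auc01()` integrates the ROC to a false-positive rate of 0.1 and
divides by 0.1, so a perfect classifier scores 1 and an uninformative one
0.05 — the normalisation is forced by the convention that a model with AUC
≈ 0.99 reports AUC 0.1 ≈ 0.92; `ppv()` is the fraction of true positives
among the top-N predictions with N the number of positives, the metric of
choice for the ~10:1 unbalanced elution sets. Ties in `ppv()` break by
stable input order.

## The synthetic world

`make_world()` fixes the ground truth the whole pipeline is validated
against:

* a 9 × 20 core PSSM whose anchor columns (P1/P4/P6/P9) put 88% of their
  mass on 2 residues (P1 anchors drawn from the hydrophobic set, as in
  real grooves; anchor information ≈ 2.4 bits) while non-anchor columns
  jitter around the background (< 0.2 bits);
* a unimodal length law over 11–19 with mode 15
  (0.02, 0.06, 0.12, 0.20, 0.24, 0.18, 0.10, 0.05, 0.03);
* a terminal cleavage signal: proline at the second residue from either
  terminus with probability `cleavage_prob` (default 0.4) whenever that
  side's PFR is ≥ 3, planted symmetrically at both termini;
* source proteins that physically embed every ligand, so negatives and
  context lookups come from a real (if synthetic) proteome. Defaults are
  500 proteins × 3000 residues: ligands then occupy ~2% of proteome
  residues, keeping accidental motif content in the sampled negatives
  negligible — an early smaller default made ligands a quarter of the
  proteome and contaminated a fifth of the negatives with true motif
  cores, which no real negative set resembles;
* BA peptides: random background peptides, half with a planted PSSM core,
  whose targets are a logistic transform of the best-window log-odds score
  plus clamped Gaussian noise (sd 0.05).

What the generator does **not** emulate: mass-spectrometry detectability
biases (notably cysteine depletion, a known technological artifact of real
elution data), multi-allele deconvolution (inputs are assumed
pre-deconvoluted), post-translational modifications, and any correlation
structure between neighbouring ligands in a protein. A green test suite
therefore demonstrates that the machinery recovers the structure this
generator plants — not that it reaches any particular performance on real
immunopeptidomes.

## Problem sizes used by the tests and the acceptance script

The shipped validation runs are scaled to a single CPU:

* Combined-model run: the default world (2000 ligands, 1000 BA peptides,
  ~22000 negatives), ensemble 2 seeds × hidden {2, 10} × 5 folds, 50
  iterations. Synthetic motifs are far cleaner than real elution data;
  out-of-fold performance plateaus well before the 400-iteration default,
  which remains the package default for real-scale use.
* Context-benefit runs: five replicate worlds per condition
  (`cleavage_prob` 0.5 vs 0), paired context-on/off cross-validations on
  identical folds, 2 seeds × hidden 10, 15 iterations. The combined
  BA + EL setting is used deliberately: BA instances carry a zero context
  block, and balanced mixing regularises the shared layer against
  exploiting context noise. At much smaller data scales the 240 extra
  context inputs overfit and context-off wins even with a planted signal —
  an artifact of scale, visible as a train/test gap, not a property of the
  method. A small residual no-signal penalty (≈ 0.02 AUC 0.1) remains at
  the shipped scale.
* Footprint runs: two independent 1000-ligand worlds. With the default
  single-position proline signal, the replicate log-odds correlation has a
  noise ceiling near 0.66 (one strong element among 120, multinomial
  noise from ~520 filter-surviving ligands per set); the corresponding
  frequency-space correlation is ≈ 0.9. See `matrix_pcc(space =)`.

## Known limitations

* Single-allele only: no pan-specific (multi-MHC) modelling, and no
  unsupervised deconvolution of mixed-allele elution sets.
* The CLI and file formats assume peptide lists small enough to hold in
  memory.
* The permutation test recomputes matrices per label permutation in R; for
  very large annotation sets prefer `null = "entries"`, which permutes a
  fixed 120-vector.
* Serialized models store dense weight matrices as JSON text: exact and
  portable, but large ensembles produce multi-megabyte files.
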