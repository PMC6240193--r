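# mhc2lig

Joint modelling of MHC class II binding affinity and mass-spectrometry
eluted ligands, with antigen-processing context.

## What this package is for

MHC class II molecules present exogenous peptide fragments to CD4+ T
cells. Their open-ended groove binds a nine-residue core (anchors P1, P4,
P6, P9) while the ligand's remaining residues protrude as peptide flanking
regions (PFRs), so naturally eluted ligands vary in length (11–19, peaking
near 14–16) and carry proteolytic trimming signals at their termini —
most prominently a proline enrichment at the second residue from either
end. `mhc2lig` is for immunoinformaticians who want to:

* train a single model on both data types — continuous binding-affinity
  targets (BA) and 1/0 eluted-ligand labels (EL) — with a two-output
  shallow network whose input→hidden weights are shared,
  `sigmoid` hidden and output layers, and per-type output heads;
* align the unobserved binding core during training (arg-max over 9mer
  windows, hydrophobic-P1 burn-in on the first iteration);
* encode each ligand's ±3-residue source-protein *context* and its
  terminal residues, and measure whether processing signals improve
  natural-ligand prediction;
* extract and compare 6×20 terminal processing matrices
  (3 context + 3 terminal residues, PFR ≥ 3), as count, frequency and
  log2-odds tables, with Pearson-correlation comparison and exact
  permutation tests;
* benchmark with the field's metrics (AUC; AUC 0.1 = ROC area to FPR 0.1,
  normalised; PPV on the top-N) and two per-protein T cell epitope
  protocols;
* generate fully synthetic ground-truth data (motif, length law, cleavage
  signal, embedding proteome) so every stage is testable end to end
  without external downloads.

Training follows the class II alignment-network recipe: random negatives
added per length (5× the modal positive length count), 5-fold
cross-validation on common-motif partitions (no 9mer shared across
folds), balanced stochastic mixing of the two data types, ensembles over
seeds × hidden sizes × folds (conventionally 10 × {2,10,20,40,60} × 5 =
250 networks, 400 iterations, no early stopping).

## A worked example

```r
library(mhc2lig)

# a synthetic immunopeptidome with known ground truth
w  <- make_world(n_ligands = 500, n_ba = 250, cleavage_prob = 0.4,
                 seed = 7)
ts <- synthetic_training_set(w, context_mode = TRUE)   # +negatives, folds

cfg <- run_config(seeds = 1:2, hidden_sizes = c(2L, 10L),
                  iterations = 30L, context_mode = TRUE)
cv  <- cross_validate(ts$data, cfg)                    # 20 networks

el <- cv$predictions[cv$predictions$data_type == "EL", ]
round(c(auc   = auc(el$el_score, el$target),
        auc01 = auc01(el$el_score, el$target),
        ppv   = ppv(el$el_score, el$target)), 3)
#>   auc auc01   ppv
#> 0.957 0.777 0.748

# how often the out-of-fold core lands exactly on the planted core
pos <- cv$predictions$target == 1 & cv$predictions$data_type == "EL"
mean(cv$predictions$core_offset[pos] == ts$ligands$true_offset)
#> [1] 0.802

# terminal processing footprint from the out-of-fold cores
ann <- annotate_pfr(ts$ligands[, 1:6], cv$predictions$core_offset[pos],
                    ts$proteins)
up  <- terminal_matrix(ann, "upstream", ts$proteins)
round(up$log_odds[5, "P"], 2)   # planted proline, 2nd residue from N term
#> [1] 2.84
```

The AUC 0.1 of 0.78 says the model recovers ~78% of the achievable
perfect-classifier area in the high-specificity regime that matters for
the ~10:1 negative-enriched elution sets; the 0.80 core recovery says the
alignment found the planted groove register for four ligands in five, and
the 2.8-bit log-odds is the recovered cleavage signal (log2 of the ~0.36
observed proline frequency over the ~0.05 background). Numbers vary
slightly with the seed, and improve at larger data scales.

A thin command-line wrapper ships in `exec/mhc2lig` with subcommands
`simulate`, `train`, `predict`, `evaluate`, `footprint`:

```sh
Rscript exec/mhc2lig simulate --n-ligands 500 --seed 7 --out sim/
Rscript exec/mhc2lig train --ligands sim/ligands.tsv --ba sim/ba.tsv \
        --proteins sim/proteins.fasta --iterations 30 --out model/
Rscript exec/mhc2lig predict --model model/model.json \
        --peptides sim/ligands.tsv --out scores.tsv
```

## Package layout

| where | what |
|---|---|
| `R/seqcodec.R` | alphabet, BLOSUM encoding, instance/feature encoding |
| `R/netcore.R` | two-output network, core alignment, ensembles, JSON models |
| `R/trainer.R` | negatives, common-motif partitioning, CV orchestration |
| `R/evalx.R` | AUC / AUC 0.1 / PPV, overlap filtering, epitope protocols |
| `R/procfoot.R` | PFR annotation, processing matrices, KL logos, PCC tests |
| `R/synthgen.R` | ground-truth generator |
| `R/io.R` | peptide tables, FASTA, manifests |
| `src/` | Rcpp training/prediction kernels |
| `vignettes/` | methods vignette (model, assumptions, design choices) |
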