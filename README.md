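# ppiface

Residue-level prediction of protein–protein interfaces with a recurrent
graph neural network.

When protein chains associate into a complex, the residues whose
solvation energy changes between the dissociated and associated forms
constitute the binding interface.  `ppiface` treats finding them as
node-focused binary classification on a residue graph:

* **Nodes** are residues (one per C-alpha) carrying an 89-dimensional
  feature vector — 3D position, an 8-class secondary-structure one-hot,
  backbone geometry (ASA, phi, psi, relative ASA), the 7-dimensional
  Meiler embedding, 47 per-residue property scales, and the residue
  one-hot.
* **Edges** carry the C-alpha distance and ten bond-type channels
  (peptide, disulfide, hydrogen, ionic, aromatic, aromatic–sulphur,
  cation–pi, hydrophobic, van der Waals, other-covalent); all atom-level
  bonds between two residues are condensed onto one undirected edge as
  per-type counts.
* **The model** iterates a learned state-transition MLP over node
  neighbourhoods,

  x_n(t) = Σ_{m ∈ ne(n)} f_w(l_n, l_m, e_{n,m}, x_m(t−1)),  x(0) = 0,

  for a fixed number of iterations, then reads each node state with an
  output MLP through a sigmoid: p_n = σ(g_w(x_n(T), l_n)).  Training is
  class-weighted cross-entropy (positive weight
  (1 − wbal) + wbal·N_neg/N_pos) with Adam, early stopping on
  validation F-score, and full grid search over state dimension,
  iterations, wbal and hidden sizes.

The package is written for structural bioinformaticians who want to
train and dissect such models without a deep-learning framework: the
forward pass, backprop-through-time and Adam are implemented directly on
BLAS matrix operations and verified against finite differences.

It covers the full pipeline: PDB/mmCIF parsing (`parse_structure`),
secondary structure (`assign_secondary_structure`), bond detection
(`detect_bonds`), graph building (`build_graph`), PISA-style
solvation-energy labels (`parse_pisa_records`, `label_from_solvation`)
with a geometric fallback (`geometric_labeler`), the Whole / Interface /
Chain dataset views (`make_whole`, `enumerate_chain_pairs`,
`make_chains`, `split_dataset`), training and evaluation (`gnn_train`,
`evaluate_model`, `grid_search`), the six standard metrics
(`compute_metrics`), feature-group ablation (`run_ablation`), and a
synthetic complex generator with planted interfaces (`generate_corpus`)
so everything is testable without downloads.  A command-line wrapper
(`exec/ppiface`) exposes `simulate`, `build`, `train`, `evaluate`,
`predict` and `ablate` subcommands.

## Worked example

Generate a small synthetic corpus, train on the Whole-protein view, and
evaluate on held-out complexes:

```r
library(ppiface)

spec <- synthetic_spec(seed = 42, residues_per_chain = c(30, 40))
corpus <- generate_corpus(12, spec)
corpus
#> synthetic_corpus: 12 complexes, 831 residues, 18.8% interface

samples <- corpus_samples(corpus, "whole")
split <- split_dataset(vapply(corpus, `[[`, character(1), "protein_id"),
                       c(0.7, 0.15, 0.15), seed = 42)
pid <- vapply(samples, function(s) s$provenance$protein_id, character(1))

cfg <- gnn_config(state_dim = 16L, max_iter = 5L, wbal = 1,
                  net_s_hidden = 256L, net_o_hidden = 256L,
                  epochs = 15L, early_stopping_patience = 5L, seed = 42L)
fit <- gnn_train(samples[split[pid] == "train"],
                 samples[split[pid] == "validation"], cfg)
fit$history
#> training_history: 12 epochs, best epoch 7 (val F 0.9333) [stopped early]

evaluate_model(fit$model, samples[split[pid] == "test"])
#> Acc       BAcc      Precision Recall    FScore    AUC
#> 0.9856    0.9913    0.9231    1.0000    0.9600    0.9996
```

The corpus plants a label-correlated signal on hydrophobicity- and
ASA-like feature channels (strength 0.8 by default), so a correctly
implemented model separates the ~19% interface residues almost
perfectly; with `feature_signal = 0` the same run stays at chance-level
AUC.  Per-residue output:

```r
head(gnn_predict(fit$model, samples[[which(split[pid] == "test")[1]]]$graph), 4)
#>   chain resno ins probability call
#> 1     A     1     0.020126303    0
#> 2     A     2     0.037256205    0
#> 3     A     3     0.121621224    0
#> 4     A     4     0.006320941    0
```

`call` is 1 when the probability reaches the 0.5 threshold; with ground
truth supplied, `cli_predict` adds each residue's TP/TN/FP/FN class.

## Layout

```
R/                  implementation (parsing, features, labels, datasets,
                    GNN, metrics, ablation, synthetic generator, CLI)
exec/ppiface        command-line dispatcher
tests/testthat/     unit, property and end-to-end suites
scripts/acceptance.R  headline-quantity reproduction
vignettes/interface-gnn.Rmd  methods notes: model, assumptions, choices
```
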