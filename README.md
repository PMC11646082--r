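# psetf — tensor-factorization link prediction for polypharmacy side effects

Adverse reactions caused by *pairs* of co-prescribed drugs (polypharmacy
side effects, PSEs) cannot be screened exhaustively in the lab: the space
of drug combinations is too large.  `psetf` treats the problem as
multirelational link prediction over a drug/gene knowledge graph — one
relation per side-effect type, plus drug–target and protein–protein
edges — and factorizes the graph's triple tensor with three classical
scorers:

| model | score of (vᵢ, r, vⱼ) | head–tail behaviour |
|---|---|---|
| DistMult | ⟨eᵢ, w_r, eⱼ⟩ = Σₖ e_{ik} w_{rk} e_{jk} | always symmetric |
| ComplEx | Re ⟨eᵢ, w_r, ēⱼ⟩ (complex factors) | antisymmetry possible |
| SimplE | ½(⟨hᵢ, v_r, tⱼ⟩ + ⟨hⱼ, v_{r⁻¹}, tᵢ⟩) | learned via inverse relations |

A sigmoid of the score gives the probability that the triple is true.
The package is aimed at researchers studying PSE prediction methods: it
provides the full experimental loop — graph construction in two variants
(monopharmacy data as **self-loop edges** vs as **PCA-reduced n-hot
feature initialization**), a shared per-side-effect 10% holdout, 1vsAll /
KvsAll mini-batch training with KL / BCE losses, five optimizers, plateau
learning-rate decay and two-strikes early stopping, a 50-Sobol +
50-Bayesian hyperparameter search, per-side-effect AUROC / AUPRC / AP@50
evaluation with matched negative sampling, and a per-epoch training-curve
analysis — plus a synthetic-data generator that plants low-rank trilinear
structure in miniature raw tables so everything is testable without any
download.

## Worked example

Generate a small planted dataset, build the self-loop graph, hold out 10%
of each side effect, train SimplE and evaluate per side effect:

```r
library(psetf)

spec <- synthetic_spec(n_drugs = 60, n_genes = 20, n_pse_types = 8,
                       n_mono_types = 12, latent_rank = 4, pse_density = 0.08,
                       seed = 42)
raw <- synthesize_raw_tables(make_planted_model(spec), spec)
raw
#> raw_tables: 1122 pair side-effect records ( 8 types ), 108 monopharmacy records,
#>   24 drug-target records, 10 protein-interaction records

graph <- build_selfloops(raw)
graph
#> triple_graph: 75 entities ( 60 drugs, 15 genes ), 21 relations, 1264 triples

split <- split_pse_holdout(graph, fraction = 0.1, seed = 1)
split
#> holdout_split: 110 held-out / 1154 training triples (fraction 0.1 , seed 1 )

dataset <- training_dataset(graph, split, seed = 2)
fit <- run_training(dataset,
                    model_config("simple", m = 16),
                    train_config(max_epochs = 15, eval_start = 5,
                                 eval_every = 5, seed = 3))
fit$history
#> train_history: 16 epochs, 3 checks, best metric 0.3075 at epoch 5, stop: early-stop

pairs <- sample_eval_negatives(graph, split, seed = 4)
evaluate_side_effects(fit$best$params, pairs)
#> eval_report over 8 side-effect relations
#>   median AUROC 0.9010 | AUPRC 0.9172 | AP@50 0.9172
```

The history line says validation filtered MRR peaked at epoch 5 and two
consecutive non-improving checks then stopped the run.  The report gives
median classification quality across the 8 side-effect relations on the
held-out pairs, each positive matched by a sampled non-edge negative: the
model recovers the planted pair structure (AUROC 0.90) after a few
seconds of training.  `run_experiment()` repeats this for every
model × graph-variant cell with one shared holdout and returns the
combined median table; `per_epoch_curve()` evaluates per-epoch snapshots
to show how quickly performance saturates.

## Package layout

- `R/synthetic_data.R` — planted-factor generator and the four raw tables
- `R/graph_build.R` — parsers, the two graph variants, PCA feature
  reduction, on-disk triple datasets
- `R/holdout_split.R` — per-side-effect holdout, negative sampling,
  permutation null
- `R/tf_models.R` — the three scorers, initialization schemes, checkpoints
- `R/training.R` — query construction, losses, optimizers, early stopping
- `R/hpo.R` — Sobol sequence, Gaussian-process surrogate, search driver
- `R/evaluation.R` — filtered MRR / hits@k, AUROC / AUPRC / AP@50 reports
- `R/experiment.R` — six-cell orchestration and per-epoch curves
- `inst/cli/psetf.R` — thin command-line dispatcher over the above
- `vignettes/tensor-factorization-pse.Rmd` — the methods vignette
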