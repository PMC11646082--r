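# Shared fixtures and independent oracles for the test suite.

# A small planted dataset (50 drugs, 6 side-effect types, rank 4) used by
# tests that need a realistic but fast graph.
small_spec <- function(seed = 3L, noise_sd = 0.5, latent_rank = 4L)
  synthetic_spec(n_drugs = 50L, n_genes = 15L, n_pse_types = 6L,
                 n_mono_types = 10L, latent_rank = latent_rank,
                 pse_density = 0.1, mono_rate = 0.15, target_rate = 0.05,
                 ppi_rate = 0.1, noise_sd = noise_sd, seed = seed)

small_graph_cache <- new.env(parent = emptyenv())

small_graph <- function(seed = 3L) {
  key <- paste0("g", seed)
  if (is.null(small_graph_cache[[key]])) {
    spec <- small_spec(seed)
    raw <- synthesize_raw_tables(make_planted_model(spec), spec)
    small_graph_cache[[key]] <- list(
      spec = spec, raw = raw, graph = build_selfloops(raw))
  }
  small_graph_cache[[key]]
}

# --- independent metric oracles ---------------------------------------------

# AUROC by exhaustive positive-negative pair counting (ties count half).
auroc_pair_oracle <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  conc <- 0
  for (p in ps) conc <- conc + sum(p > ns) + 0.5 * sum(p == ns)
  conc / (length(ps) * length(ns))
}

# Average precision by stepwise scan over descending thresholds, ties
# grouped; written independently of the package implementation.
auprc_step_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0; ap <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Filtered ranking by explicit sort-and-scan for a single triple/direction.
rank_oracle <- function(params, s, r, o, filter_triples, direction) {
  n <- params$n_entities
  if (direction == "tail") {
    sc <- vapply(seq_len(n), function(k)
      score_triples(params, cbind(s, r, k)), double(1L))
    true <- o
    known <- filter_triples[filter_triples[, 1L] == s &
                              filter_triples[, 2L] == r, 3L]
  } else {
    sc <- vapply(seq_len(n), function(k)
      score_triples(params, cbind(k, r, o)), double(1L))
    true <- s
    known <- filter_triples[filter_triples[, 3L] == o &
                              filter_triples[, 2L] == r, 1L]
  }
  sc[setdiff(known, true)] <- -Inf
  1 + sum(sc > sc[true]) + (sum(sc == sc[true]) - 1) / 2
}

# Build model_params that score with the planted factors directly
# (DistMult layout: drug rows = drug factors, PSE relation rows = type
# factors), for evaluating the generator against its own ground truth.
params_from_planted <- function(planted, graph) {
  k <- ncol(planted$drug_factors)
  n <- nrow(graph$entities)
  R <- nrow(graph$relations)
  E <- matrix(0, n, k)
  drugs <- which(graph$entities$type == "Drug")
  # synthetic drug ids sort in numeric order, so row i is drug i
  E[drugs, ] <- planted$drug_factors
  W <- matrix(0, R, k)
  pse <- which(graph$relations$role == "PSE")
  W[pse, ] <- planted$pse_factors
  structure(list(model = "distmult", m = k,
                 config = model_config("distmult", m = k),
                 n_entities = n, n_relations = R,
                 mats = list(E = E, W = W)),
            class = "model_params")
}

# --- shared heavy fixture: planted-structure recovery runs ------------------
# One SimplE recovery run (with per-epoch snapshots) plus its permutation
# null per seed, on the study-scale generator defaults (200 drugs, 30 pair
# side-effect types, rank 8, noise 0.5).  Cached so several tests can share
# the same three runs.

recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function(s) {
  key <- paste0("seed", s)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  spec <- synthetic_spec(seed = 100L + s)
  raw <- synthesize_raw_tables(make_planted_model(spec), spec)
  g <- build_selfloops(raw)
  split <- split_pse_holdout(g, 0.1, seed = 200L + s)
  lab <- sample_eval_negatives(g, split, seed = 300L + s)
  mc <- model_config("simple", m = 16L)
  tc <- train_config(optimizer = "adam", lr = 0.011, batch_size = 256L,
                     max_epochs = 15L, eval_start = 5L, eval_every = 5L,
                     seed = 400L + s, checkpoint_every_epoch = TRUE)
  ds <- training_dataset(g, split, seed = 500L + s)
  fit <- run_training(ds, mc, tc)
  report <- evaluate_side_effects(fit$best$params, lab)
  curve <- per_epoch_curve(fit$epoch_params, lab)
  ds0 <- null_control_dataset(g, split, seed = 600L + s,
                              valid_seed = 500L + s)
  tc0 <- tc
  tc0$checkpoint_every_epoch <- FALSE
  fit0 <- run_training(ds0, mc, tc0)
  control <- evaluate_side_effects(fit0$best$params, lab)
  out <- list(report = report, control = control, curve = curve,
              history = fit$history)
  recovery_cache[[key]] <- out
  out
}

# Discretized mutual information between two integer vectors.
mutual_information <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  mi
}
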