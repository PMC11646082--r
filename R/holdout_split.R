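# Per-side-effect holdout of drug-pair edges, shared across graph variants,
# plus matched negative pairs for classification metrics.

#' Destroy cross-relation structure by permuting drug labels per relation
#'
#' Applies an independent random permutation of the drug identities to
#' the edges of every pair-side-effect relation.  Within-relation degree
#' structure is preserved but the assignments become mutually
#' inconsistent across relations, so shared entity embeddings can no
#' longer explain the data: a negative control for recovery experiments
#' (held-out AUROC should drop to chance).
#'
#' @param graph A `triple_graph`.
#' @param seed Integer seed.
#' @return A `triple_graph` with permuted PSE triples.
#' @export
permute_pse_drug_labels <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "triple_graph"))
  drug_idx <- which(graph$entities$type == "Drug")
  triples <- graph$triples
  for (r in which(graph$relations$role == "PSE")) {
    rows <- which(triples[, 2L] == r)
    if (!length(rows)) next
    perm <- stats::setNames(
      drug_idx[with_seed(derive_seed(seed, 3000L + r),
                         sample.int(length(drug_idx)))],
      drug_idx)
    s <- perm[as.character(triples[rows, 1L])]
    o <- perm[as.character(triples[rows, 3L])]
    triples[rows, 1L] <- pmin(s, o)
    triples[rows, 3L] <- pmax(s, o)
  }
  new_triple_graph(graph$entities, graph$relations, triples)
}

triple_key <- function(tr) paste(tr[, 1L], tr[, 2L], tr[, 3L], sep = ":")

#' Hold out a fraction of edges from every pair-side-effect relation
#'
#' Removes `floor(fraction * n_r)` edges, sampled uniformly, from each
#' pair side-effect (PSE) relation `r`; non-PSE triples (mono self-loops,
#' targets, protein interactions) are never held out.  Within each
#' relation the candidate triples are put in canonical (subject, object)
#' order before sampling and the RNG is re-seeded per relation from
#' (`seed`, relation id), so the selected edges depend only on the PSE
#' triple set.  Since both graph variants share that set and its entity
#' indexing, applying this function to either variant selects the same
#' edges, enabling a fair comparison between them.
#'
#' @param graph A `triple_graph` with at least one PSE relation.
#' @param fraction Fraction to hold out, in (0,1); default 0.1.
#' @param seed Integer seed.
#' @return A `holdout_split`: list with `train` and `holdout` triple
#'   matrices, `per_relation` summary data frame, `fraction`, `seed`.
#' @export
split_pse_holdout <- function(graph, fraction = 0.1, seed = 1L) {
  stopifnot(inherits(graph, "triple_graph"))
  fraction <- check_fraction(fraction, "fraction")
  pse_rels <- which(graph$relations$role == "PSE")
  if (length(pse_rels) == 0L)
    stop("graph contains no PSE relation", call. = FALSE)

  hold_rows <- integer(0)
  per_rel <- vector("list", length(pse_rels))
  for (k in seq_along(pse_rels)) {
    r <- pse_rels[k]
    rows <- which(graph$triples[, 2L] == r)
    ord <- order(graph$triples[rows, 1L], graph$triples[rows, 3L])
    rows <- rows[ord]
    n_r <- length(rows)
    n_hold <- floor(fraction * n_r)
    if (n_hold == 0L) {
      warning(sprintf("relation '%s' has only %d edge(s); none held out",
                      graph$relations$id[r], n_r), call. = FALSE)
    } else {
      sel <- with_seed(derive_seed(seed, r), sample.int(n_r, n_hold))
      hold_rows <- c(hold_rows, rows[sel])
    }
    per_rel[[k]] <- data.frame(relation = graph$relations$id[r],
                               n = n_r, n_holdout = n_hold,
                               stringsAsFactors = FALSE)
  }
  holdout <- graph$triples[hold_rows, , drop = FALSE]
  train <- graph$triples[setdiff(seq_len(nrow(graph$triples)), hold_rows), ,
                         drop = FALSE]
  structure(list(train = train, holdout = holdout,
                 per_relation = do.call(rbind, per_rel),
                 fraction = fraction, seed = as.integer(seed)),
            class = "holdout_split")
}

#' @export
print.holdout_split <- function(x, ...) {
  cat("holdout_split:", nrow(x$holdout), "held-out /", nrow(x$train),
      "training triples (fraction", x$fraction, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Build the permutation-null training dataset for a recovery experiment
#'
#' Applies [permute_pse_drug_labels()] to the training portion of a
#' holdout split while leaving the held-out evaluation edges untouched,
#' then carves the validation split from the permuted training triples.
#' Training on this dataset severs the link between what the model can
#' learn and what it is evaluated on, so held-out AUROC should be at
#' chance (about 0.5); this is the negative control matching a
#' successful recovery run.
#'
#' @param graph The original `triple_graph`.
#' @param split A [split_pse_holdout()] result for `graph`.
#' @param seed Integer permutation seed.
#' @param valid_fraction,valid_seed Passed to [training_dataset()].
#' @return A dataset list as produced by [training_dataset()].
#' @export
null_control_dataset <- function(graph, split, seed = 1L,
                                 valid_fraction = 0.05, valid_seed = 2L) {
  g_train <- new_triple_graph(graph$entities, graph$relations, split$train)
  g_perm <- permute_pse_drug_labels(g_train, seed = seed)
  split_perm <- split
  split_perm$train <- g_perm$triples
  training_dataset(graph, split_perm, valid_fraction = valid_fraction,
                   seed = valid_seed)
}

#' Sample matched negative drug pairs for held-out edges
#'
#' For each PSE relation with held-out positives, rejection-samples the
#' same number of unordered drug--drug pairs that occur nowhere in the
#' full graph (train or holdout) under that relation; self-pairs are
#' excluded.  Together with the positives these form the labelled pairs
#' on which per-side-effect AUROC/AUPRC/AP@50 are computed.
#'
#' @param graph The full `triple_graph` the split was computed from.
#' @param split A [split_pse_holdout()] result.
#' @param seed Integer seed; sampling is deterministic given it.
#' @return A `labeled_pairs` object: per relation a data frame with
#'   columns `a`, `b` (entity indices) and `label` (1 positive / 0
#'   negative).
#' @export
sample_eval_negatives <- function(graph, split, seed = 1L) {
  stopifnot(inherits(graph, "triple_graph"), inherits(split, "holdout_split"))
  drug_idx <- which(graph$entities$type == "Drug")
  n_drugs <- length(drug_idx)
  out <- list()
  rels <- sort(unique(split$holdout[, 2L]))
  for (r in rels) {
    pos <- split$holdout[split$holdout[, 2L] == r, , drop = FALSE]
    n_pos <- nrow(pos)
    all_r <- rbind(split$train[split$train[, 2L] == r, , drop = FALSE], pos)
    cp <- canonical_pairs(all_r[, 1L], all_r[, 3L])
    edge_keys <- paste(cp$a, cp$b)
    n_possible <- n_drugs * (n_drugs - 1) / 2 - length(unique(edge_keys))
    if (n_possible < n_pos)
      stop(sprintf("relation '%s': only %d non-edges available for %d positives",
                   graph$relations$id[r], n_possible, n_pos), call. = FALSE)
    neg <- with_seed(derive_seed(seed, 1000L + r), {
      seen <- character(0)
      acc_a <- integer(0); acc_b <- integer(0)
      while (length(acc_a) < n_pos) {
        need <- n_pos - length(acc_a)
        i <- drug_idx[sample.int(n_drugs, 2L * need + 8L, replace = TRUE)]
        j <- drug_idx[sample.int(n_drugs, 2L * need + 8L, replace = TRUE)]
        ok <- i != j
        a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
        key <- paste(a, b)
        keep <- !(key %in% edge_keys) & !(key %in% seen) & !duplicated(key)
        a <- a[keep][seq_len(min(need, sum(keep)))]
        b <- b[keep][seq_len(min(need, sum(keep)))]
        seen <- c(seen, paste(a, b))
        acc_a <- c(acc_a, a); acc_b <- c(acc_b, b)
      }
      list(a = acc_a, b = acc_b)
    })
    pcp <- canonical_pairs(pos[, 1L], pos[, 3L])
    out[[graph$relations$id[r]]] <- data.frame(
      a = c(pcp$a, neg$a), b = c(pcp$b, neg$b),
      label = rep(c(1L, 0L), c(n_pos, n_pos)))
  }
  structure(out, class = "labeled_pairs", seed = as.integer(seed),
            relation_index = stats::setNames(rels, graph$relations$id[rels]))
}
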