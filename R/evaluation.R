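# Ranking metrics for model selection (filtered MRR / hits@k) and the
# per-side-effect classification metrics (AUROC, AUPRC, AP@50).

#' Filtered mean reciprocal rank and hits@k
#'
#' For every evaluation triple the true entity is ranked among all
#' candidates in both directions (tail and head).  Candidates that form
#' other known-true triples under the filter set are removed before
#' ranking; ties take the mean rank over the tied block, so the result
#' is invariant to candidate order.
#'
#' @param params A `model_params`.
#' @param eval_triples Integer (s, r, o) matrix to rank.
#' @param filter_triples Known-true triples (must contain
#'   `eval_triples`); typically train + valid (+ test).
#' @param k_list Cutoffs for hits@k.
#' @return List with `mrr` and named `hits` vector.
#' @export
rank_metrics <- function(params, eval_triples, filter_triples,
                         k_list = c(1L, 3L, 10L)) {
  if (nrow(eval_triples) == 0L) stop("no evaluation triples", call. = FALSE)
  fkey <- triple_key(filter_triples)
  if (!all(triple_key(eval_triples) %in% fkey))
    stop("filter set must contain the evaluation triples", call. = FALSE)
  # known-true answer lists per (entity, relation, direction)
  tails <- split(filter_triples[, 3L],
                 paste(filter_triples[, 1L], filter_triples[, 2L]))
  heads <- split(filter_triples[, 1L],
                 paste(filter_triples[, 3L], filter_triples[, 2L]))
  ranks <- double(2L * nrow(eval_triples))
  pos <- 0L
  for (i in seq_len(nrow(eval_triples))) {
    s <- eval_triples[i, 1L]; r <- eval_triples[i, 2L]; o <- eval_triples[i, 3L]
    for (dir in c("tail", "head")) {
      fixed <- if (dir == "tail") s else o
      true <- if (dir == "tail") o else s
      others <- if (dir == "tail") tails[[paste(s, r)]] else heads[[paste(o, r)]]
      sc <- score_candidates(params, fixed, r, dir)
      sc[setdiff(others, true)] <- -Inf
      st <- sc[true]
      ranks[pos <- pos + 1L] <-
        1 + sum(sc > st) + (sum(sc == st) - 1) / 2
    }
  }
  hits <- vapply(k_list, function(k) mean(ranks <= k), double(1L))
  list(mrr = mean(1 / ranks),
       hits = stats::setNames(hits, paste0("hits@", k_list)))
}

#' Area under the ROC curve
#'
#' Mann--Whitney formulation: the fraction of positive--negative pairs
#' ranked concordantly, counting ties as one half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @param relation Optional relation id used in error messages.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(scores, labels, relation = NULL) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop(sprintf("AUROC undefined%s: needs both classes (got %d pos, %d neg)",
                 if (is.null(relation)) "" else paste0(" for relation ", relation),
                 n_pos, n_neg), call. = FALSE)
  rk <- rank(scores)  # mid-ranks for ties
  (sum(rk[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision--recall curve (average precision)
#'
#' Step-integral average precision `sum_k (R_k - R_{k-1}) P_k` over
#' descending distinct score thresholds, with tied scores grouped into a
#' single threshold (so the result is permutation-invariant).  The
#' trapezoidal PR interpolation is deliberately not used: it
#' overestimates the area.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0,1\].
#' @export
auprc <- function(scores, labels, relation = NULL) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L)
    stop(sprintf("AUPRC undefined%s: no positives",
                 if (is.null(relation)) "" else paste0(" for relation ", relation)),
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; y <- labels[ord]
  grp_end <- cumsum(rle(sc)$lengths)  # last index of each tied block
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Average precision at k
#'
#' `sum_{j <= k} P(j) * rel(j) / min(k, total_positives)`, where `P(j)`
#' is the precision among the top `j` entries of a label vector already
#' sorted by descending score.  The denominator uses
#' `min(k, total_positives)` so a relation with fewer than `k` positives
#' can still reach 1.
#'
#' @param ranked_labels 0/1 labels sorted by descending score.
#' @param k Cutoff (default 50).
#' @param total_positives Number of positives for the relation
#'   (defaults to `sum(ranked_labels)`).
#' @return AP@k in \[0,1\].
#' @export
ap_at_k <- function(ranked_labels, k = 50L, total_positives = NULL) {
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  total_positives <- total_positives %||% sum(ranked_labels)
  if (total_positives < 1L) stop("'total_positives' must be >= 1", call. = FALSE)
  top <- ranked_labels[seq_len(min(k, length(ranked_labels)))]
  prec <- cumsum(top) / seq_along(top)
  sum(prec * top) / min(k, total_positives)
}

#' Per-side-effect evaluation report
#'
#' Scores every labelled pair with the model (mean of the two
#' orientations, since drug pairs are unordered), then computes AUROC,
#' AUPRC and AP@50 per pair-side-effect relation and their medians
#' across relations.  For AP@50, tied scores are ordered negatives-first
#' (a conservative, permutation-invariant convention).  Relations whose
#' metrics cannot be computed are skipped with a note instead of
#' aborting the report.
#'
#' @param params A `model_params`.
#' @param labeled A [sample_eval_negatives()] result.
#' @param k AP cutoff (default 50).
#' @return An `eval_report`: list with `per_relation` data frame,
#'   `medians`, `n_relations`, `notes` and metadata attributes.
#' @export
evaluate_side_effects <- function(params, labeled, k = 50L) {
  stopifnot(inherits(labeled, "labeled_pairs"))
  if (length(labeled) == 0L) stop("no labelled pairs", call. = FALSE)
  rel_index <- attr(labeled, "relation_index")
  rows <- list(); notes <- character(0)
  for (rel_id in names(labeled)) {
    df <- labeled[[rel_id]]
    r <- rel_index[[rel_id]]
    res <- tryCatch({
      s1 <- score_triples(params, cbind(df$a, r, df$b))
      s2 <- score_triples(params, cbind(df$b, r, df$a))
      sc <- (s1 + s2) / 2
      ord <- order(-sc, df$label)  # ties: negatives first
      data.frame(relation = rel_id,
                 auroc = auroc(sc, df$label, rel_id),
                 auprc = auprc(sc, df$label, rel_id),
                 ap50 = ap_at_k(df$label[ord], k = k,
                                total_positives = sum(df$label)),
                 n_pos = sum(df$label), stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      notes <- c(notes, sprintf("relation %s skipped: %s", rel_id,
                                conditionMessage(res)))
    } else {
      rows[[rel_id]] <- res
    }
  }
  per_rel <- do.call(rbind, rows)
  rownames(per_rel) <- NULL
  structure(list(
    per_relation = per_rel,
    medians = list(auroc = stats::median(per_rel$auroc),
                   auprc = stats::median(per_rel$auprc),
                   ap50 = stats::median(per_rel$ap50)),
    n_relations = nrow(per_rel),
    notes = notes,
    negative_seed = attr(labeled, "seed")),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report over %d side-effect relations\n", x$n_relations))
  cat(sprintf("  median AUROC %.4f | AUPRC %.4f | AP@50 %.4f\n",
              x$medians$auroc, x$medians$auprc, x$medians$ap50))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' The report schema as JSON plus the per-relation table as TSV for
#' audit.
#'
#' @param report An `eval_report`.
#' @param json_path,tsv_path Output paths (either may be NULL).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(medians = report$medians,
                              n_relations = report$n_relations,
                              negative_seed = report$negative_seed,
                              per_relation = report$per_relation,
                              notes = report$notes),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    data.table::fwrite(report$per_relation, tsv_path, sep = "\t")
  invisible(report)
}
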