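# Mini-batch training: 1vsAll / KvsAll query construction, losses,
# optimizers, plateau learning-rate decay, early stopping, checkpoints.

#' Configure a training run
#'
#' Defaults follow the strongest configuration found by the
#' hyperparameter search: Adam at learning rate 0.011 with batch size
#' 256 under the 1vsAll strategy with KL loss.  Validation performance
#' (filtered MRR) is checked every `eval_every` epochs starting at
#' `eval_start`; the run stops once `patience_checks` consecutive checks
#' fail to improve on the best metric seen before them, so with the
#' default schedule (check every 5 epochs from 50) the earliest possible
#' stop is epoch 55 and the latest epoch `max_epochs` = 500.  On every
#' failed check the learning rate is multiplied by `scheduler_factor`.
#'
#' @param strategy `"1vsAll"` (two single-truth queries per triple) or
#'   `"KvsAll"` (one multi-hot query per distinct (entity, relation,
#'   direction) key).
#' @param loss `"kl"` (cross-entropy of the softmax against the one-hot
#'   truth; 1vsAll only), `"bce"` (binary cross-entropy, the natural
#'   KvsAll pairing), `"margin"` (margin ranking, 1vsAll only) or
#'   `"se"` (squared error).
#' @param optimizer One of `"adam"`, `"adamax"`, `"adadelta"`,
#'   `"adagrad"`, `"sgd"`.
#' @param lr Positive initial learning rate.
#' @param batch_size Queries per batch.
#' @param max_epochs,eval_every,eval_start,patience_checks Early-stop
#'   schedule; `eval_start >= eval_every` and
#'   `max_epochs >= eval_start + eval_every` are required so at least
#'   two checks fit.
#' @param scheduler_factor Plateau decay multiplier in (0,1].
#' @param margin Margin for the ranking loss.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param checkpoint_every_epoch Keep a parameter snapshot after every
#'   epoch (needed for [per_epoch_curve()]).
#' @return A `train_config`.
#' @export
train_config <- function(strategy = c("1vsAll", "KvsAll"),
                         loss = NULL,
                         optimizer = c("adam", "adamax", "adadelta",
                                       "adagrad", "sgd"),
                         lr = 0.011, batch_size = 256L, max_epochs = 500L,
                         eval_every = 5L, eval_start = 50L,
                         patience_checks = 2L, scheduler_factor = 0.95,
                         margin = 1, seed = 1L,
                         checkpoint_every_epoch = FALSE) {
  strategy <- match.arg(strategy)
  loss <- loss %||% if (strategy == "1vsAll") "kl" else "bce"
  loss <- check_choice(loss, "loss", c("kl", "bce", "margin", "se"))
  if (loss %in% c("kl", "margin") && strategy != "1vsAll")
    stop(sprintf("loss '%s' requires the 1vsAll strategy", loss), call. = FALSE)
  optimizer <- match.arg(optimizer)
  if (lr < 0) stop("'lr' must be nonnegative", call. = FALSE)
  cfg <- list(strategy = strategy, loss = loss, optimizer = optimizer,
              lr = as.double(lr),
              batch_size = check_count(batch_size, "batch_size"),
              max_epochs = check_count(max_epochs, "max_epochs"),
              eval_every = check_count(eval_every, "eval_every"),
              eval_start = check_count(eval_start, "eval_start"),
              patience_checks = check_count(patience_checks, "patience_checks"),
              scheduler_factor = as.double(scheduler_factor),
              margin = check_nonneg(margin, "margin"),
              seed = check_count(seed, "seed", min = 0L),
              checkpoint_every_epoch = isTRUE(checkpoint_every_epoch))
  if (cfg$eval_start < cfg$eval_every)
    stop("'eval_start' must be >= 'eval_every'", call. = FALSE)
  if (cfg$max_epochs < cfg$eval_start + cfg$eval_every)
    stop("'max_epochs' must be >= eval_start + eval_every", call. = FALSE)
  if (scheduler_factor <= 0 || scheduler_factor > 1)
    stop("'scheduler_factor' must be in (0, 1]", call. = FALSE)
  structure(cfg, class = "train_config")
}

# --- query construction ------------------------------------------------------

# Internal: the epoch-invariant query table.
# 1vsAll: each triple (s, r, o) yields a tail query (s, r, ?) with truth o
# and a head query (?, r, o) with truth s; truths are length-1.
# KvsAll: one query per distinct (entity, relation, direction) key with the
# multi-set of training-true answers as a multi-hot label.
make_query_table <- function(triples, strategy) {
  s <- triples[, 1L]; r <- triples[, 2L]; o <- triples[, 3L]
  if (strategy == "1vsAll") {
    list(ent = c(s, o), rel = c(r, r),
         dir = rep(c(1L, 2L), each = nrow(triples)),
         truths = as.list(c(o, s)))
  } else {
    tail_key <- paste(s, r); head_key <- paste(o, r)
    tg <- split(o, tail_key); hg <- split(s, head_key)
    tk <- do.call(rbind, strsplit(names(tg), " ", fixed = TRUE))
    hk <- do.call(rbind, strsplit(names(hg), " ", fixed = TRUE))
    list(ent = as.integer(c(tk[, 1L], hk[, 1L])),
         rel = as.integer(c(tk[, 2L], hk[, 2L])),
         dir = rep(c(1L, 2L), c(length(tg), length(hg))),
         truths = c(unname(tg), unname(hg)))
  }
}

#' Build shuffled query batches for one epoch
#'
#' See [train_config()] for the two strategies.  Query order is shuffled
#' by `seed`; batches carry entity / relation / direction index vectors
#' plus a list of true-answer index vectors per query.
#'
#' @param train_triples Integer (s, r, o) triple matrix.
#' @param strategy `"1vsAll"` or `"KvsAll"`.
#' @param batch_size Queries per batch.
#' @param seed Shuffle seed.
#' @return List of batches, each a list `(ent, rel, dir, truths)`.
#' @export
build_queries <- function(train_triples, strategy = c("1vsAll", "KvsAll"),
                          batch_size = 256L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (nrow(train_triples) == 0L) stop("empty training set", call. = FALSE)
  q <- make_query_table(train_triples, strategy)
  n <- length(q$ent)
  perm <- with_seed(seed, sample.int(n))
  chunks <- split(perm, ceiling(seq_along(perm) / batch_size))
  lapply(chunks, function(idx)
    list(ent = q$ent[idx], rel = q$rel[idx], dir = q$dir[idx],
         truths = q$truths[idx]))
}

# --- losses ------------------------------------------------------------------

#' Binary cross-entropy of logits against 0/1 labels
#'
#' Mean over entries of `-(y log sigmoid(s) + (1-y) log(1-sigmoid(s)))`,
#' computed in log-sum-exp-safe form.
#'
#' @param scores Numeric vector of logits.
#' @param labels 0/1 vector of the same length.
#' @return Nonnegative scalar.
#' @export
loss_bce <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  mean(pmax(scores, 0) - scores * labels + log1p(exp(-abs(scores))))
}

#' Softmax cross-entropy against a one-hot truth
#'
#' `-log softmax(scores)[true_index]`, the KL divergence from the
#' one-hot target distribution up to its (zero) entropy, computed with a
#' stable log-softmax.
#'
#' @param scores Numeric score vector over candidates.
#' @param true_index Index of the true candidate.
#' @return Nonnegative scalar.
#' @export
loss_kl <- function(scores, true_index) {
  stopifnot(true_index >= 1L, true_index <= length(scores))
  mx <- max(scores)
  (mx + log(sum(exp(scores - mx)))) - scores[true_index]
}

# Multi-hot label matrix for a batch: B x n.
batch_labels <- function(truths, n_entities) {
  Y <- matrix(0, length(truths), n_entities)
  Y[cbind(rep.int(seq_along(truths), lengths(truths)), unlist(truths))] <- 1
  Y
}

# Batch loss value and gradient wrt the score matrix S (B x n).
batch_loss_grad <- function(S, truths, loss, margin) {
  B <- nrow(S); n <- ncol(S)
  switch(loss,
    kl = {
      LS <- row_log_softmax(S)
      ti <- cbind(seq_len(B), vapply(truths, `[`, integer(1L), 1L))
      G <- exp(LS)
      G[ti] <- G[ti] - 1
      list(loss = -sum(LS[ti]) / B, grad = G / B)
    },
    bce = {
      Y <- batch_labels(truths, n)
      l <- sum(pmax(S, 0) - S * Y + log1p(exp(-abs(S)))) / (B * n)
      list(loss = l, grad = (sigmoid(S) - Y) / (B * n))
    },
    se = {
      Y <- batch_labels(truths, n)
      D <- S - Y
      list(loss = sum(D * D) / (B * n), grad = 2 * D / (B * n))
    },
    margin = {
      ti <- cbind(seq_len(B), vapply(truths, `[`, integer(1L), 1L))
      st <- S[ti]
      viol <- pmax(margin - st + S, 0)  # includes the true column (= margin)
      viol[ti] <- 0
      G <- matrix(0, B, n)
      act <- viol > 0
      G[act] <- 1 / (B * (n - 1))
      G[ti] <- -rowSums(act) / (B * (n - 1))
      list(loss = sum(viol) / (B * (n - 1)), grad = G)
    })
}

# --- gradient accumulation ---------------------------------------------------

add_rows <- function(M, idx, contrib) {
  rs <- rowsum(contrib, idx)
  rows <- as.integer(rownames(rs))
  M[rows, ] <- M[rows, , drop = FALSE] + rs
  M
}

zero_grads <- function(mats) lapply(mats, function(m) array(0, dim(m)))

# Backward pass through candidate_scores() for one direction sub-batch.
# G is dLoss/dS (B x n); grads is updated and returned.
backward_candidates <- function(mats, model, ent, rel, direction, G, grads) {
  switch(model,
    distmult = {
      A <- mats$E[ent, , drop = FALSE] * mats$W[rel, , drop = FALSE]
      grads$E <- grads$E + crossprod(G, A)
      dA <- G %*% mats$E
      grads$E <- add_rows(grads$E, ent, dA * mats$W[rel, , drop = FALSE])
      grads$W <- add_rows(grads$W, rel, dA * mats$E[ent, , drop = FALSE])
    },
    complex = {
      c_ <- mats$wr[rel, , drop = FALSE]; d <- mats$wi[rel, , drop = FALSE]
      if (direction == "tail") {
        a <- mats$er[ent, , drop = FALSE]; b <- mats$ei[ent, , drop = FALSE]
        P1 <- a * c_ - b * d; P2 <- a * d + b * c_
        grads$er <- grads$er + crossprod(G, P1)
        grads$ei <- grads$ei + crossprod(G, P2)
        dP1 <- G %*% mats$er; dP2 <- G %*% mats$ei
        grads$er <- add_rows(grads$er, ent, dP1 * c_ + dP2 * d)
        grads$ei <- add_rows(grads$ei, ent, -dP1 * d + dP2 * c_)
        grads$wr <- add_rows(grads$wr, rel, dP1 * a + dP2 * b)
        grads$wi <- add_rows(grads$wi, rel, -dP1 * b + dP2 * a)
      } else {
        p <- mats$er[ent, , drop = FALSE]; q <- mats$ei[ent, , drop = FALSE]
        P1 <- c_ * p + d * q; P2 <- c_ * q - d * p
        grads$er <- grads$er + crossprod(G, P1)
        grads$ei <- grads$ei + crossprod(G, P2)
        dP1 <- G %*% mats$er; dP2 <- G %*% mats$ei
        grads$wr <- add_rows(grads$wr, rel, dP1 * p + dP2 * q)
        grads$wi <- add_rows(grads$wi, rel, dP1 * q - dP2 * p)
        grads$er <- add_rows(grads$er, ent, dP1 * c_ - dP2 * d)
        grads$ei <- add_rows(grads$ei, ent, dP1 * d + dP2 * c_)
      }
    },
    simple = {
      if (direction == "tail") {
        P1 <- 0.5 * mats$H[ent, , drop = FALSE] * mats$V[rel, , drop = FALSE]
        P2 <- 0.5 * mats$T[ent, , drop = FALSE] * mats$Vinv[rel, , drop = FALSE]
        grads$T <- grads$T + crossprod(G, P1)
        grads$H <- grads$H + crossprod(G, P2)
        dP1 <- G %*% mats$T; dP2 <- G %*% mats$H
        grads$H <- add_rows(grads$H, ent, 0.5 * dP1 * mats$V[rel, , drop = FALSE])
        grads$V <- add_rows(grads$V, rel, 0.5 * dP1 * mats$H[ent, , drop = FALSE])
        grads$T <- add_rows(grads$T, ent,
                            0.5 * dP2 * mats$Vinv[rel, , drop = FALSE])
        grads$Vinv <- add_rows(grads$Vinv, rel,
                               0.5 * dP2 * mats$T[ent, , drop = FALSE])
      } else {
        P1 <- 0.5 * mats$T[ent, , drop = FALSE] * mats$V[rel, , drop = FALSE]
        P2 <- 0.5 * mats$H[ent, , drop = FALSE] * mats$Vinv[rel, , drop = FALSE]
        grads$H <- grads$H + crossprod(G, P1)
        grads$T <- grads$T + crossprod(G, P2)
        dP1 <- G %*% mats$H; dP2 <- G %*% mats$T
        grads$T <- add_rows(grads$T, ent, 0.5 * dP1 * mats$V[rel, , drop = FALSE])
        grads$V <- add_rows(grads$V, rel, 0.5 * dP1 * mats$T[ent, , drop = FALSE])
        grads$H <- add_rows(grads$H, ent,
                            0.5 * dP2 * mats$Vinv[rel, , drop = FALSE])
        grads$Vinv <- add_rows(grads$Vinv, rel,
                               0.5 * dP2 * mats$H[ent, , drop = FALSE])
      }
    })
  grads
}

entity_mat_names <- function(model)
  switch(model, distmult = "E", complex = c("er", "ei"), simple = c("H", "T"))
relation_mat_names <- function(model)
  switch(model, distmult = "W", complex = c("wr", "wi"),
         simple = c("V", "Vinv"))

# One batch: optional dropout masks, forward, loss, backward; returns
# loss (sum over queries weight already folded in) and gradient matrices.
batch_step <- function(mats, model, batch, loss, margin, n_entities,
                       p_ent, p_rel) {
  masks <- NULL
  work <- mats
  if (p_ent > 0 || p_rel > 0) {
    masks <- list()
    for (nm in entity_mat_names(model)) if (p_ent > 0) {
      masks[[nm]] <- matrix(stats::runif(length(mats[[nm]])) >= p_ent,
                            nrow(mats[[nm]]), ncol(mats[[nm]])) / (1 - p_ent)
      work[[nm]] <- mats[[nm]] * masks[[nm]]
    }
    for (nm in relation_mat_names(model)) if (p_rel > 0) {
      masks[[nm]] <- matrix(stats::runif(length(mats[[nm]])) >= p_rel,
                            nrow(mats[[nm]]), ncol(mats[[nm]])) / (1 - p_rel)
      work[[nm]] <- mats[[nm]] * masks[[nm]]
    }
  }
  grads <- zero_grads(mats)
  total_loss <- 0
  B_total <- length(batch$ent)
  for (d in c(1L, 2L)) {
    sel <- which(batch$dir == d)
    if (!length(sel)) next
    dir <- if (d == 1L) "tail" else "head"
    S <- candidate_scores(work, model, batch$ent[sel], batch$rel[sel], dir)
    lg <- batch_loss_grad(S, batch$truths[sel], loss, margin)
    # re-weight sub-batch means to a whole-batch mean
    w <- length(sel) / B_total
    total_loss <- total_loss + w * lg$loss
    grads <- backward_candidates(work, model, batch$ent[sel], batch$rel[sel],
                                 dir, w * lg$grad, grads)
  }
  if (!is.null(masks))
    for (nm in names(masks)) grads[[nm]] <- grads[[nm]] * masks[[nm]]
  list(loss = total_loss, grads = grads)
}

# --- optimizers --------------------------------------------------------------

opt_init <- function(name, mats) {
  state <- lapply(mats, function(m) switch(
    name,
    sgd = list(),
    adagrad = list(acc = array(0, dim(m))),
    adadelta = list(eg = array(0, dim(m)), ex = array(0, dim(m))),
    adam = list(m = array(0, dim(m)), v = array(0, dim(m))),
    adamax = list(m = array(0, dim(m)), u = array(0, dim(m)))))
  list(name = name, t = 0L, state = state)
}

opt_step <- function(opt, mats, grads, lr) {
  opt$t <- opt$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rho <- 0.9; deps <- 1e-6
  for (nm in names(mats)) {
    g <- grads[[nm]]
    st <- opt$state[[nm]]
    upd <- switch(opt$name,
      sgd = -lr * g,
      adagrad = {
        st$acc <- st$acc + g * g
        -lr * g / (sqrt(st$acc) + eps)
      },
      adadelta = {
        st$eg <- rho * st$eg + (1 - rho) * g * g
        dx <- -sqrt(st$ex + deps) / sqrt(st$eg + deps) * g
        st$ex <- rho * st$ex + (1 - rho) * dx * dx
        lr * dx
      },
      adam = {
        st$m <- b1 * st$m + (1 - b1) * g
        st$v <- b2 * st$v + (1 - b2) * g * g
        mh <- st$m / (1 - b1^opt$t)
        vh <- st$v / (1 - b2^opt$t)
        -lr * mh / (sqrt(vh) + eps)
      },
      adamax = {
        st$m <- b1 * st$m + (1 - b1) * g
        st$u <- pmax(b2 * st$u, abs(g))
        -(lr / (1 - b1^opt$t)) * st$m / (st$u + eps)
      })
    opt$state[[nm]] <- st
    mats[[nm]] <- mats[[nm]] + upd
  }
  list(opt = opt, mats = mats)
}

# --- early stopping ----------------------------------------------------------

#' Apply the early-stopping rule to a check history
#'
#' The run stops once `patience` consecutive checks have each failed to
#' exceed the best metric recorded before them (the pre-training
#' baseline counts as a record), so with checks every 5 epochs starting
#' at epoch 50 the earliest stop is epoch 55.
#'
#' @param history A `train_history`, or any list with elements
#'   `baseline` (numeric or NA) and `checks` (data frame with columns
#'   `epoch`, `metric`).
#' @param patience Number of consecutive failed checks that triggers a
#'   stop (default 2).
#' @return `"stop"` or `"continue"`.
#' @export
check_early_stop <- function(history, patience = 2L) {
  checks <- history$checks
  if (is.null(checks) || nrow(checks) == 0L) return("continue")
  best <- if (!is.null(history$baseline) && is.finite(history$baseline))
    history$baseline else -Inf
  fails <- 0L
  for (i in seq_len(nrow(checks))) {
    if (checks$metric[i] > best) {
      best <- checks$metric[i]
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
  }
  if (fails >= patience) "stop" else "continue"
}

# --- training driver ---------------------------------------------------------

# Materialize both orientations of unordered drug-pair (PSE) triples so the
# directional scorers see each stored pair both ways; SimplE's inverse
# relations can then learn the symmetry instead of having it imposed.
materialize_reverse_pse <- function(graph, triples) {
  pse <- graph$relations$role[triples[, 2L]] == "PSE"
  rev <- triples[pse & triples[, 1L] != triples[, 3L], c(3L, 2L, 1L),
                 drop = FALSE]
  colnames(rev) <- c("s", "r", "o")
  rbind(triples, rev)
}

#' Assemble a training dataset with a validation carve-out
#'
#' Reserves `valid_fraction` of the training pair-side-effect triples
#' (stratified per relation, floor-rounded, independent seed) as the
#' validation split used for early stopping; all remaining triples stay
#' in train.
#'
#' @param graph The full `triple_graph`.
#' @param split A [split_pse_holdout()] result for `graph`.
#' @param valid_fraction Fraction of training PSE triples per relation.
#' @param seed Integer seed, independent of the holdout seed.
#' @return A list `(graph, train, valid, test)` suitable for
#'   [run_training()].
#' @export
training_dataset <- function(graph, split, valid_fraction = 0.05, seed = 2L) {
  stopifnot(inherits(graph, "triple_graph"), inherits(split, "holdout_split"))
  valid_fraction <- check_fraction(valid_fraction, "valid_fraction")
  train <- split$train
  pse_rels <- which(graph$relations$role == "PSE")
  valid_rows <- integer(0)
  for (r in pse_rels) {
    rows <- which(train[, 2L] == r)
    rows <- rows[order(train[rows, 1L], train[rows, 3L])]
    k <- floor(valid_fraction * length(rows))
    if (k > 0L)
      valid_rows <- c(valid_rows,
                      rows[with_seed(derive_seed(seed, 5000L + r),
                                     sample.int(length(rows), k))])
  }
  list(graph = graph,
       train = train[setdiff(seq_len(nrow(train)), valid_rows), , drop = FALSE],
       valid = train[valid_rows, , drop = FALSE],
       test = split$holdout)
}

new_history <- function(baseline) {
  structure(list(baseline = baseline,
                 epochs = data.frame(epoch = integer(), loss = double(),
                                     lr = double()),
                 checks = data.frame(epoch = integer(), metric = double(),
                                     best = double(), improved = logical()),
                 best_metric = -Inf, best_epoch = NA_integer_,
                 stop_reason = NA_character_),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("train_history: %d epochs, %d checks, best metric %.4f at epoch %s, stop: %s\n",
              nrow(x$epochs), nrow(x$checks), x$best_metric,
              as.character(x$best_epoch), x$stop_reason))
  invisible(x)
}

# Forward-only mean loss over all queries (used for the epoch-0 record).
forward_loss <- function(mats, model, q, loss, margin, n_entities, batch_size) {
  n <- length(q$ent)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  total <- 0
  for (idx in chunks) {
    for (d in c(1L, 2L)) {
      sel <- idx[q$dir[idx] == d]
      if (!length(sel)) next
      dir <- if (d == 1L) "tail" else "head"
      S <- candidate_scores(mats, model, q$ent[sel], q$rel[sel], dir)
      lg <- batch_loss_grad(S, q$truths[sel], loss, margin)
      total <- total + lg$loss * length(sel)
    }
  }
  total / n
}

#' Train a tensor-factorization model
#'
#' Runs mini-batch gradient training with the configured strategy, loss
#' and optimizer.  Stored drug-pair triples are materialized in both
#' orientations before query construction.  Validation filtered MRR is
#' measured before training (the baseline) and at every check epoch;
#' the best-scoring parameters are retained, the learning rate decays on
#' failed checks, and the early-stopping rule of [check_early_stop()]
#' ends the run.  Training aborts with a diagnostic naming the epoch and
#' batch if the loss becomes non-finite.
#'
#' @param dataset A [training_dataset()] result (or any list with
#'   `graph`, `train` and `valid` components).
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()].
#' @param features Initialization matrix for `init = "feature"`.
#' @param resume_from A checkpoint returned in a previous run's
#'   `$last` slot (or loaded with [load_checkpoint()]); training
#'   continues from the epoch after it.
#' @param verbose Print one line per epoch and per check.
#' @return A list: `best` (checkpoint with the best-validation
#'   parameters), `last` (checkpoint after the final epoch), `history`
#'   (a `train_history`), and `epoch_params` (list of per-epoch
#'   parameter snapshots when `checkpoint_every_epoch`).
#' @export
run_training <- function(dataset, mconfig, tconfig, features = NULL,
                         resume_from = NULL, verbose = FALSE) {
  stopifnot(inherits(mconfig, "model_config"), inherits(tconfig, "train_config"))
  graph <- dataset$graph
  n_ent <- nrow(graph$entities)
  n_rel <- nrow(graph$relations)
  train_mat <- materialize_reverse_pse(graph, dataset$train)
  valid <- dataset$valid
  q <- make_query_table(train_mat, tconfig$strategy)
  nq <- length(q$ent)
  filter <- rbind(dataset$train, valid)

  if (is.null(resume_from)) {
    params <- init_params(mconfig, n_ent, n_rel, seed = tconfig$seed,
                          features = features)
    opt <- opt_init(tconfig$optimizer, params$mats)
    lr <- tconfig$lr
    start_epoch <- 0L
    baseline <- if (nrow(valid))
      rank_metrics(params, valid, filter)$mrr else NA_real_
    history <- new_history(baseline)
    history$epochs <- rbind(history$epochs, data.frame(
      epoch = 0L,
      loss = forward_loss(params$mats, mconfig$model, q, tconfig$loss,
                          tconfig$margin, n_ent, tconfig$batch_size),
      lr = lr))
    best_params <- params
  } else {
    params <- resume_from$params
    opt <- resume_from$opt
    lr <- resume_from$lr
    start_epoch <- resume_from$epoch
    history <- resume_from$history
    best_params <- resume_from$best_params %||% params
  }
  epoch_params <- list()
  model <- mconfig$model
  stop_reason <- "max-epochs"

  for (epoch in seq.int(start_epoch + 1L, tconfig$max_epochs)) {
    epoch_loss <- with_seed(derive_seed(tconfig$seed, 10000L + epoch), {
      perm <- sample.int(nq)
      chunks <- split(perm, ceiling(seq_along(perm) / tconfig$batch_size))
      acc <- 0
      for (bi in seq_along(chunks)) {
        idx <- chunks[[bi]]
        batch <- list(ent = q$ent[idx], rel = q$rel[idx], dir = q$dir[idx],
                      truths = q$truths[idx])
        bs <- batch_step(params$mats, model, batch, tconfig$loss,
                         tconfig$margin, n_ent,
                         mconfig$dropout_entity, mconfig$dropout_relation)
        if (!is.finite(bs$loss))
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi),
               call. = FALSE)
        if (mconfig$reg_weight > 0)
          bs$grads <- mapply(function(g, p) g + mconfig$reg_weight * p,
                             bs$grads, params$mats, SIMPLIFY = FALSE)
        stepped <- opt_step(opt, params$mats, bs$grads, lr)
        opt <- stepped$opt
        params$mats <- stepped$mats
        acc <- acc + bs$loss * length(idx)
      }
      acc / nq
    })
    history$epochs <- rbind(history$epochs,
                            data.frame(epoch = epoch, loss = epoch_loss, lr = lr))
    if (verbose) message(sprintf("epoch %d  loss %.5f  lr %.5g",
                                 epoch, epoch_loss, lr))
    if (tconfig$checkpoint_every_epoch)
      epoch_params[[as.character(epoch)]] <- params

    is_check <- nrow(valid) > 0L && epoch >= tconfig$eval_start &&
      (epoch - tconfig$eval_start) %% tconfig$eval_every == 0L
    if (is_check) {
      metric <- rank_metrics(params, valid, filter)$mrr
      prev_best <- max(history$best_metric,
                       if (is.finite(history$baseline %||% NA_real_))
                         history$baseline else -Inf)
      improved <- metric > prev_best
      if (improved) {
        history$best_metric <- metric
        history$best_epoch <- epoch
        best_params <- params
      } else {
        lr <- lr * tconfig$scheduler_factor
      }
      history$checks <- rbind(history$checks, data.frame(
        epoch = epoch, metric = metric,
        best = max(history$best_metric, prev_best), improved = improved))
      if (verbose) message(sprintf("check %d  MRR %.4f  best %.4f  %s",
                                   epoch, metric, max(metric, prev_best),
                                   if (improved) "improved" else "no improvement"))
      if (check_early_stop(history, tconfig$patience_checks) == "stop") {
        stop_reason <- "early-stop"
        history$stop_reason <- stop_reason
        break
      }
    }
  }
  history$stop_reason <- stop_reason
  if (!is.finite(history$best_metric)) {
    best_params <- params
    history$best_epoch <- utils::tail(history$epochs$epoch, 1L)
  }
  mk_ckpt <- function(p) list(params = p, opt = opt, lr = lr,
                              epoch = utils::tail(history$epochs$epoch, 1L),
                              history = history, best_params = best_params,
                              mconfig = mconfig, tconfig = tconfig)
  list(best = mk_ckpt(best_params), last = mk_ckpt(params),
       history = history, epoch_params = epoch_params)
}
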