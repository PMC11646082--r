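# The three tensor-factorization scorers and their parameter layouts.
#
# DistMult: score(i, r, j) = sum_k E[i,k] W[r,k] E[j,k]          (symmetric)
# ComplEx:  score(i, r, j) = Re(sum_k e_i[k] w_r[k] conj(e_j[k]))
#           with complex vectors stored as real/imaginary halves
# SimplE:   score(i, r, j) = (  <H[i], V[r],   T[j]>
#                             + <H[j], Vinv[r], T[i]> ) / 2
#           head/tail entity roles coupled through the inverse relation

#' Configure a tensor-factorization model
#'
#' @param model `"distmult"`, `"complex"` or `"simple"`.
#' @param m Embedding size (total per-entity parameter width; typical
#'   search values are 32, 64, 128, 256, 512).  For ComplEx `m` must be
#'   even: the first `m/2` columns are the real parts and the last `m/2`
#'   the imaginary parts, i.e. complex dimension `m/2`.
#' @param init `"normal"` (sd 0.1), `"xavier-normal"` (Glorot-scaled
#'   normal) or `"feature"` (drug rows copied from a [reduce_features()]
#'   matrix, everything else normal).
#' @param dropout_entity,dropout_relation Training-time dropout rates on
#'   entity / relation embeddings, in \[0,1).
#' @param reg_weight L2 regularization weight (0 disables; 0 was the
#'   best-found value for the strongest configuration).
#' @return A `model_config`.
#' @export
model_config <- function(model = c("simple", "complex", "distmult"),
                         m = 128L, init = c("normal", "xavier-normal", "feature"),
                         dropout_entity = 0, dropout_relation = 0,
                         reg_weight = 0) {
  model <- match.arg(model)
  init <- match.arg(init)
  m <- check_count(m, "m")
  if (model == "complex" && m %% 2L != 0L)
    stop("'m' must be even for ComplEx (real + imaginary halves)", call. = FALSE)
  structure(list(model = model, m = m, init = init,
                 dropout_entity = check_fraction(dropout_entity, "dropout_entity",
                                                 closed_zero = TRUE),
                 dropout_relation = check_fraction(dropout_relation,
                                                   "dropout_relation",
                                                   closed_zero = TRUE),
                 reg_weight = check_nonneg(reg_weight, "reg_weight")),
            class = "model_config")
}

glorot_sd <- function(fan_in, fan_out) sqrt(2 / (fan_in + fan_out))

init_matrix <- function(nrow, ncol, init) {
  sd <- if (init == "xavier-normal") glorot_sd(nrow, ncol) else default_init_sd
  matrix(stats::rnorm(nrow * ncol, sd = sd), nrow, ncol)
}

#' Initialize model parameters
#'
#' `"normal"` draws every entry from N(0, 0.1^2); `"xavier-normal"`
#' rescales the draw of each matrix by the Glorot rule
#' `sd = sqrt(2 / (fan_in + fan_out))` from its own dimensions;
#' `"feature"` copies drug rows of the entity matrix (or matrices) from
#' a [reduce_features()] initialization matrix and fills gene rows and
#' all relation rows by the normal rule.  For ComplEx the feature
#' matrix's first half of columns initializes the real parts and the
#' second half the imaginary parts; for SimplE the same matrix is copied
#' into both the head-role and tail-role entity matrices.
#'
#' @param config A [model_config()].
#' @param n_entities,n_relations Vocabulary sizes.
#' @param seed Integer seed (identical seeds give identical parameters).
#' @param features Initialization matrix; required iff
#'   `config$init == "feature"`, with `config$m` columns.
#' @param feature_rows Entity indices the rows of `features` correspond
#'   to; defaults to the first `nrow(features)` entities (the drug block
#'   when entities are drugs-first).
#' @return A `model_params` object.
#' @export
init_params <- function(config, n_entities, n_relations, seed = 1L,
                        features = NULL, feature_rows = NULL) {
  stopifnot(inherits(config, "model_config"))
  n_entities <- check_count(n_entities, "n_entities")
  n_relations <- check_count(n_relations, "n_relations")
  if ((config$init == "feature") != !is.null(features))
    stop("'features' must be supplied exactly when init = \"feature\"",
         call. = FALSE)
  if (!is.null(features)) {
    if (ncol(features) != config$m)
      stop(sprintf("feature matrix has %d columns but m = %d",
                   ncol(features), config$m), call. = FALSE)
    feature_rows <- feature_rows %||% seq_len(nrow(features))
    stopifnot(length(feature_rows) == nrow(features),
              all(feature_rows >= 1L), all(feature_rows <= n_entities))
  }
  base_init <- if (config$init == "xavier-normal") "xavier-normal" else "normal"
  m <- config$m
  mats <- with_seed(seed, switch(
    config$model,
    distmult = list(E = init_matrix(n_entities, m, base_init),
                    W = init_matrix(n_relations, m, base_init)),
    complex = {
      mc <- m %/% 2L
      list(er = init_matrix(n_entities, mc, base_init),
           ei = init_matrix(n_entities, mc, base_init),
           wr = init_matrix(n_relations, mc, base_init),
           wi = init_matrix(n_relations, mc, base_init))
    },
    simple = list(H = init_matrix(n_entities, m, base_init),
                  T = init_matrix(n_entities, m, base_init),
                  V = init_matrix(n_relations, m, base_init),
                  Vinv = init_matrix(n_relations, m, base_init))
  ))
  if (!is.null(features)) {
    mats <- switch(config$model,
      distmult = { mats$E[feature_rows, ] <- features; mats },
      complex = {
        mc <- m %/% 2L
        mats$er[feature_rows, ] <- features[, seq_len(mc), drop = FALSE]
        mats$ei[feature_rows, ] <- features[, mc + seq_len(mc), drop = FALSE]
        mats
      },
      simple = {
        mats$H[feature_rows, ] <- features
        mats$T[feature_rows, ] <- features
        mats
      })
  }
  structure(list(model = config$model, m = m, config = config,
                 n_entities = n_entities, n_relations = n_relations,
                 mats = mats),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: %s, m = %d, %d entities, %d relations\n",
              x$model, x$m, x$n_entities, x$n_relations))
  invisible(x)
}

check_indices <- function(params, vi, r, vj) {
  if (any(vi < 1L) || any(vi > params$n_entities) ||
      any(vj < 1L) || any(vj > params$n_entities))
    stop("entity index out of range", call. = FALSE)
  if (any(r < 1L) || any(r > params$n_relations))
    stop("relation index out of range", call. = FALSE)
}

#' Score triples under DistMult
#'
#' Vectorized over equal-length index vectors; the trilinear form is
#' symmetric in `vi` and `vj` by construction.
#'
#' @param params `model_params` with `model = "distmult"`.
#' @param vi,r,vj Head entity, relation and tail entity indices.
#' @return Numeric score vector.
#' @export
score_distmult <- function(params, vi, r, vj) {
  stopifnot(params$model == "distmult")
  check_indices(params, vi, r, vj)
  E <- params$mats$E; W <- params$mats$W
  rowSums(E[vi, , drop = FALSE] * W[r, , drop = FALSE] * E[vj, , drop = FALSE])
}

#' Score triples under ComplEx
#'
#' Real part of the Hermitian trilinear product
#' `sum_k e_vi[k] w_r[k] conj(e_vj[k])`; antisymmetric head--tail
#' behaviour is possible when relation vectors have imaginary parts.
#'
#' @inheritParams score_distmult
#' @export
score_complex <- function(params, vi, r, vj) {
  stopifnot(params$model == "complex")
  check_indices(params, vi, r, vj)
  with(params$mats, {
    a <- er[vi, , drop = FALSE]; b <- ei[vi, , drop = FALSE]
    c_ <- wr[r, , drop = FALSE]; d <- wi[r, , drop = FALSE]
    p <- er[vj, , drop = FALSE]; q <- ei[vj, , drop = FALSE]
    rowSums((a * c_ - b * d) * p + (a * d + b * c_) * q)
  })
}

#' Score triples under SimplE
#'
#' Mean of the forward trilinear term (head-role, relation, tail-role)
#' and the inverse-relation term with the entity roles swapped, which
#' couples each entity's head and tail factors.
#'
#' @inheritParams score_distmult
#' @export
score_simple <- function(params, vi, r, vj) {
  stopifnot(params$model == "simple")
  check_indices(params, vi, r, vj)
  with(params$mats, {
    fwd <- rowSums(H[vi, , drop = FALSE] * V[r, , drop = FALSE] *
                     T[vj, , drop = FALSE])
    bwd <- rowSums(H[vj, , drop = FALSE] * Vinv[r, , drop = FALSE] *
                     T[vi, , drop = FALSE])
    (fwd + bwd) / 2
  })
}

#' Score triples with the model-appropriate scorer
#'
#' @param params A `model_params`.
#' @param triples Integer matrix with columns (s, r, o).
#' @return Numeric score vector.
#' @export
score_triples <- function(params, triples) {
  f <- switch(params$model, distmult = score_distmult,
              complex = score_complex, simple = score_simple)
  f(params, triples[, 1L], triples[, 2L], triples[, 3L])
}

#' Score all candidate entities for a partially fixed triple
#'
#' With `direction = "tail"` the free slot is the object: entry `k` is
#' `score(entity, relation, k)`.  With `direction = "head"` the free
#' slot is the subject: entry `k` is `score(k, relation, entity)`.
#' Agreement with the scalar scorers is exact, not approximate.
#'
#' @param params A `model_params`.
#' @param entity Fixed entity index.
#' @param relation Relation index.
#' @param direction `"tail"` or `"head"`.
#' @return Numeric vector of length `n_entities`.
#' @export
score_candidates <- function(params, entity, relation,
                             direction = c("tail", "head")) {
  direction <- match.arg(direction)
  drop(candidate_scores(params$mats, params$model, entity, relation,
                        direction))
}

# Batch candidate scoring: ent, rel are equal-length index vectors; returns
# a length(ent) x n_entities matrix.  `mats` is passed separately so the
# training loop can substitute dropout-masked copies.
candidate_scores <- function(mats, model, ent, rel, direction) {
  switch(model,
    distmult = {
      A <- mats$E[ent, , drop = FALSE] * mats$W[rel, , drop = FALSE]
      tcrossprod(A, mats$E)
    },
    complex = {
      c_ <- mats$wr[rel, , drop = FALSE]; d <- mats$wi[rel, , drop = FALSE]
      if (direction == "tail") {
        a <- mats$er[ent, , drop = FALSE]; b <- mats$ei[ent, , drop = FALSE]
        P1 <- a * c_ - b * d; P2 <- a * d + b * c_
      } else {
        p <- mats$er[ent, , drop = FALSE]; q <- mats$ei[ent, , drop = FALSE]
        P1 <- c_ * p + d * q; P2 <- c_ * q - d * p
      }
      tcrossprod(P1, mats$er) + tcrossprod(P2, mats$ei)
    },
    simple = {
      if (direction == "tail") {
        P1 <- 0.5 * mats$H[ent, , drop = FALSE] * mats$V[rel, , drop = FALSE]
        P2 <- 0.5 * mats$T[ent, , drop = FALSE] * mats$Vinv[rel, , drop = FALSE]
        tcrossprod(P1, mats$T) + tcrossprod(P2, mats$H)
      } else {
        P1 <- 0.5 * mats$T[ent, , drop = FALSE] * mats$V[rel, , drop = FALSE]
        P2 <- 0.5 * mats$H[ent, , drop = FALSE] * mats$Vinv[rel, , drop = FALSE]
        tcrossprod(P1, mats$H) + tcrossprod(P2, mats$T)
      }
    })
}

# --- checkpoints -------------------------------------------------------------

#' Save / load a training checkpoint
#'
#' A checkpoint is a plain list (parameters, optimizer state, epoch
#' number, RNG state, history) serialized with R's native RDS format;
#' `load_checkpoint(save_checkpoint(x, f))` reproduces `x` bit-exactly.
#'
#' @param checkpoint A checkpoint list (see [run_training()]).
#' @param path File path.
#' @return `save_checkpoint` invisibly returns `path`;
#'   `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
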