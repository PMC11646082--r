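test_that("initialization is deterministic and honours feature copies", {
  mc <- model_config("distmult", m = 4L)
  p1 <- init_params(mc, 10L, 3L, seed = 5)
  p2 <- init_params(mc, 10L, 3L, seed = 5)
  expect_identical(p1, p2)
  feats <- matrix(seq_len(24) / 10, 6, 4)
  mcf <- model_config("distmult", m = 4L, init = "feature")
  pf <- init_params(mcf, 10L, 3L, seed = 5, features = feats)
  expect_equal(pf$mats$E[1, ], feats[1, ])
  expect_equal(pf$mats$E[1:6, ], feats)
  # SimplE copies the same features into both entity roles
  mcs <- model_config("simple", m = 4L, init = "feature")
  ps <- init_params(mcs, 10L, 3L, seed = 5, features = feats)
  expect_equal(ps$mats$H[1:6, ], feats)
  expect_equal(ps$mats$T[1:6, ], feats)
  # ComplEx splits the feature columns half/half into real and imaginary
  mcc <- model_config("complex", m = 4L, init = "feature")
  pc <- init_params(mcc, 10L, 3L, seed = 5, features = feats)
  expect_equal(pc$mats$er[1:6, ], feats[, 1:2])
  expect_equal(pc$mats$ei[1:6, ], feats[, 3:4])
  expect_error(init_params(mcf, 10L, 3L, seed = 5,
                           features = feats[, 1:3]), "columns")
  expect_error(init_params(mc, 10L, 3L, seed = 5, features = feats),
               "feature")
})

test_that("xavier-normal matches the Glorot scale empirically", {
  mc <- model_config("distmult", m = 64L, init = "xavier-normal")
  p <- init_params(mc, 19734L, 5L, seed = 3)
  target <- sqrt(2 / (19734 + 64))
  expect_lt(abs(stats::sd(p$mats$E) - target) / target, 0.1)
})

test_that("hand-computed scalar scores are exact", {
  # DistMult: E[vi]=[1,2], W[r]=[1,0], E[vj]=[3,4] -> 3
  p <- init_params(model_config("distmult", m = 2L), 2L, 1L, seed = 1)
  p$mats$E <- rbind(c(1, 2), c(3, 4)); p$mats$W <- rbind(c(1, 0))
  expect_equal(score_distmult(p, 1L, 1L, 2L), 3)
  # ComplEx: e_vi = 1+0i, w_r = 0+1i, e_vj = 0+1i -> Re((1)(i)(-i)) = 1
  pc <- init_params(model_config("complex", m = 2L), 2L, 1L, seed = 1)
  pc$mats$er <- rbind(1, 0); pc$mats$ei <- rbind(0, 1)
  pc$mats$wr <- rbind(0); pc$mats$wi <- rbind(1)
  expect_equal(score_complex(pc, 1L, 1L, 2L), 1)
  # SimplE: 0.5 * (2*1*3 + 1*5*4) = 13
  ps <- init_params(model_config("simple", m = 1L), 2L, 1L, seed = 1)
  ps$mats$H <- rbind(2, 1); ps$mats$T <- rbind(4, 3)
  ps$mats$V <- rbind(1); ps$mats$Vinv <- rbind(5)
  expect_equal(score_simple(ps, 1L, 1L, 2L), 13)
  expect_error(score_simple(ps, 1L, 2L, 2L), "out of range")
})

test_that("vectorized scorers match naive triple-loop oracles", {
  loop_score <- function(p, vi, r, vj) {
    m <- p$m
    switch(p$model,
      distmult = sum(sapply(1:m, function(k)
        p$mats$E[vi, k] * p$mats$W[r, k] * p$mats$E[vj, k])),
      complex = {
        mc <- m %/% 2L
        s <- 0
        for (k in 1:mc) {
          e1 <- complex(real = p$mats$er[vi, k], imaginary = p$mats$ei[vi, k])
          w <- complex(real = p$mats$wr[r, k], imaginary = p$mats$wi[r, k])
          e2 <- complex(real = p$mats$er[vj, k], imaginary = p$mats$ei[vj, k])
          s <- s + Re(e1 * w * Conj(e2))
        }
        s
      },
      simple = {
        f <- sum(sapply(1:m, function(k)
          p$mats$H[vi, k] * p$mats$V[r, k] * p$mats$T[vj, k]))
        b <- sum(sapply(1:m, function(k)
          p$mats$H[vj, k] * p$mats$Vinv[r, k] * p$mats$T[vi, k]))
        (f + b) / 2
      })
  }
  set.seed(11)
  n <- 12L; R <- 4L
  for (model in c("distmult", "complex", "simple")) {
    m <- if (model == "complex") 10L else 5L
    p <- init_params(model_config(model, m = m), n, R, seed = 2)
    vi <- sample(n, 100, TRUE); r <- sample(R, 100, TRUE)
    vj <- sample(n, 100, TRUE)
    vec <- score_triples(p, cbind(vi, r, vj))
    loop <- vapply(1:100, function(i) loop_score(p, vi[i], r[i], vj[i]),
                   double(1L))
    expect_lt(max(abs(vec - loop)), 1e-10)
  }
})

test_that("symmetry and antisymmetry identities hold", {
  set.seed(21)
  n <- 9L; R <- 3L
  vi <- sample(n, 60, TRUE); r <- sample(R, 60, TRUE); vj <- sample(n, 60, TRUE)
  # DistMult symmetric for all parameter values
  pd <- init_params(model_config("distmult", m = 6L), n, R, seed = 4)
  expect_equal(score_distmult(pd, vi, r, vj), score_distmult(pd, vj, r, vi))
  # ComplEx: purely imaginary relation -> antisymmetric
  pc <- init_params(model_config("complex", m = 6L), n, R, seed = 4)
  pc$mats$wr[] <- 0
  expect_equal(score_complex(pc, vi, r, vj), -score_complex(pc, vj, r, vi))
  # ComplEx: purely real relation -> symmetric
  pc2 <- init_params(model_config("complex", m = 6L), n, R, seed = 4)
  pc2$mats$wi[] <- 0
  expect_equal(score_complex(pc2, vi, r, vj), score_complex(pc2, vj, r, vi))
  # SimplE: forced symmetry when Vinv = V and H = T
  ps <- init_params(model_config("simple", m = 6L), n, R, seed = 4)
  ps$mats$Vinv <- ps$mats$V; ps$mats$T <- ps$mats$H
  expect_equal(score_simple(ps, vi, r, vj), score_simple(ps, vj, r, vi))
})

test_that("candidate vectors agree elementwise with scalar calls", {
  n <- 8L; R <- 3L
  for (model in c("distmult", "complex", "simple")) {
    m <- if (model == "complex") 8L else 8L
    p <- init_params(model_config(model, m = m), n, R, seed = 6)
    for (dir in c("tail", "head")) {
      v <- score_candidates(p, 3L, 2L, dir)
      scalar <- if (dir == "tail")
        score_triples(p, cbind(3L, 2L, seq_len(n)))
      else
        score_triples(p, cbind(seq_len(n), 2L, 3L))
      expect_lt(max(abs(v - scalar)), 1e-12)
    }
  }
  # DistMult: tail and head candidate vectors coincide
  pd <- init_params(model_config("distmult", m = 4L), n, R, seed = 6)
  expect_equal(score_candidates(pd, 5L, 1L, "tail"),
               score_candidates(pd, 5L, 1L, "head"))
})

test_that("SimplE and ComplEx can fit an antisymmetric fact but DistMult cannot", {
  # facts: (a, r, b) true, (b, r, a) false
  bce2 <- function(s) loss_bce(s, c(1, 0))
  fit_model <- function(model, m) {
    obj <- function(theta) {
      p <- init_params(model_config(model, m = m), 2L, 1L, seed = 1)
      i <- 0L
      for (nm in names(p$mats)) {
        k <- length(p$mats[[nm]])
        p$mats[[nm]][] <- theta[i + seq_len(k)]
        i <- i + k
      }
      bce2(score_triples(p, rbind(c(1L, 1L, 2L), c(2L, 1L, 1L))))
    }
    n_par <- sum(vapply(init_params(model_config(model, m = m), 2L, 1L,
                                    seed = 1)$mats, length, integer(1L)))
    set.seed(2)
    stats::optim(stats::rnorm(n_par, sd = 0.5), obj, method = "BFGS",
                 control = list(maxit = 500))$value
  }
  expect_lt(fit_model("simple", 2L), 1e-3)
  expect_lt(fit_model("complex", 2L), 1e-3)
  # DistMult: the two scores are identical for all parameter values,
  # so the loss is bounded away from 0
  pd <- init_params(model_config("distmult", m = 4L), 2L, 1L, seed = 3)
  expect_identical(score_distmult(pd, 1L, 1L, 2L), score_distmult(pd, 2L, 1L, 1L))
  expect_gt(fit_model("distmult", 4L), log(2) * 0.49)  # >= ln(2)/2 at optimum
})

test_that("checkpoints round-trip bit-exactly through disk", {
  p <- init_params(model_config("simple", m = 4L), 6L, 2L, seed = 9)
  ck <- list(params = p, epoch = 3L, lr = 0.011, rng = .Random.seed)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  expect_identical(load_checkpoint(path), ck)
})
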