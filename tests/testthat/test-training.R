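test_that("query construction counts follow the strategy definitions", {
  set.seed(3)
  tr <- cbind(sample(6L, 10, TRUE), sample(2L, 10, TRUE), sample(6L, 10, TRUE))
  q1 <- build_queries(tr, "1vsAll", batch_size = 4L, seed = 1)
  expect_equal(sum(lengths(lapply(q1, `[[`, "ent"))), 20L)  # 2 per triple
  # KvsAll groups multi-hot truths
  tr2 <- rbind(c(1L, 1L, 2L), c(1L, 1L, 3L))
  q2 <- build_queries(tr2, "KvsAll", batch_size = 10L, seed = 1)
  b <- q2[[1L]]
  tail_q <- which(b$dir == 1L & b$ent == 1L & b$rel == 1L)
  expect_length(b$truths[[tail_q]], 2L)
  # brute-force key-count oracle on the toy self-loop graph
  g <- build_selfloops(toy_fixture())
  trs <- g$triples
  qk <- build_queries(trs, "KvsAll", batch_size = 1000L, seed = 1)[[1L]]
  expected <- length(unique(paste(trs[, 1L], trs[, 2L]))) +
    length(unique(paste(trs[, 3L], trs[, 2L])))
  expect_length(qk$ent, expected)
})

test_that("losses match their closed forms and limits", {
  expect_equal(loss_bce(rep(0, 5), c(1, 0, 1, 0, 1)), log(2))
  # y = 1, s -> +inf: loss -> 0 monotonically
  ss <- c(0, 2, 5, 10, 20)
  ls <- vapply(ss, function(s) loss_bce(s, 1), double(1L))
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[5], 1e-8)
  # random vector against an independent stable formulation
  set.seed(8)
  s <- rnorm(10, sd = 3); y <- rbinom(10, 1, 0.5)
  ref <- -mean(y * stats::plogis(s, log.p = TRUE) +
                 (1 - y) * stats::plogis(-s, log.p = TRUE))
  expect_lt(abs(loss_bce(s, y) - ref), 1e-12)
  # KL: N equal scores -> ln N; true score dominant -> 0
  expect_equal(loss_kl(rep(1.7, 7), 3L), log(7))
  expect_lt(loss_kl(c(50, 0, 0), 1L), 1e-8)
  set.seed(9)
  s7 <- rnorm(7)
  ref_kl <- -log(exp(s7[4]) / sum(exp(s7)))
  expect_lt(abs(loss_kl(s7, 4L) - ref_kl), 1e-12)
  # extreme scores stay finite
  expect_true(is.finite(loss_bce(c(1e4, -1e4), c(0, 1))))
  expect_true(is.finite(loss_kl(c(1e4, -1e4), 2L)))
})

test_that("early stopping reproduces the schedule bounds", {
  mk <- function(metrics, baseline = 0.10) {
    list(baseline = baseline,
         checks = data.frame(epoch = seq(50, by = 5,
                                         length.out = length(metrics)),
                             metric = metrics))
  }
  # no improvement at checks 50 and 55 -> stop at 55 (the minimum)
  expect_equal(check_early_stop(mk(c(0.08, 0.09))), "stop")
  # improvement at 50, none at 55 -> continue (only one failed check)
  expect_equal(check_early_stop(mk(c(0.12, 0.11))), "continue")
  # two consecutive failures after a peak -> stop
  expect_equal(check_early_stop(mk(c(0.12, 0.11, 0.115))), "stop")
  # monotone improvement through 500 never stops on checks
  metrics <- seq(0.2, 0.9, length.out = 91)  # checks 50, 55, ..., 500
  expect_equal(check_early_stop(mk(metrics)), "continue")
  tc <- train_config()
  expect_equal(tc$max_epochs, 500L)  # the run then ends at max-epochs
  # schedule invariants enforced
  expect_error(train_config(eval_start = 3L, eval_every = 5L), "eval_start")
  expect_error(train_config(max_epochs = 52L), "max_epochs")
})

test_that("lr = 0 leaves parameters unchanged and loss constant", {
  sg <- small_graph()
  split <- suppressWarnings(split_pse_holdout(sg$graph, 0.1, seed = 5))
  ds <- training_dataset(sg$graph, split, seed = 7)
  mc <- model_config("simple", m = 4L)
  tc <- train_config(lr = 0, optimizer = "sgd", max_epochs = 12L,
                     eval_start = 5L, eval_every = 5L, seed = 11)
  fit <- run_training(ds, mc, tc)
  p0 <- init_params(mc, nrow(sg$graph$entities), nrow(sg$graph$relations),
                    seed = 11)
  expect_identical(fit$last$params$mats, p0$mats)
  expect_lt(diff(range(fit$history$epochs$loss)), 1e-12)
})

test_that("identical seeds give identical loss trajectories", {
  sg <- small_graph()
  split <- suppressWarnings(split_pse_holdout(sg$graph, 0.1, seed = 5))
  ds <- training_dataset(sg$graph, split, seed = 7)
  mc <- model_config("simple", m = 4L, dropout_entity = 0.1)
  tc <- train_config(max_epochs = 8L, eval_start = 3L, eval_every = 3L,
                     seed = 13)
  f1 <- run_training(ds, mc, tc)
  f2 <- run_training(ds, mc, tc)
  expect_identical(f1$history$epochs$loss, f2$history$epochs$loss)
})

test_that("resuming from a checkpoint reproduces the next epochs exactly", {
  sg <- small_graph()
  split <- suppressWarnings(split_pse_holdout(sg$graph, 0.1, seed = 5))
  ds <- training_dataset(sg$graph, split, seed = 7)
  mc <- model_config("simple", m = 4L)
  tcA <- train_config(max_epochs = 10L, eval_start = 4L, eval_every = 2L,
                      seed = 17)
  full <- run_training(ds, mc, tcA)
  tcB <- tcA
  tcB$max_epochs <- 7L
  part <- run_training(ds, mc, tcB)
  resumed <- run_training(ds, mc, tcA, resume_from = part$last)
  got <- c(part$history$epochs$loss,
           utils::tail(resumed$history$epochs$loss,
                       nrow(full$history$epochs) -
                         nrow(part$history$epochs)))
  expect_equal(got, full$history$epochs$loss, tolerance = 1e-12)
})

test_that("training reduces the loss for every model, strategy and loss pairing", {
  sg <- small_graph()
  split <- suppressWarnings(split_pse_holdout(sg$graph, 0.1, seed = 5))
  ds <- training_dataset(sg$graph, split, seed = 7)
  combos <- list(list("1vsAll", "kl"), list("KvsAll", "bce"),
                 list("1vsAll", "margin"), list("KvsAll", "se"))
  for (model in c("distmult", "complex", "simple")) {
    for (cb in combos) {
      mc <- model_config(model, m = 4L)
      tc <- train_config(strategy = cb[[1L]], loss = cb[[2L]], lr = 0.02,
                         max_epochs = 10L, eval_start = 5L, eval_every = 5L,
                         patience_checks = 5L, seed = 19)
      fit <- run_training(ds, mc, tc)
      losses <- fit$history$epochs$loss
      expect_lt(stats::median(losses[-1L]), losses[1L],
                label = paste(model, cb[[1L]], cb[[2L]], "median loss"))
    }
  }
})

test_that("KvsAll+BCE and 1vsAll+KL both rank the unique true tail first", {
  # 3 entities, 1 relation, each subject has exactly one true tail
  entities <- data.frame(id = c("a", "b", "c"), type = "Drug",
                         stringsAsFactors = FALSE)
  # a directional role so pairs are not reverse-materialized and each
  # (subject, relation) keeps exactly one true tail
  relations <- data.frame(id = "r", role = "TARGET", stringsAsFactors = FALSE)
  triples <- rbind(c(1L, 1L, 2L), c(2L, 1L, 3L), c(3L, 1L, 1L))
  g <- psetf:::new_triple_graph(entities, relations, triples)
  ds <- list(graph = g, train = triples,
             valid = triples[0L, , drop = FALSE])
  for (setting in list(c("KvsAll", "bce"), c("1vsAll", "kl"))) {
    mc <- model_config("simple", m = 4L)
    tc <- train_config(strategy = setting[1L], loss = setting[2L],
                       optimizer = "adam", lr = 0.05, max_epochs = 300L,
                       eval_start = 250L, eval_every = 50L, seed = 23)
    fit <- run_training(ds, mc, tc)
    p <- fit$last$params
    for (i in 1:3) {
      sc <- score_candidates(p, triples[i, 1L], 1L, "tail")
      expect_equal(which.max(sc), triples[i, 3L],
                   label = paste(setting[1L], "subject", i))
    }
  }
})

test_that("divergence aborts with an epoch/batch diagnostic", {
  sg <- small_graph()
  split <- suppressWarnings(split_pse_holdout(sg$graph, 0.1, seed = 5))
  ds <- training_dataset(sg$graph, split, seed = 7)
  mc <- model_config("simple", m = 4L)
  tc <- train_config(optimizer = "sgd", lr = 1e4, max_epochs = 12L,
                     eval_start = 5L, eval_every = 5L, seed = 29)
  expect_error(run_training(ds, mc, tc), "non-finite loss at epoch")
})
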