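test_that("the Sobol generator reproduces the reference sequence", {
  # frozen from an independent reference implementation (unscrambled,
  # Joe-Kuo direction numbers), first 8 points in 3 dimensions
  expected <- matrix(c(
    0,     0,     0,
    0.5,   0.5,   0.5,
    0.75,  0.25,  0.25,
    0.25,  0.75,  0.75,
    0.375, 0.375, 0.625,
    0.875, 0.875, 0.125,
    0.625, 0.125, 0.875,
    0.125, 0.625, 0.375), ncol = 3L, byrow = TRUE)
  expect_equal(sobol_points(8L, 3L, skip = 0L), expected)
  # 10-dimensional spot check (row 5 of the reference)
  expect_equal(sobol_points(5L, 10L, skip = 0L)[5L, ],
               c(0.375, 0.375, 0.625, 0.875, 0.375, 0.125, 0.375, 0.875,
                 0.875, 0.625))
  # origin-skipped 1-d prefix used by the search phase
  expect_equal(sobol_points(4L, 1L, skip = 1L)[, 1L],
               c(0.5, 0.75, 0.25, 0.375))
})

test_that("16 two-dimensional Sobol points balance every dyadic box", {
  p <- sobol_points(16L, 2L, skip = 0L)
  # 2x2 quadrants: exactly 4 points each
  q <- table(floor(p[, 1L] * 2), floor(p[, 2L] * 2))
  expect_true(all(q == 4L))
  # finer elementary intervals: 4x1, 1x4, 4x4, 2x8 strata
  expect_true(all(table(floor(p[, 1L] * 4)) == 4L))
  expect_true(all(table(floor(p[, 2L] * 4)) == 4L))
  expect_true(all(table(floor(p[, 1L] * 4), floor(p[, 2L] * 4)) == 1L))
  expect_true(all(table(floor(p[, 1L] * 2), floor(p[, 2L] * 8)) == 1L))
})

test_that("search-space validation and projection work", {
  expect_error(search_space(lr = list(kind = "log-real", lower = 0,
                                      upper = 1)), "positive")
  expect_error(search_space(x = list(kind = "real", lower = 2, upper = 1)),
               "lower < upper")
  space <- default_search_space()
  cfgs <- sobol_phase(space, 50L)
  for (cfg in cfgs) expect_true(psetf:::validate_config(space, cfg))
  # log-real mapping spans the decades
  lrs <- vapply(cfgs, `[[`, double(1L), "lr")
  expect_lt(min(lrs), 1e-3)
  expect_gt(max(lrs), 0.1)
  # projection repairs conditional parameters
  fixed <- psetf:::project_config(list(init = "feature", loss = "kl",
                                       strategy = "KvsAll", m = 33L),
                                  "complex", features = NULL)
  expect_equal(fixed$init, "normal")
  expect_equal(fixed$loss, "bce")
  expect_equal(fixed$m %% 2L, 0L)
})

test_that("the surrogate proposes near the optimum of a smooth metric", {
  sp <- search_space(x = list(kind = "real", lower = 0, upper = 1))
  hist <- lapply(seq(0.05, 0.95, length.out = 20), function(x)
    list(config = list(x = x), metric = -(x - 0.3)^2, status = "ok"))
  for (s in 1:3) {
    prop <- bayes_phase(sp, hist, seed = s)
    expect_gte(prop$x, 0.1)
    expect_lte(prop$x, 0.5)
  }
  # a single observed trial still yields a valid configuration
  one <- bayes_phase(sp, hist[1L], seed = 1)
  expect_true(psetf:::validate_config(sp, one))
  # degenerate history (all metrics equal) still yields a valid proposal
  flat <- lapply(hist, function(h) { h$metric <- 0.5; h })
  expect_true(psetf:::validate_config(sp, bayes_phase(sp, flat, seed = 1)))
  # all-diverged history falls back to Sobol continuation with a warning
  dead <- lapply(hist[1:3], function(h) { h$status <- "diverged"; h })
  expect_warning(fb <- bayes_phase(sp, dead, seed = 1), "Sobol")
  expect_true(psetf:::validate_config(sp, fb))
})

test_that("proposals avoid re-evaluating exhausted categorical configurations", {
  sp <- search_space(a = list(kind = "categorical", values = c("x", "y")),
                     b = list(kind = "categorical", values = c(1L, 2L)))
  hist <- list(
    list(config = list(a = "x", b = 1L), metric = 0.9, status = "ok"),
    list(config = list(a = "x", b = 2L), metric = 0.3, status = "ok"),
    list(config = list(a = "y", b = 1L), metric = 0.2, status = "ok"))
  for (s in 1:5) {
    prop <- bayes_phase(sp, hist, seed = s)
    expect_equal(prop, list(a = "y", b = 2L))  # the only untried combo
  }
})

test_that("run_search keeps dense trial records and resumes from file", {
  sg <- small_graph()
  split <- suppressWarnings(split_pse_holdout(sg$graph, 0.1, seed = 5))
  ds <- training_dataset(sg$graph, split, seed = 7)
  space <- search_space(
    m = list(kind = "categorical", values = c(4L, 8L)),
    lr = list(kind = "log-real", lower = 1e-3, upper = 1e-1))
  base <- train_config(max_epochs = 8L, eval_start = 3L, eval_every = 3L)
  hf <- withr::local_tempfile(fileext = ".jsonl")
  out <- run_search(ds, "simple", space, n_sobol = 3L, n_bayes = 2L,
                    seed = 21, base_train = base, history_file = hf)
  expect_length(out$history, 5L)
  expect_equal(vapply(out$history, `[[`, integer(1L), "trial"), 0:4)
  metrics <- vapply(out$history, `[[`, double(1L), "metric")
  expect_equal(out$best$metric, max(metrics, na.rm = TRUE))
  expect_length(readLines(hf), 5L)
  # resume: nothing is re-run, results identical
  t0 <- Sys.time()
  out2 <- run_search(ds, "simple", space, n_sobol = 3L, n_bayes = 2L,
                     seed = 21, base_train = base, history_file = hf)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(out2$best$metric, out$best$metric)
  # phase boundary: trials 0..2 are exactly the Sobol prefix
  sobol_prefix <- sobol_phase(space, 3L)
  for (i in 1:3)
    expect_equal(out$history[[i]]$config$m, sobol_prefix[[i]]$m)
})

test_that("the search prefers capacity matching the planted rank", {
  # rank-8 structure: m = 16 should beat m = 4 for most search seeds
  spec <- synthetic_spec(n_drugs = 50L, n_genes = 15L, n_pse_types = 6L,
                         n_mono_types = 10L, latent_rank = 8L,
                         pse_density = 0.1, seed = 3L)
  raw <- synthesize_raw_tables(make_planted_model(spec), spec)
  g <- build_selfloops(raw)
  split <- suppressWarnings(split_pse_holdout(g, 0.1, seed = 5))
  ds <- training_dataset(g, split, seed = 7)
  space <- search_space(
    m = list(kind = "categorical", values = c(4L, 16L)),
    lr = list(kind = "log-real", lower = 1e-3, upper = 1e-1))
  base <- train_config(max_epochs = 10L, eval_start = 5L, eval_every = 5L)
  wins <- vapply(1:3, function(s) {
    out <- run_search(ds, "simple", space, n_sobol = 10L, n_bayes = 5L,
                      seed = 100L + s, base_train = base)
    out$best$config$m == 16L
  }, logical(1L))
  expect_gte(sum(wins), 2L)
})
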