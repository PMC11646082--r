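test_that("unordered pair records deduplicate on load", {
  dir <- withr::local_tempdir()
  writeLines(c("STITCH 1,STITCH 2,Polypharmacy Side Effect,Side Effect Name",
               "A,B,se1,x", "B,A,se1,x", "A,B,se2,y"),
             file.path(dir, "combo.csv"))
  writeLines("STITCH,Individual Side Effect,Side Effect Name",
             file.path(dir, "mono.csv"))
  writeLines(c("STITCH,Gene", "A,G1"), file.path(dir, "targets.csv"))
  writeLines(c("Gene 1,Gene 2", "G1,G2"), file.path(dir, "ppi.csv"))
  raw <- suppressWarnings(suppressMessages(
    read_raw_tables(file.path(dir, "combo.csv"), file.path(dir, "mono.csv"),
                    file.path(dir, "targets.csv"), file.path(dir, "ppi.csv"))))
  expect_equal(nrow(raw$pse), 2L)  # (A,B,se1) stored once
  expect_equal(raw$pse$drug_a, c("A", "A"))
})

test_that("missing columns are reported with file and column name", {
  dir <- withr::local_tempdir()
  writeLines(c("STITCH 1,Polypharmacy Side Effect", "A,se1"),
             file.path(dir, "combo.csv"))
  expect_error(
    read_raw_tables(file.path(dir, "combo.csv"), "x", "y", "z"),
    "combo.csv.*STITCH 2")
})

test_that("selfloops construction follows the counting rules", {
  raw <- toy_fixture()
  g <- build_selfloops(raw)
  expect_equal(nrow(g$triples), 12L)
  expect_equal(nrow(g$relations), 7L)  # 2 PSE + 3 mono + TARGET + PPI
  # mono records become self-loops on drug nodes
  mono_rows <- g$relations$role[g$triples[, 2L]] == "MONO"
  expect_true(all(g$triples[mono_rows, 1L] == g$triples[mono_rows, 3L]))
  expect_true(all(g$entities$type[g$triples[mono_rows, 1L]] == "Drug"))
  # meta-node typing of every role
  roles <- g$relations$role[g$triples[, 2L]]
  stype <- g$entities$type[g$triples[, 1L]]
  otype <- g$entities$type[g$triples[, 3L]]
  expect_true(all(stype[roles == "PSE"] == "Drug" & otype[roles == "PSE"] == "Drug"))
  expect_true(all(stype[roles == "TARGET"] == "Drug" & otype[roles == "TARGET"] == "Gene"))
  expect_true(all(stype[roles == "PPI"] == "Gene" & otype[roles == "PPI"] == "Gene"))
})

test_that("nonnaive variant drops mono edges into an n-hot feature matrix", {
  raw <- toy_fixture()
  nn <- build_nonnaive(raw)
  expect_equal(nrow(nn$graph$triples), 9L)
  expect_equal(dim(nn$features), c(4L, 3L))
  expect_equal(sum(nn$features), 3)
  # a drug with no mono records has an all-zero feature row
  expect_equal(unname(nn$features["D3", ]), c(0, 0, 0))
  # edge accounting across variants
  g <- build_selfloops(raw)
  expect_equal(nrow(g$triples) - nrow(nn$graph$triples), nrow(raw$mono))
})

test_that("both variants share the PSE/TARGET/PPI triple set and vocabularies", {
  sg <- small_graph()
  g1 <- sg$graph
  nn <- build_nonnaive(sg$raw)
  expect_identical(g1$entities, nn$graph$entities)
  core <- g1$relations$role[g1$triples[, 2L]] != "MONO"
  key <- function(g, rows) paste(g$entities$id[g$triples[rows, 1L]],
                                 g$relations$id[g$triples[rows, 2L]],
                                 g$entities$id[g$triples[rows, 3L]])
  expect_setequal(key(g1, which(core)),
                  key(nn$graph, seq_len(nrow(nn$graph$triples))))
  expect_equal(nrow(g1$triples) - nrow(nn$graph$triples), nrow(sg$raw$mono))
})

test_that("feature reduction matches an eigendecomposition oracle", {
  set.seed(42)
  F <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30)
  m <- 5L
  scores <- reduce_features(F, m)
  # oracle: eigendecomposition of the covariance of centered columns
  Fc <- scale(F, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Fc), symmetric = TRUE)
  oracle <- Fc %*% eg$vectors[, 1:m]
  # compare up to per-column sign after matching the overall rescale
  for (j in 1:m) {
    a <- scores[, j] / sqrt(sum(scores[, j]^2))
    b <- oracle[, j] / sqrt(sum(oracle[, j]^2))
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  # sign convention: largest-magnitude loading positive => deterministic
  expect_identical(scores, reduce_features(F, m))
})

test_that("centered 2x2 identity gives antisymmetric one-component scores", {
  s <- reduce_features(diag(2), 1L)
  expect_equal(s[1, 1], -s[2, 1])
  expect_gt(abs(s[1, 1]), 0)
})

test_that("PCA reconstruction error is monotone in the component count", {
  set.seed(7)
  F <- matrix(rbinom(15 * 12, 1, 0.4), 15, 12)
  Fc <- scale(F, center = TRUE, scale = FALSE)
  sv <- svd(Fc)
  err <- vapply(1:5, function(k) {
    rec <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    sum((Fc - rec)^2)
  }, double(1L))
  expect_true(all(diff(err) <= 1e-10))
  # m beyond rank: random fallback with warning, full width returned
  expect_warning(out <- reduce_features(diag(3), 3L), "rank")
  expect_equal(ncol(out), 3L)
})

test_that("dataset directory round-trips and empty holdout yields empty test file", {
  sg <- small_graph()
  g <- sg$graph
  split <- suppressWarnings(split_pse_holdout(g, 0.1, seed = 5))
  gtrain <- psetf:::new_triple_graph(g$entities, g$relations, split$train)
  dir <- withr::local_tempdir()
  write_kge_dataset(gtrain, dir, holdout = split$holdout)
  back <- read_kge_dataset(dir)
  expect_identical(back$graph$entities, gtrain$entities)
  expect_identical(back$graph$relations, gtrain$relations)
  expect_identical(back$graph$triples, gtrain$triples)
  expect_identical(back$test, split$holdout)
  # overlap between graph and holdout is rejected
  expect_error(write_kge_dataset(g, withr::local_tempdir(),
                                 holdout = split$holdout), "disjoint")
  # empty holdout: test file exists and is empty
  dir2 <- withr::local_tempdir()
  write_kge_dataset(gtrain, dir2)
  expect_true(file.exists(file.path(dir2, "test.txt")))
  expect_equal(file.size(file.path(dir2, "test.txt")), 0)
  # byte-identical rebuild (vocabulary stability)
  dir3 <- withr::local_tempdir()
  write_kge_dataset(psetf:::new_triple_graph(g$entities, g$relations,
                                             split$train),
                    dir3, holdout = split$holdout)
  for (f in c("train.txt", "test.txt", "entity_ids.del", "relation_ids.del"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir3, f)))
})
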