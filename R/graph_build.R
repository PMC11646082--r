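# Raw-table container and the two graph constructions.
#
# The knowledge graph has two meta-nodes (Drug, Gene) and four edge roles:
# PSE   drug--drug, one relation per pair side-effect type
# MONO  drug self-loops, one relation per single-drug side-effect type
#       (present only in the "selfloops" variant)
# TARGET drug--gene, a single relation
# PPI   gene--gene, a single relation

default_init_sd <- 0.1

# Construct a validated raw_tables object: duplicates dropped, unordered
# pairs stored canonically (lexicographically smaller id first), self-pairs
# rejected for PSE and PPI.
new_raw_tables <- function(pse, mono, targets, ppi, quiet = TRUE) {
  cp <- canonical_pairs(pse$drug_a, pse$drug_b)
  self <- cp$a == cp$b
  if (any(self)) {
    if (!quiet) message(sum(self), " self-pair PSE record(s) dropped")
    cp$a <- cp$a[!self]; cp$b <- cp$b[!self]
    pse <- pse[!self, , drop = FALSE]
  }
  pse$drug_a <- cp$a; pse$drug_b <- cp$b
  dup <- duplicated(pse[c("drug_a", "drug_b", "se_type")])
  if (!quiet && any(dup)) message(sum(dup), " duplicate PSE record(s) dropped")
  pse <- pse[!dup, , drop = FALSE]

  mono <- mono[!duplicated(mono[c("drug", "se_type")]), , drop = FALSE]
  targets <- targets[!duplicated(targets[c("drug", "gene")]), , drop = FALSE]

  gp <- canonical_pairs(ppi$gene_a, ppi$gene_b)
  gself <- gp$a == gp$b
  ppi <- ppi[!gself, , drop = FALSE]
  ppi$gene_a <- gp$a[!gself]; ppi$gene_b <- gp$b[!gself]
  ppi <- ppi[!duplicated(ppi[c("gene_a", "gene_b")]), , drop = FALSE]

  rownames(pse) <- rownames(mono) <- rownames(targets) <- rownames(ppi) <- NULL
  structure(list(pse = pse, mono = mono, targets = targets, ppi = ppi),
            class = "raw_tables")
}

#' @export
print.raw_tables <- function(x, ...) {
  cat("raw_tables:",
      nrow(x$pse), "pair side-effect records (",
      length(unique(x$pse$se_type)), "types ),",
      nrow(x$mono), "monopharmacy records,",
      nrow(x$targets), "drug-target records,",
      nrow(x$ppi), "protein-interaction records\n")
  invisible(x)
}

read_one_table <- function(path, required, rename) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop(sprintf("file '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(dt) == 0L) warning("empty table: ", path, call. = FALSE)
  out <- as.data.frame(dt[, required, with = FALSE])
  names(out) <- rename
  out
}

#' Read the four raw polypharmacy tables
#'
#' Parses the downloadable-data CSV dialect (header row required, extra
#' columns ignored): the drug-pair side-effect file with columns
#' `STITCH 1, STITCH 2, Polypharmacy Side Effect, Side Effect Name`; the
#' monopharmacy file with `STITCH, Individual Side Effect, Side Effect
#' Name`; the target file with `STITCH, Gene`; and the
#' protein-interaction file with `Gene 1, Gene 2`.  Records are
#' deduplicated, unordered pairs canonicalized and self-pairs dropped.
#'
#' @param combo_file,mono_file,targets_file,ppi_file File paths.
#' @param min_pse_count Optional minimum number of records a pair
#'   side-effect type must have to be retained (0 = keep all; the
#'   commonly used occurrence filter in this literature is 500).
#' @return A `raw_tables` object.
#' @export
read_raw_tables <- function(combo_file, mono_file, targets_file, ppi_file,
                            min_pse_count = 0L) {
  pse <- read_one_table(combo_file,
                        c("STITCH 1", "STITCH 2", "Polypharmacy Side Effect",
                          "Side Effect Name"),
                        c("drug_a", "drug_b", "se_type", "se_name"))
  mono <- read_one_table(mono_file,
                         c("STITCH", "Individual Side Effect", "Side Effect Name"),
                         c("drug", "se_type", "se_name"))
  targets <- read_one_table(targets_file, c("STITCH", "Gene"), c("drug", "gene"))
  ppi <- read_one_table(ppi_file, c("Gene 1", "Gene 2"), c("gene_a", "gene_b"))
  raw <- new_raw_tables(pse, mono, targets, ppi, quiet = FALSE)
  if (min_pse_count > 0L) {
    keep_types <- names(which(table(raw$pse$se_type) >= min_pse_count))
    raw$pse <- raw$pse[raw$pse$se_type %in% keep_types, , drop = FALSE]
    rownames(raw$pse) <- NULL
  }
  raw
}

new_triple_graph <- function(entities, relations, triples) {
  stopifnot(all(triples[, 1L] >= 1L), all(triples[, 1L] <= nrow(entities)),
            all(triples[, 3L] >= 1L), all(triples[, 3L] <= nrow(entities)),
            all(triples[, 2L] >= 1L), all(triples[, 2L] <= nrow(relations)))
  colnames(triples) <- c("s", "r", "o")
  structure(list(entities = entities, relations = relations,
                 triples = triples),
            class = "triple_graph")
}

#' @export
print.triple_graph <- function(x, ...) {
  cat("triple_graph:", nrow(x$entities), "entities (",
      sum(x$entities$type == "Drug"), "drugs,",
      sum(x$entities$type == "Gene"), "genes ),",
      nrow(x$relations), "relations,", nrow(x$triples), "triples\n")
  invisible(x)
}

# Shared vocabulary builder: sorted drug ids first, then sorted gene ids;
# relations are sorted PSE types, then (optionally) sorted mono types, then
# TARGET and PPI.  Sorting makes index assignment deterministic so repeated
# builds of the same raw data are byte-identical on disk.
graph_vocab <- function(raw, with_mono_relations) {
  drugs <- sort(unique(c(raw$pse$drug_a, raw$pse$drug_b,
                         raw$mono$drug, raw$targets$drug)))
  genes <- sort(unique(c(raw$targets$gene, raw$ppi$gene_a, raw$ppi$gene_b)))
  entities <- data.frame(id = c(drugs, genes),
                         type = rep(c("Drug", "Gene"),
                                    c(length(drugs), length(genes))),
                         stringsAsFactors = FALSE)
  pse_types <- sort(unique(raw$pse$se_type))
  rel_id <- pse_types
  rel_role <- rep("PSE", length(pse_types))
  if (with_mono_relations) {
    mono_types <- sort(unique(raw$mono$se_type))
    rel_id <- c(rel_id, mono_types)
    rel_role <- c(rel_role, rep("MONO", length(mono_types)))
  }
  rel_id <- c(rel_id, "TARGET", "PPI")
  rel_role <- c(rel_role, "TARGET", "PPI")
  relations <- data.frame(id = rel_id, role = rel_role, stringsAsFactors = FALSE)
  list(entities = entities, relations = relations,
       ent_index = stats::setNames(seq_along(entities$id), entities$id),
       rel_index = stats::setNames(seq_len(nrow(relations)), relations$id))
}

core_triples <- function(raw, v) {
  rbind(
    cbind(v$ent_index[raw$pse$drug_a], v$rel_index[raw$pse$se_type],
          v$ent_index[raw$pse$drug_b]),
    cbind(v$ent_index[raw$targets$drug], v$rel_index["TARGET"],
          v$ent_index[raw$targets$gene]),
    cbind(v$ent_index[raw$ppi$gene_a], v$rel_index["PPI"],
          v$ent_index[raw$ppi$gene_b])
  )
}

#' Build the self-loop graph variant
#'
#' Every record becomes one triple; monopharmacy records become
#' self-loop triples `(drug, mono_type, drug)` with one relation per
#' monopharmacy side-effect type.  Relation count is therefore
#' `|PSE types| + |mono types| + 2`.
#'
#' @param raw A `raw_tables` object.
#' @return A `triple_graph`.
#' @export
build_selfloops <- function(raw) {
  stopifnot(inherits(raw, "raw_tables"))
  v <- graph_vocab(raw, with_mono_relations = TRUE)
  triples <- rbind(core_triples(raw, v),
                   cbind(v$ent_index[raw$mono$drug],
                         v$rel_index[raw$mono$se_type],
                         v$ent_index[raw$mono$drug]))
  storage.mode(triples) <- "integer"
  rownames(triples) <- NULL
  new_triple_graph(v$entities, v$relations, triples)
}

#' Build the feature-vector graph variant
#'
#' Monopharmacy data is excluded from the edge list and returned instead
#' as an n-hot drug-by-type indicator matrix, intended to initialize drug
#' embeddings after PCA reduction (see [reduce_features()]).  The triple
#' set is exactly the self-loop variant minus the mono self-loops, and
#' drugs appearing only in the mono table remain in the entity
#' vocabulary so both variants index entities identically.
#'
#' @param raw A `raw_tables` object.
#' @return A list with elements `graph` (a `triple_graph`) and
#'   `features` (the 0/1 feature matrix, drugs x mono types).
#' @export
build_nonnaive <- function(raw) {
  stopifnot(inherits(raw, "raw_tables"))
  v <- graph_vocab(raw, with_mono_relations = FALSE)
  triples <- core_triples(raw, v)
  storage.mode(triples) <- "integer"
  rownames(triples) <- NULL
  graph <- new_triple_graph(v$entities, v$relations, triples)

  drugs <- v$entities$id[v$entities$type == "Drug"]
  mono_types <- sort(unique(raw$mono$se_type))
  F <- matrix(0, length(drugs), length(mono_types),
              dimnames = list(drugs, mono_types))
  F[cbind(match(raw$mono$drug, drugs), match(raw$mono$se_type, mono_types))] <- 1
  list(graph = graph, features = F)
}

#' Reduce n-hot drug features to an embedding-sized initialization matrix
#'
#' Principal-component scores of the column-centered feature matrix,
#' computed by truncated SVD (centered SVD and PCA coincide), keeping the
#' `m` leading components.  Component signs are fixed by the convention
#' that the largest-magnitude loading of each component is positive.  The
#' score matrix is rescaled so its overall entry standard deviation
#' equals the default random-initialization scale of the factorization
#' models (0.1), keeping feature-based and random starts comparable.
#' When `m` exceeds the matrix rank the remaining columns are filled with
#' normal draws at that same scale (with a warning).
#'
#' @param F Drug-by-type 0/1 feature matrix.
#' @param m Number of components (1 to `nrow(F)`).
#' @param seed Seed for the random fallback columns.
#' @return An `nrow(F) x m` initialization matrix with `F`'s rownames.
#' @export
reduce_features <- function(F, m, seed = 1L) {
  m <- check_count(m, "m")
  if (m > nrow(F)) stop("'m' must not exceed the number of drugs", call. = FALSE)
  Fc <- scale(F, center = TRUE, scale = FALSE)
  sv <- svd(Fc)
  rank <- sum(sv$d > max(dim(F)) * .Machine$double.eps * max(sv$d, 1))
  k <- min(m, rank)
  scores <- matrix(0, nrow(F), 0L)
  if (k > 0L) {
    V <- sv$v[, seq_len(k), drop = FALSE]
    flip <- vapply(seq_len(k), function(j) {
      lead <- which.max(abs(V[, j]))
      sign(V[lead, j]) < 0
    }, logical(1L))
    scores <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)] * ifelse(flip, -1, 1), nrow = k)
    sd0 <- stats::sd(as.vector(scores))
    if (sd0 > 0) scores <- scores * (default_init_sd / sd0)
  }
  if (k < m) {
    warning(sprintf("requested m=%d exceeds feature rank %d; %d column(s) filled randomly",
                    m, rank, m - k), call. = FALSE)
    fill <- with_seed(derive_seed(seed, 17L),
                      matrix(stats::rnorm(nrow(F) * (m - k), sd = default_init_sd),
                             nrow(F), m - k))
    scores <- cbind(scores, fill)
  }
  rownames(scores) <- rownames(F)
  colnames(scores) <- NULL
  scores
}

# --- on-disk dataset (RDF-triple dialect) ------------------------------------

#' Write a graph as an on-disk triple dataset
#'
#' Writes `train.txt`, `valid.txt` and `test.txt` as tab-separated
#' `subject<TAB>predicate<TAB>object` string triples, 0-based index maps
#' `entity_ids.del` and `relation_ids.del` (`index<TAB>id`), side files
#' `entity_meta.tsv` / `relation_meta.tsv` carrying the meta-node and
#' role tags, and a `dataset.yaml` metadata file with the counts.
#' Reading the directory back with [read_kge_dataset()] reproduces the
#' graph exactly.
#'
#' @param graph A `triple_graph` whose triples form the training set.
#' @param dir Output directory.
#' @param holdout Optional matrix of held-out (test) triples; must be
#'   disjoint from `graph$triples`.
#' @param valid Optional matrix of validation triples; must be disjoint
#'   from both other sets.
#' @return Invisibly, `dir`.
#' @export
write_kge_dataset <- function(graph, dir, holdout = NULL, valid = NULL) {
  stopifnot(inherits(graph, "triple_graph"))
  key <- function(tr) paste(tr[, 1L], tr[, 2L], tr[, 3L])
  if (!is.null(holdout) && nrow(holdout) &&
      any(key(holdout) %in% key(graph$triples)))
    stop("holdout triples must be disjoint from the graph's triples",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)

  write_split <- function(tr, file) {
    ents <- graph$entities$id; rels <- graph$relations$id
    if (is.null(tr) || nrow(tr) == 0L) {
      cat("", file = file.path(dir, file))
      return(0L)
    }
    if (any(tr[, c(1L, 3L)] > length(ents)) || any(tr[, 2L] > length(rels)))
      stop("dangling index in triples for ", file, call. = FALSE)
    data.table::fwrite(
      data.table::data.table(s = ents[tr[, 1L]], p = rels[tr[, 2L]],
                             o = ents[tr[, 3L]]),
      file.path(dir, file), sep = "\t", col.names = FALSE, quote = FALSE)
    nrow(tr)
  }
  n_train <- write_split(graph$triples, "train.txt")
  n_valid <- write_split(valid, "valid.txt")
  n_test <- write_split(holdout, "test.txt")

  data.table::fwrite(
    data.table::data.table(i = seq_len(nrow(graph$entities)) - 1L,
                           id = graph$entities$id),
    file.path(dir, "entity_ids.del"), sep = "\t", col.names = FALSE, quote = FALSE)
  data.table::fwrite(
    data.table::data.table(i = seq_len(nrow(graph$relations)) - 1L,
                           id = graph$relations$id),
    file.path(dir, "relation_ids.del"), sep = "\t", col.names = FALSE, quote = FALSE)
  data.table::fwrite(
    data.table::data.table(i = seq_len(nrow(graph$entities)) - 1L,
                           id = graph$entities$id, type = graph$entities$type),
    file.path(dir, "entity_meta.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(
    data.table::data.table(i = seq_len(nrow(graph$relations)) - 1L,
                           id = graph$relations$id, role = graph$relations$role),
    file.path(dir, "relation_meta.tsv"), sep = "\t", quote = FALSE)
  yaml::write_yaml(list(
    name = "psetf-dataset",
    num_entities = nrow(graph$entities),
    num_relations = nrow(graph$relations),
    files = list(train = n_train, valid = n_valid, test = n_test)
  ), file.path(dir, "dataset.yaml"))
  invisible(dir)
}

#' Read back an on-disk triple dataset
#'
#' @param dir A directory written by [write_kge_dataset()].
#' @return A list: `graph` (the training `triple_graph`), `valid` and
#'   `test` triple matrices (possibly 0-row).
#' @export
read_kge_dataset <- function(dir) {
  emeta <- data.table::fread(file.path(dir, "entity_meta.tsv"),
                             colClasses = "character")
  rmeta <- data.table::fread(file.path(dir, "relation_meta.tsv"),
                             colClasses = "character")
  entities <- data.frame(id = emeta$id, type = emeta$type,
                         stringsAsFactors = FALSE)
  relations <- data.frame(id = rmeta$id, role = rmeta$role,
                          stringsAsFactors = FALSE)
  ent_index <- stats::setNames(seq_len(nrow(entities)), entities$id)
  rel_index <- stats::setNames(seq_len(nrow(relations)), relations$id)
  read_split <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path) || file.size(path) == 0L)
      return(matrix(integer(), 0L, 3L, dimnames = list(NULL, c("s", "r", "o"))))
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = "character")
    m <- cbind(ent_index[dt$V1], rel_index[dt$V2], ent_index[dt$V3])
    if (anyNA(m)) stop("dangling id in ", file, call. = FALSE)
    storage.mode(m) <- "integer"
    colnames(m) <- c("s", "r", "o")
    rownames(m) <- NULL
    m
  }
  graph <- new_triple_graph(entities, relations, read_split("train.txt"))
  list(graph = graph, valid = read_split("valid.txt"),
       test = read_split("test.txt"))
}
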