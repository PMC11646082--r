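# End-to-end orchestration: build both graph variants from one raw-table
# read, share a single holdout, run every model x variant cell, and the
# per-epoch performance-curve analysis.

#' Configure an end-to-end experiment
#'
#' @param raw Either a `raw_tables` object, a [synthetic_spec()] (tables
#'   are generated), or a named list/vector of the four raw CSV paths
#'   (`combo`, `mono`, `targets`, `ppi`).
#' @param variants Subset of `c("selfloops", "nonnaive")`.
#' @param models Subset of `c("simple", "complex", "distmult")`.
#' @param holdout_fraction Fraction of each pair-side-effect relation
#'   held out (default 0.1).
#' @param mconfig Base [model_config()] applied to every cell (its
#'   `model` field is overridden per cell; `init` becomes `"feature"`
#'   automatically for the nonnaive variant when `feature_init`).
#' @param tconfig Base [train_config()] applied to every cell.
#' @param feature_init Initialize nonnaive-cell embeddings from the
#'   PCA-reduced monopharmacy features (the variant's defining option).
#' @param seed Master seed; build/split/train/eval seeds are derived
#'   from it and recorded in the result.
#' @param per_epoch_curve Keep per-epoch snapshots in each cell so
#'   [per_epoch_curve()] can be applied afterwards.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(raw, variants = c("selfloops", "nonnaive"),
                              models = c("simple", "complex", "distmult"),
                              holdout_fraction = 0.1,
                              mconfig = model_config("simple", m = 16L),
                              tconfig = NULL, feature_init = TRUE,
                              seed = 1L, per_epoch_curve = FALSE) {
  variants <- match.arg(variants, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  if (!length(variants) || !length(models))
    stop("need at least one variant and one model", call. = FALSE)
  structure(list(raw = raw, variants = variants, models = models,
                 holdout_fraction = check_fraction(holdout_fraction,
                                                   "holdout_fraction"),
                 mconfig = mconfig,
                 tconfig = tconfig %||%
                   train_config(max_epochs = 20L, eval_start = 10L,
                                eval_every = 5L),
                 feature_init = isTRUE(feature_init),
                 seed = check_count(seed, "seed", min = 0L),
                 per_epoch_curve = isTRUE(per_epoch_curve)),
            class = "experiment_config")
}

resolve_raw <- function(raw) {
  if (inherits(raw, "raw_tables")) return(raw)
  if (inherits(raw, "synthetic_spec"))
    return(synthesize_raw_tables(make_planted_model(raw), raw))
  if (is.list(raw) || is.character(raw))
    return(read_raw_tables(raw[["combo"]], raw[["mono"]],
                           raw[["targets"]], raw[["ppi"]]))
  stop("cannot interpret 'raw' input", call. = FALSE)
}

#' Run the model-by-variant comparison
#'
#' Builds both graph variants from a single raw-table read, computes one
#' shared per-side-effect holdout (both variants contain the same
#' drug-pair data, so the same edges are removed from each), trains
#' every requested model on every requested variant, evaluates each cell
#' on the same labelled holdout pairs, and assembles a combined ranking
#' table of median AUROC/AUPRC/AP@50.  A failure in one cell is
#' recorded and the remaining cells proceed.  A boolean diagnostic
#' reports whether the cell ranking is identical under all three
#' metrics (an empirical observation, not an invariant).
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for JSON reports and the combined
#'   TSV table.
#' @param verbose Print progress.
#' @return A list: `cells` (per-cell fits and `eval_report`s), `table`
#'   (combined medians data frame), `rank_consistent` (logical),
#'   `split`, `seeds`, and `failures`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- list(build = config$seed,
                split = derive_seed(config$seed, 1L),
                valid = derive_seed(config$seed, 2L),
                train = derive_seed(config$seed, 3L),
                negatives = derive_seed(config$seed, 4L))
  raw <- resolve_raw(config$raw)
  builds <- list()
  if ("selfloops" %in% config$variants)
    builds$selfloops <- list(graph = build_selfloops(raw), features = NULL)
  if ("nonnaive" %in% config$variants) {
    nn <- build_nonnaive(raw)
    builds$nonnaive <- list(graph = nn$graph, features = nn$features)
  }
  # Shared holdout: computed per variant from the common PSE subset; the
  # per-relation seeding makes the selected edges identical across variants.
  splits <- lapply(builds, function(b)
    suppressWarnings(split_pse_holdout(b$graph, config$holdout_fraction,
                                       seed = seeds$split)))
  ref <- splits[[1L]]
  labeled <- sample_eval_negatives(builds[[1L]]$graph, ref,
                                  seed = seeds$negatives)
  cells <- list(); failures <- list(); rows <- list()
  for (variant in config$variants) {
    b <- builds[[variant]]
    dataset <- training_dataset(b$graph, splits[[variant]],
                                seed = seeds$valid)
    for (model in config$models) {
      cell <- paste(model, variant, sep = "-")
      if (verbose) message("cell: ", cell)
      res <- tryCatch({
        mc <- config$mconfig
        mc$model <- model
        use_features <- config$feature_init && variant == "nonnaive"
        features <- NULL
        if (use_features) {
          mc$init <- "feature"
          features <- reduce_features(b$features, mc$m, seed = seeds$train)
        } else if (mc$init == "feature") {
          mc$init <- "normal"
        }
        if (model == "complex" && mc$m %% 2L != 0L) mc$m <- mc$m + 1L
        tc <- config$tconfig
        tc$seed <- derive_seed(seeds$train, match(model, config$models) * 10L +
                                 match(variant, config$variants))
        tc$checkpoint_every_epoch <- config$per_epoch_curve
        fit <- run_training(dataset, mc, tc, features = features)
        report <- evaluate_side_effects(fit$best$params, labeled)
        list(fit = fit, report = report, dataset = dataset)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[cell]] <- conditionMessage(res)
      } else {
        cells[[cell]] <- res
        rows[[cell]] <- data.frame(
          model = model, variant = variant,
          median_auroc = res$report$medians$auroc,
          median_auprc = res$report$medians$auprc,
          median_ap50 = res$report$medians$ap50,
          n_relations = res$report$n_relations,
          stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)
  rank_consistent <- NA
  if (!is.null(table) && nrow(table) > 1L) {
    o1 <- order(-table$median_auroc)
    o2 <- order(-table$median_auprc)
    o3 <- order(-table$median_ap50)
    rank_consistent <- identical(o1, o2) && identical(o1, o3)
    table <- table[order(-table$median_auprc), , drop = FALSE]
    rownames(table) <- NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cell in names(cells))
      write_eval_report(cells[[cell]]$report,
                        json_path = file.path(out_dir, paste0(cell, ".json")),
                        tsv_path = file.path(out_dir, paste0(cell, ".tsv")))
    if (!is.null(table))
      data.table::fwrite(table, file.path(out_dir, "combined.tsv"), sep = "\t")
    jsonlite::write_json(seeds, file.path(out_dir, "seeds.json"),
                         auto_unbox = TRUE)
  }
  list(cells = cells, table = table, rank_consistent = rank_consistent,
       split = ref, labeled = labeled, seeds = seeds, failures = failures)
}

#' Per-epoch performance curve of a training run
#'
#' Evaluates every per-epoch parameter snapshot on a fixed set of
#' labelled holdout pairs (fixed negative-sampling seed, so the curve
#' varies only through the model) and reports, per metric, the fraction
#' of the best-over-epochs median reached at each epoch.  Gaps in the
#' epoch sequence are recorded and the curve continues.
#'
#' @param checkpoints Either the `epoch_params` list of a
#'   [run_training()] result or a directory of per-epoch checkpoint
#'   `.rds` files named `epoch_<n>.rds`.
#' @param labeled A [sample_eval_negatives()] result.
#' @return A data frame: epoch, median AUROC/AUPRC/AP@50 and the
#'   corresponding fraction-of-best columns; attribute `gaps` lists
#'   missing epochs.
#' @export
per_epoch_curve <- function(checkpoints, labeled) {
  if (is.character(checkpoints)) {
    files <- list.files(checkpoints, pattern = "^epoch_\\d+\\.rds$",
                        full.names = TRUE)
    epochs <- as.integer(sub("^epoch_(\\d+)\\.rds$", "\\1", basename(files)))
    ord <- order(epochs)
    params_list <- lapply(files[ord], function(f) {
      ck <- readRDS(f)
      if (!is.null(ck$params)) ck$params else ck
    })
    epochs <- epochs[ord]
  } else {
    epochs <- as.integer(names(checkpoints))
    params_list <- checkpoints
  }
  if (!length(params_list)) stop("no checkpoints found", call. = FALSE)
  gaps <- setdiff(seq(min(epochs), max(epochs)), epochs)
  rows <- lapply(seq_along(params_list), function(i) {
    rep <- evaluate_side_effects(params_list[[i]], labeled)
    data.frame(epoch = epochs[i], median_auroc = rep$medians$auroc,
               median_auprc = rep$medians$auprc,
               median_ap50 = rep$medians$ap50)
  })
  curve <- do.call(rbind, rows)
  for (m in c("median_auroc", "median_auprc", "median_ap50")) {
    best <- max(curve[[m]])
    curve[[paste0("frac_best_", sub("median_", "", m))]] <-
      if (best > 0) curve[[m]] / best else NA_real_
  }
  attr(curve, "gaps") <- gaps
  curve
}
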