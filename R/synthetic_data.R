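#' Specify a miniature synthetic polypharmacy dataset
#'
#' Describes a desk-scale analogue of the four raw tables used for
#' polypharmacy side-effect (PSE) prediction: drug-pair side effects,
#' single-drug (monopharmacy) side effects, drug--gene targets and
#' protein--protein interactions.  Drug-pair edges are planted with
#' low-rank trilinear structure so that tensor-factorization models can
#' recover held-out edges, and monopharmacy records are derived from the
#' same drug factors so that feature-based initialization carries signal.
#'
#' @param n_drugs,n_genes Number of drug / gene nodes.
#' @param n_pse_types Number of pair side-effect types (one relation each).
#' @param n_mono_types Number of single-drug side-effect types.
#' @param latent_rank Dimensionality of the planted factors; must not
#'   exceed `n_drugs`.
#' @param pse_density Target fraction of drug-pair-by-type slots that
#'   become edges, in (0,1).  Realized density is calibrated to within
#'   about 20% relative error via bisection on the intercept.
#' @param mono_rate,target_rate,ppi_rate Target edge fractions for the
#'   monopharmacy, drug-target and protein-interaction tables, in (0,1).
#' @param noise_sd Standard deviation of Gaussian noise added to planted
#'   edge scores on the logit scale (0 disables noise).
#' @param gain Multiplier applied to the (unit-variance) planted score
#'   before the sigmoid; larger values give cleaner planted signal.
#' @param seed Integer seed; identical spec + seed give byte-identical
#'   output tables.
#' @return An object of class `synthetic_spec`.
#' @seealso [make_planted_model()], [synthesize_raw_tables()]
#' @export
synthetic_spec <- function(n_drugs = 200L, n_genes = 100L, n_pse_types = 30L,
                           n_mono_types = 40L, latent_rank = 8L,
                           pse_density = 0.05, mono_rate = 0.15,
                           target_rate = 0.02, ppi_rate = 0.05,
                           noise_sd = 0.5, gain = 4, seed = 1L) {
  spec <- list(
    n_drugs      = check_count(n_drugs, "n_drugs"),
    n_genes      = check_count(n_genes, "n_genes"),
    n_pse_types  = check_count(n_pse_types, "n_pse_types"),
    n_mono_types = check_count(n_mono_types, "n_mono_types"),
    latent_rank  = check_count(latent_rank, "latent_rank"),
    pse_density  = check_fraction(pse_density, "pse_density"),
    mono_rate    = check_fraction(mono_rate, "mono_rate"),
    target_rate  = check_fraction(target_rate, "target_rate"),
    ppi_rate     = check_fraction(ppi_rate, "ppi_rate"),
    noise_sd     = check_nonneg(noise_sd, "noise_sd"),
    gain         = check_nonneg(gain, "gain"),
    seed         = check_count(seed, "seed", min = 0L)
  )
  if (spec$latent_rank > spec$n_drugs)
    stop("'latent_rank' must not exceed 'n_drugs'", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' Draw the planted ground-truth factors for a synthetic dataset
#'
#' Drug and side-effect-type factors are i.i.d. zero-mean normal with
#' scale `latent_rank^(-1/6)`, so the planted trilinear score
#' `sum_k u_i[k] w_r[k] u_j[k]` has variance approximately 1 regardless
#' of rank.  Gene factors share the same scale; monopharmacy loadings
#' are standard normal (they only enter through a quantile threshold).
#'
#' @param spec A [synthetic_spec()].
#' @return A `planted_model`: list of `drug_factors`, `pse_factors`,
#'   `mono_loadings`, `gene_factors`.
#' @export
make_planted_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$latent_rank
  s <- k^(-1 / 6)
  with_seed(spec$seed, {
    m <- list(
      drug_factors  = matrix(stats::rnorm(spec$n_drugs * k, sd = s), spec$n_drugs, k),
      pse_factors   = matrix(stats::rnorm(spec$n_pse_types * k, sd = s), spec$n_pse_types, k),
      mono_loadings = matrix(stats::rnorm(spec$n_mono_types * k), spec$n_mono_types, k),
      gene_factors  = matrix(stats::rnorm(spec$n_genes * k, sd = s), spec$n_genes, k)
    )
  })
  structure(m, class = "planted_model")
}

# Symmetric planted pair-score matrix for one PSE type.  The trilinear form
# sum_k u_i w_r u_j is already symmetric in (i, j); the explicit averaging of
# both orientations is kept for clarity with directional scorers downstream.
planted_pair_scores <- function(planted, r) {
  U <- planted$drug_factors
  w <- planted$pse_factors[r, ]
  S <- tcrossprod(U %*% diag(w, nrow = length(w)), U)
  (S + t(S)) / 2
}

synthetic_ids <- function(spec) {
  list(
    drugs = sprintf("D%04d", seq_len(spec$n_drugs)),
    genes = sprintf("G%04d", seq_len(spec$n_genes)),
    pse   = sprintf("C%04d", seq_len(spec$n_pse_types)),
    mono  = sprintf("M%04d", seq_len(spec$n_mono_types))
  )
}

#' Generate the four raw tables from a planted model
#'
#' Drug-pair side-effect edges are sampled independently per unordered
#' pair and type with probability
#' `sigmoid(gain * score + noise + b)`, where `score` is the planted
#' symmetrized trilinear score and the intercept `b` is calibrated by
#' bisection so the realized edge density matches `spec$pse_density`.
#' Monopharmacy records are obtained by thresholding
#' `drug_factors %*% t(mono_loadings)` at the quantile matching
#' `mono_rate`, which ties a drug's monopharmacy profile to the same
#' factors that drive its pair behaviour.  Target and protein-interaction
#' tables are thresholded factor similarities (weak signal by design).
#'
#' @param planted A [make_planted_model()] result consistent with `spec`.
#' @param spec The [synthetic_spec()] used to create `planted`.
#' @param intercept Optional fixed intercept `b`; when supplied the
#'   density calibration is skipped.
#' @return A `raw_tables` object (see [read_raw_tables()]).
#' @export
synthesize_raw_tables <- function(planted, spec, intercept = NULL) {
  stopifnot(inherits(planted, "planted_model"), inherits(spec, "synthetic_spec"))
  if (nrow(planted$drug_factors) != spec$n_drugs ||
      nrow(planted$pse_factors) != spec$n_pse_types)
    stop("planted model shapes inconsistent with spec", call. = FALSE)
  ids <- synthetic_ids(spec)
  nd <- spec$n_drugs
  up <- which(upper.tri(matrix(0, nd, nd)))  # i < j slots, column-major
  ij <- arrayInd(up, c(nd, nd))

  # Per-type logits (gain * planted score + noise), noise drawn first so the
  # intercept calibration is deterministic given the seed.
  eta <- matrix(0, length(up), spec$n_pse_types)
  with_seed(derive_seed(spec$seed, 1L), {
    for (r in seq_len(spec$n_pse_types)) {
      s <- planted_pair_scores(planted, r)[up]
      noise <- if (spec$noise_sd > 0)
        stats::rnorm(length(up), sd = spec$noise_sd) else 0
      eta[, r] <- spec$gain * s + noise
    }
    b <- intercept %||%
      calibrate_intercept(eta, spec$pse_density)
    edges <- matrix(stats::runif(length(eta)) < sigmoid(eta + b),
                    nrow(eta), ncol(eta))
  })
  hit <- which(edges, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    stop("degenerate spec: no drug-pair side-effect edges realized", call. = FALSE)
  pse <- data.frame(
    drug_a  = ids$drugs[ij[hit[, 1L], 1L]],
    drug_b  = ids$drugs[ij[hit[, 1L], 2L]],
    se_type = ids$pse[hit[, 2L]],
    se_name = paste0("pair-side-effect-", hit[, 2L]),
    stringsAsFactors = FALSE
  )

  # Monopharmacy: deterministic quantile threshold on shared-factor logits.
  L <- planted$drug_factors %*% t(planted$mono_loadings)
  tau <- stats::quantile(L, 1 - spec$mono_rate, names = FALSE)
  mh <- which(L > tau, arr.ind = TRUE)
  if (nrow(mh) == 0L)
    stop("degenerate spec: no monopharmacy records realized", call. = FALSE)
  mono <- data.frame(
    drug    = ids$drugs[mh[, 1L]],
    se_type = ids$mono[mh[, 2L]],
    se_name = paste0("mono-side-effect-", mh[, 2L]),
    stringsAsFactors = FALSE
  )

  A <- planted$drug_factors %*% t(planted$gene_factors)
  th <- which(A > stats::quantile(A, 1 - spec$target_rate, names = FALSE),
              arr.ind = TRUE)
  if (nrow(th) == 0L)
    stop("degenerate spec: no drug-target records realized", call. = FALSE)
  targets <- data.frame(drug = ids$drugs[th[, 1L]], gene = ids$genes[th[, 2L]],
                        stringsAsFactors = FALSE)

  G <- tcrossprod(planted$gene_factors)
  gup <- which(upper.tri(G))
  gij <- arrayInd(gup, dim(G))
  gv <- G[gup]
  ph <- which(gv > stats::quantile(gv, 1 - spec$ppi_rate, names = FALSE))
  if (length(ph) == 0L)
    stop("degenerate spec: no protein-interaction records realized", call. = FALSE)
  ppi <- data.frame(gene_a = ids$genes[gij[ph, 1L]],
                    gene_b = ids$genes[gij[ph, 2L]],
                    stringsAsFactors = FALSE)

  new_raw_tables(pse, mono, targets, ppi)
}

# Bisection on the intercept b so mean(sigmoid(eta + b)) equals the target
# density.  Expected (not realized) density is matched; the Bernoulli draw
# adds only binomial jitter.
calibrate_intercept <- function(eta, density, tol = 1e-6) {
  f <- function(b) mean(sigmoid(eta + b)) - density
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("density calibration failed", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' A hand-checkable fixture of the four raw tables
#'
#' Four drugs, two genes, two pair side-effect types with 6 pair records
#' (4 of type C1, 2 of type C2), 3 monopharmacy records over 3 distinct
#' types, 2 drug-target records and 1 protein-interaction record.  The
#' self-loop graph built from it therefore has 6 + 3 + 2 + 1 = 12 edges
#' and 2 + 3 + 2 = 7 relations; the feature-based variant has 9 edges.
#'
#' @return A `raw_tables` object.
#' @export
toy_fixture <- function() {
  pse <- data.frame(
    drug_a  = c("D1", "D1", "D2", "D3", "D1", "D2"),
    drug_b  = c("D2", "D3", "D3", "D4", "D2", "D4"),
    se_type = c("C1", "C1", "C1", "C1", "C2", "C2"),
    se_name = c(rep("pair-se-1", 4), rep("pair-se-2", 2)),
    stringsAsFactors = FALSE
  )
  mono <- data.frame(
    drug    = c("D1", "D2", "D4"),
    se_type = c("M1", "M2", "M3"),
    se_name = c("mono-se-1", "mono-se-2", "mono-se-3"),
    stringsAsFactors = FALSE
  )
  targets <- data.frame(drug = c("D1", "D3"), gene = c("G1", "G2"),
                        stringsAsFactors = FALSE)
  ppi <- data.frame(gene_a = "G1", gene_b = "G2", stringsAsFactors = FALSE)
  new_raw_tables(pse, mono, targets, ppi)
}

#' Write raw tables in the downloadable-data CSV dialect
#'
#' Emits the four CSV files with the column headers used by the public
#' polypharmacy raw tables, so the synthetic path exercises the same
#' parsers as real data: `combo.csv` ("STITCH 1, STITCH 2, Polypharmacy
#' Side Effect, Side Effect Name"), `mono.csv` ("STITCH, Individual Side
#' Effect, Side Effect Name"), `targets.csv` ("STITCH, Gene") and
#' `ppi.csv` ("Gene 1, Gene 2").
#'
#' @param raw A `raw_tables` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_raw_tables <- function(raw, dir) {
  stopifnot(inherits(raw, "raw_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("combo.csv", "mono.csv", "targets.csv", "ppi.csv"))
  combo <- data.table::data.table(
    "STITCH 1" = raw$pse$drug_a, "STITCH 2" = raw$pse$drug_b,
    "Polypharmacy Side Effect" = raw$pse$se_type,
    "Side Effect Name" = raw$pse$se_name)
  mono <- data.table::data.table(
    "STITCH" = raw$mono$drug, "Individual Side Effect" = raw$mono$se_type,
    "Side Effect Name" = raw$mono$se_name)
  targ <- data.table::data.table("STITCH" = raw$targets$drug,
                                 "Gene" = raw$targets$gene)
  ppi <- data.table::data.table("Gene 1" = raw$ppi$gene_a,
                                "Gene 2" = raw$ppi$gene_b)
  data.table::fwrite(combo, paths[1L])
  data.table::fwrite(mono, paths[2L])
  data.table::fwrite(targ, paths[3L])
  data.table::fwrite(ppi, paths[4L])
  invisible(stats::setNames(paths, c("combo", "mono", "targets", "ppi")))
}
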