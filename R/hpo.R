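# Sobol-then-Bayesian hyperparameter search.
#
# The 100-trial protocol: the first 50 configurations come from an
# unscrambled base-2 Sobol sequence mapped onto the search space, the
# remaining 50 are proposed one at a time by a Gaussian-process surrogate
# with expected-improvement acquisition over the full preceding history.

# Joe-Kuo direction-number table (primitive polynomial degree s, coefficient
# a, initial direction numbers m) for dimensions 2..13; dimension 1 is the
# van der Corput sequence in base 2.  Verified against an independent
# reference implementation of the same direction numbers.
sobol_dirnum_table <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L)),
  list(s = 5L, a = 11L, m = c(1L, 1L, 5L, 1L, 1L)),
  list(s = 5L, a = 13L, m = c(1L, 1L, 1L, 3L, 11L)),
  list(s = 5L, a = 14L, m = c(1L, 3L, 5L, 5L, 31L))
)

# Direction integers V[k] = m_k * 2^(nbits - k) for one dimension, from
# (s, a, m) via the standard recurrence
# m_k = 2 a_1 m_{k-1} xor 4 a_2 m_{k-2} xor ... xor 2^{s-1} a_{s-1} m_{k-s+1}
#       xor 2^s m_{k-s} xor m_{k-s}.
sobol_directions <- function(dim_entry, nbits = 31L) {
  s <- dim_entry$s; a <- dim_entry$a; m <- as.double(dim_entry$m)
  # a encodes the inner polynomial coefficients a_1..a_{s-1}, a_1 first
  # (most significant bit)
  abits <- rev(as.integer(intToBits(a))[seq_len(max(s - 1L, 1L))])
  if (length(m) < nbits) {
    for (k in (length(m) + 1L):nbits) {
      val <- xor_dbl(2^s * m[k - s], m[k - s])
      if (s > 1L) for (j in seq_len(s - 1L)) {
        if (abits[j] == 1L) val <- xor_dbl(val, 2^j * m[k - j])
      }
      m[k] <- val
    }
  }
  m[seq_len(nbits)] * 2^(nbits - seq_len(nbits))
}

# xor of two nonnegative integers stored as doubles (< 2^53), via 16-bit limbs
xor_dbl <- function(x, y) {
  out <- 0; mult <- 1
  while (x > 0 || y > 0) {
    out <- out + mult * bitwXor(x %% 65536, y %% 65536)
    x <- x %/% 65536; y <- y %/% 65536
    mult <- mult * 65536
  }
  out
}

#' Unscrambled Sobol points in the unit hypercube
#'
#' Generates the standard base-2 Sobol sequence (Gray-code order,
#' van der Corput first dimension, Joe--Kuo direction numbers) starting
#' from index `skip`.  With `skip = 0` the first point is the origin and
#' any power-of-two prefix balances every dyadic box exactly; with
#' `skip = 1` (the search-phase default) the origin is omitted and the
#' one-dimensional prefix is 0.5, 0.75, 0.25, 0.375, ...
#'
#' @param n Number of points.
#' @param dim Dimension (1 to 13).
#' @param skip Number of initial sequence elements to skip.
#' @return An `n x dim` matrix in \[0,1).
#' @export
sobol_points <- function(n, dim, skip = 0L) {
  n <- check_count(n, "n")
  dim <- check_count(dim, "dim")
  if (dim > length(sobol_dirnum_table) + 1L)
    stop("sobol_points supports at most ", length(sobol_dirnum_table) + 1L,
         " dimensions", call. = FALSE)
  nbits <- 31L
  # integer direction numbers, stored as doubles (< 2^31, exactly representable)
  V <- matrix(0, nbits, dim)
  V[, 1L] <- 2^(nbits - seq_len(nbits))  # van der Corput: m_k = 1
  if (dim > 1L)
    for (d in 2L:dim)
      V[, d] <- sobol_directions(sobol_dirnum_table[[d - 1L]], nbits)
  out <- matrix(0, n, dim)
  x <- rep(0, dim)  # integer state per dimension
  total <- n + skip
  for (i in seq_len(total)) {
    if (i > skip) out[i - skip, ] <- x / 2^nbits
    # Gray-code update: flip bit c = position of lowest zero bit of (i - 1)
    j <- i - 1L
    c <- 1L
    while (j %% 2L == 1L) { j <- j %/% 2L; c <- c + 1L }
    for (d in seq_len(dim)) x[d] <- xor_dbl(x[d], V[c, d])
  }
  out
}

#' Define a hyperparameter search space
#'
#' @param ... Named parameter definitions, each a list with `kind`
#'   (`"categorical"`, `"integer"`, `"real"`, `"log-real"`) and either
#'   `values` (categorical) or `lower` / `upper` bounds.
#' @return A `search_space`.
#' @export
search_space <- function(...) {
  params <- list(...)
  if (is.null(names(params)) || any(names(params) == ""))
    stop("all search-space parameters must be named", call. = FALSE)
  for (nm in names(params)) {
    p <- params[[nm]]
    kind <- check_choice(p$kind %||% "", paste0(nm, "$kind"),
                         c("categorical", "integer", "real", "log-real"))
    if (kind == "categorical") {
      if (!length(p$values)) stop("categorical '", nm, "' needs values",
                                  call. = FALSE)
    } else {
      if (is.null(p$lower) || is.null(p$upper) || p$lower >= p$upper)
        stop("'", nm, "' needs lower < upper", call. = FALSE)
      if (kind == "log-real" && p$lower <= 0)
        stop("log-real '", nm, "' needs strictly positive bounds",
             call. = FALSE)
    }
  }
  structure(params, class = "search_space")
}

#' The default model-agnostic search space
#'
#' Embedding sizes, optimizer (5 options), loss (4 options), training
#' strategy, learning rate (log scale), batch size, the two dropout
#' rates, regularization weight and weight initialization.
#'
#' @param embed_sizes Candidate embedding sizes.
#' @param batch_sizes Candidate batch sizes.
#' @param feature_init Include `"feature"` among the initialization
#'   options (only valid for datasets with feature matrices).
#' @return A `search_space`.
#' @export
default_search_space <- function(embed_sizes = c(32L, 64L, 128L, 256L, 512L),
                                 batch_sizes = c(128L, 256L, 512L),
                                 feature_init = FALSE) {
  inits <- c("normal", "xavier-normal", if (feature_init) "feature")
  search_space(
    m = list(kind = "categorical", values = embed_sizes),
    lr = list(kind = "log-real", lower = 1e-4, upper = 1),
    batch_size = list(kind = "categorical", values = batch_sizes),
    optimizer = list(kind = "categorical",
                     values = c("adam", "adamax", "adadelta", "adagrad", "sgd")),
    strategy = list(kind = "categorical", values = c("1vsAll", "KvsAll")),
    loss = list(kind = "categorical", values = c("kl", "bce", "margin", "se")),
    dropout_entity = list(kind = "real", lower = 0, upper = 0.5),
    dropout_relation = list(kind = "real", lower = 0, upper = 0.5),
    reg_weight = list(kind = "real", lower = 0, upper = 0.1),
    init = list(kind = "categorical", values = inits)
  )
}

# Map one unit-hypercube row onto a configuration (named list).
unit_to_config <- function(space, u) {
  cfg <- list()
  for (j in seq_along(space)) {
    p <- space[[j]]; v <- u[j]
    cfg[[names(space)[j]]] <- switch(p$kind,
      categorical = p$values[[min(floor(v * length(p$values)) + 1L,
                                  length(p$values))]],
      integer = as.integer(min(floor(p$lower + v * (p$upper - p$lower + 1)),
                               p$upper)),
      real = p$lower + v * (p$upper - p$lower),
      `log-real` = exp(log(p$lower) + v * (log(p$upper) - log(p$lower))))
  }
  cfg
}

# Encode a configuration back into the unit hypercube (for the surrogate).
config_to_unit <- function(space, cfg) {
  vapply(seq_along(space), function(j) {
    p <- space[[j]]; v <- cfg[[names(space)[j]]]
    switch(p$kind,
      categorical = (match(v, p$values) - 0.5) / length(p$values),
      integer = (v - p$lower) / (p$upper - p$lower),
      real = (v - p$lower) / (p$upper - p$lower),
      `log-real` = (log(v) - log(p$lower)) / (log(p$upper) - log(p$lower)))
  }, double(1L))
}

validate_config <- function(space, cfg) {
  for (nm in names(space)) {
    p <- space[[nm]]; v <- cfg[[nm]]
    ok <- switch(p$kind,
      categorical = v %in% p$values,
      integer = v >= p$lower && v <= p$upper,
      v >= p$lower * (1 - 1e-12) && v <= p$upper * (1 + 1e-12))
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' Quasi-random (Sobol) phase of the search
#'
#' Maps the unscrambled Sobol sequence (origin skipped) onto the search
#' space: categorical parameters by equal-width bins, log-real ones by
#' exponential transform.  Deterministic; `seed` is accepted for
#' interface symmetry but unused because the sequence is unscrambled.
#'
#' @param space A [search_space()].
#' @param n Number of configurations.
#' @param seed Unused (unscrambled sequence).
#' @return List of `n` configurations.
#' @export
sobol_phase <- function(space, n, seed = 1L) {
  U <- sobol_points(n, length(space), skip = 1L)
  lapply(seq_len(n), function(i) unit_to_config(space, U[i, ]))
}

# --- Gaussian-process surrogate ---------------------------------------------

gp_fit <- function(X, y) {
  n <- nrow(X)
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  z <- (y - mu) / sdy
  D2 <- as.matrix(stats::dist(X))^2
  med <- stats::median(D2[upper.tri(D2)])
  ell2 <- if (is.finite(med) && med > 0) med else 0.25
  K <- exp(-D2 / (2 * ell2)) + diag(1e-5, n)
  list(X = X, alpha = solve(K, z), K = K, ell2 = ell2, mu = mu, sdy = sdy, z = z)
}

gp_predict <- function(fit, Xnew) {
  # squared distances between Xnew and fit$X
  D2 <- outer(rowSums(Xnew^2), rowSums(fit$X^2), "+") - 2 * Xnew %*% t(fit$X)
  D2[D2 < 0] <- 0
  Ks <- exp(-D2 / (2 * fit$ell2))
  mean_z <- Ks %*% fit$alpha
  v <- t(solve(fit$K, t(Ks)))
  var_z <- pmax(1 - rowSums(Ks * v), 1e-12)
  list(mean = drop(mean_z) * fit$sdy + fit$mu,
       sd = sqrt(var_z) * fit$sdy)
}

expected_improvement <- function(mu, sd, best) {
  d <- mu - best
  z <- d / sd
  ei <- d * stats::pnorm(z) + sd * stats::dnorm(z)
  ei[sd <= 0] <- 0
  ei
}

#' Propose the next configuration from a Gaussian-process surrogate
#'
#' Fits a GP (RBF kernel, median-heuristic lengthscale, standardized
#' outcomes) of validation metric against the unit-cube encoding of the
#' evaluated configurations, then proposes the candidate maximizing
#' expected improvement over a seeded quasi-random candidate pool plus
#' local perturbations of the incumbent.  Exact duplicates of evaluated
#' configurations are excluded while untried candidates remain.  If
#' every recorded trial diverged, the proposal falls back to continuing
#' the Sobol sequence (with a warning).
#'
#' @param space A [search_space()].
#' @param history List of trial records, each with `config`, `metric`,
#'   `status` (`"ok"` or `"diverged"`).
#' @param seed Integer seed for the candidate pool.
#' @param n_candidates Candidate pool size.
#' @return A configuration (named list) validating against `space`.
#' @export
bayes_phase <- function(space, history, seed = 1L, n_candidates = 256L) {
  if (length(history) == 0L) stop("history must be nonempty", call. = FALSE)
  ok <- Filter(function(tr) identical(tr$status, "ok") && is.finite(tr$metric),
               history)
  if (length(ok) == 0L) {
    warning("all trials diverged; falling back to Sobol continuation",
            call. = FALSE)
    return(unit_to_config(space,
                          sobol_points(1L, length(space),
                                       skip = length(history) + 1L)[1L, ]))
  }
  X <- do.call(rbind, lapply(ok, function(tr) config_to_unit(space, tr$config)))
  y <- vapply(ok, function(tr) tr$metric, double(1L))
  d <- length(space)
  cand <- with_seed(derive_seed(seed, 77L), {
    pool <- matrix(stats::runif(n_candidates * d), n_candidates, d)
    # local perturbations around the incumbent
    inc <- X[which.max(y), ]
    loc <- matrix(rep(inc, each = 32L), 32L, d) +
      matrix(stats::rnorm(32L * d, sd = 0.05), 32L, d)
    loc <- pmin(pmax(loc, 0), 1 - 1e-9)
    rbind(pool, loc)
  })
  configs <- lapply(seq_len(nrow(cand)), function(i)
    unit_to_config(space, cand[i, ]))
  # drop exact duplicates of evaluated configurations while alternatives exist
  seen <- vapply(history, function(tr)
    paste(deparse(tr$config[order(names(tr$config))]), collapse = ""),
    character(1L))
  keys <- vapply(configs, function(cf)
    paste(deparse(cf[order(names(cf))]), collapse = ""), character(1L))
  fresh <- !(keys %in% seen)
  if (any(fresh)) {
    cand <- cand[fresh, , drop = FALSE]
    configs <- configs[fresh]
  }
  if (length(unique(y)) == 1L) {
    # degenerate history: any candidate is as good as any other
    return(configs[[1L]])
  }
  fit <- gp_fit(X, y)
  pred <- gp_predict(fit, cand)
  ei <- expected_improvement(pred$mean, pred$sd, max(y))
  configs[[which.max(ei)]]
}

#' Run the full Sobol + Bayesian search
#'
#' Executes one training run per trial with the trial's configuration
#' and the configured early-stopping rule; the first `n_sobol` trials
#' are the Sobol prefix, each later trial consults the full preceding
#' history through [bayes_phase()].  Trials whose training fails are
#' recorded as `"diverged"` and the search continues.  History is
#' persisted incrementally as JSON lines so an interrupted search
#' resumes without re-running completed trials.
#'
#' @param dataset A [training_dataset()] result.
#' @param model `"simple"`, `"complex"` or `"distmult"`.
#' @param space A [search_space()] over any subset of
#'   [model_config()] / [train_config()] fields.
#' @param n_sobol,n_bayes Trial counts for the two phases (the
#'   full-scale protocol uses 50 + 50).
#' @param seed Integer seed.
#' @param base_train A [train_config()] whose fields are used wherever
#'   the space does not override them (sets the epoch budget).
#' @param features Optional feature matrix for `init = "feature"`.
#' @param history_file Optional JSONL path for persistence/resume.
#' @return List with `best` (highest-metric trial record) and `history`
#'   (list of all trial records).
#' @export
run_search <- function(dataset, model, space, n_sobol = 50L, n_bayes = 50L,
                       seed = 1L, base_train = NULL, features = NULL,
                       history_file = NULL) {
  model <- check_choice(model, "model", c("simple", "complex", "distmult"))
  base_train <- base_train %||% train_config()
  history <- list()
  if (!is.null(history_file) && file.exists(history_file)) {
    lines <- readLines(history_file)
    history <- lapply(lines[nzchar(lines)], function(l)
      jsonlite::fromJSON(l, simplifyVector = TRUE))
  }
  sobol_cfgs <- sobol_phase(space, n_sobol, seed = seed)
  n_total <- n_sobol + n_bayes
  for (trial in seq_len(n_total)) {
    if (trial <= length(history)) next  # already done (resume)
    cfg <- if (trial <= n_sobol) sobol_cfgs[[trial]]
      else bayes_phase(space, history, seed = derive_seed(seed, trial))
    cfg <- project_config(cfg, model, features)
    rec <- tryCatch({
      tm <- trial_settings(model, cfg, base_train, seed = derive_seed(seed, trial))
      fit <- run_training(dataset, tm$mconfig, tm$tconfig, features =
                            if (identical(cfg$init, "feature")) features)
      metric <- fit$history$best_metric
      if (!is.finite(metric)) metric <- fit$history$baseline
      list(trial = trial - 1L, config = cfg, metric = metric,
           epochs = max(fit$history$epochs$epoch), status = "ok")
    }, error = function(e)
      list(trial = trial - 1L, config = cfg, metric = NA_real_,
           epochs = NA_integer_, status = "diverged",
           message = conditionMessage(e)))
    history[[trial]] <- rec
    if (!is.null(history_file))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          sep = "", file = history_file, append = TRUE)
  }
  ok <- Filter(function(tr) identical(tr$status, "ok") && is.finite(tr$metric),
               history)
  if (length(ok) == 0L) stop("every trial diverged", call. = FALSE)
  best <- ok[[which.max(vapply(ok, function(tr) tr$metric, double(1L)))]]
  list(best = best, history = history)
}

# Conditional-parameter handling: projection to a valid configuration
# rather than rejection (e.g. feature init without a feature matrix, or a
# loss incompatible with the sampled strategy).
project_config <- function(cfg, model, features) {
  if (identical(cfg$init, "feature") && is.null(features)) cfg$init <- "normal"
  if (!is.null(cfg$loss) && !is.null(cfg$strategy) &&
      cfg$loss %in% c("kl", "margin") && cfg$strategy != "1vsAll")
    cfg$loss <- "bce"
  if (identical(model, "complex") && !is.null(cfg$m) && cfg$m %% 2L != 0L)
    cfg$m <- cfg$m + 1L
  cfg
}

# Split a flat search configuration into model_config + train_config,
# falling back to `base` for unsampled training fields.
trial_settings <- function(model, cfg, base, seed) {
  mconfig <- model_config(
    model = model,
    m = as.integer(cfg$m %||% 128L),
    init = cfg$init %||% "normal",
    dropout_entity = cfg$dropout_entity %||% 0,
    dropout_relation = cfg$dropout_relation %||% 0,
    reg_weight = cfg$reg_weight %||% 0)
  tconfig <- train_config(
    strategy = cfg$strategy %||% base$strategy,
    loss = cfg$loss %||% base$loss,
    optimizer = cfg$optimizer %||% base$optimizer,
    lr = cfg$lr %||% base$lr,
    batch_size = as.integer(cfg$batch_size %||% base$batch_size),
    max_epochs = base$max_epochs, eval_every = base$eval_every,
    eval_start = base$eval_start, patience_checks = base$patience_checks,
    scheduler_factor = base$scheduler_factor, margin = base$margin,
    seed = seed, checkpoint_every_epoch = FALSE)
  list(mconfig = mconfig, tconfig = tconfig)
}
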