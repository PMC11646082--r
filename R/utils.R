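# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and an integer salt, kept inside the
# 32-bit integer range R's set.seed() accepts.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + as.double(salt) * 104729) %% 2147483629L) + 1L
}

# --- argument validation -----------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d (got %s)",
                 name, min, deparse(x)), call. = FALSE)
  as.integer(x)
}

check_fraction <- function(x, name, closed_zero = FALSE) {
  lo_ok <- if (closed_zero) x >= 0 else x > 0
  if (length(x) != 1L || !is.finite(x) || !lo_ok || x >= 1)
    stop(sprintf("'%s' must be a single value in %s1) (got %s)",
                 name, if (closed_zero) "[0," else "(0,", deparse(x)),
         call. = FALSE)
  as.double(x)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single nonnegative number (got %s)",
                 name, deparse(x)), call. = FALSE)
  as.double(x)
}

check_choice <- function(x, name, choices) {
  if (length(x) != 1L || !x %in% choices)
    stop(sprintf("'%s' must be one of %s (got %s)",
                 name, paste(sQuote(choices), collapse = ", "), deparse(x)),
         call. = FALSE)
  x
}

# --- numerics ----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable log(sigmoid(x)) and row-wise log-softmax.
log_sigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

row_log_softmax <- function(S) {
  mx <- apply(S, 1L, max)
  Z <- S - mx
  Z - log(rowSums(exp(Z)))
}

# Canonical unordered-pair ordering: lexicographically smaller id first.
canonical_pairs <- function(a, b) {
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}
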