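# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All user-facing randomness in the package goes through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a reproducible child seed from a parent seed and an index,
# kept within the 32-bit signed integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Stratified fold assignment: within each class, members are shuffled and
# dealt round-robin so every fold's class proportions are within one
# member of the global proportions.
make_folds <- function(y, k, seed = NULL) {
  y <- as.character(y)
  n <- length(y)
  if (k < 2) stopf("number of folds must be >= 2, got %d", k)
  min_class <- min(table(y))
  if (min_class < k) {
    k_new <- max(2L, as.integer(min_class))
    warnf("smallest class has %d members < %d folds; reducing to %d folds",
          min_class, k, k_new)
    k <- k_new
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  attr(folds, "k") <- k
  folds
}

# Stratified subsample preserving at least one member per class.
stratified_subsample <- function(y, fraction, seed = NULL) {
  y <- as.character(y)
  keep <- integer(0)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_take <- max(1L, round(fraction * length(idx)))
      keep <- c(keep, idx[sample.int(length(idx), n_take)])
    }
  })
  sort(keep)
}
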