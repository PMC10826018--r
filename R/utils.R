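# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: one master seed fans out to independent
# stages via distinct salts.  Kept strictly below 2^31 - 1.
derive_seed <- function(seed, salt) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.numeric(salt) * 16807) %% 2147483647
  as.integer(x)
}

# Rank-based AUC (Mann-Whitney); handles tied scores correctly.
auc_rank <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment: returns integer fold id per observation.
# Within each class, shuffled observations are dealt round-robin so every
# fold keeps both classes whenever each class has >= k members.
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  if (min(table(y)) < k) {
    stop("cannot build ", k, " stratified folds: smallest class has fewer than ",
         k, " members")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x > 0
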