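# Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a run-level seed
#'
#' All stochastic stages of the package draw from a single run-level seed,
#' fanned out deterministically per stage so that changing the seed of one
#' stage does not perturb another.
#'
#' @param seed integer run-level seed.
#' @param stage character label of the stage.
#' @param k optional integer offset (e.g. repeat number).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
fan_seed <- function(seed, stage, k = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100003
  x <- (abs(as.numeric(seed)) %% 1000003) * 2017 + h * 131 + as.numeric(k) * 7919
  as.integer(x %% 2147483647)
}

# Canonical key for an unordered node pair ("a|b" with a < b).
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Canonicalize a two-column edge table: a < b lexicographically, unique rows,
# no self loops. Accepts a data.frame/matrix with >= 2 columns.
canonical_edges <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(ncol(edges) >= 2)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  df <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  df[order(df$a, df$b), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
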