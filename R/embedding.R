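# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream. All internal randomness goes through this.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed in [0, 2^31 - 2] from a base seed and integer keys.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(h)
}

unit_vector <- function(d) {
  v <- rnorm(d)
  n <- sqrt(sum(v * v))
  while (n < 1e-12) { # essentially impossible, but keep the invariant airtight
    v <- rnorm(d)
    n <- sqrt(sum(v * v))
  }
  v / n
}

#' Embedding provider configuration
#'
#' Configures how per-residue embeddings are produced. The built-in
#' `"synthetic"` provider maps each residue letter to a seeded pseudorandom
#' unit vector and adds a small deterministic position-keyed jitter, so that
#' identical sequences always embed to identical matrices, equal letters have
#' cosine near 1, and distinct letters are near-orthogonal. With `jitter = 0`
#' it degenerates to a "soft identity" embedder in which equal letters have
#' cosine exactly 1. A `"custom"` provider plugs in any function of a
#' [protein_record()] returning an n x dim matrix (e.g. an adapter around a
#' transformer protein language model).
#'
#' @param provider `"synthetic"` or `"custom"`.
#' @param dim Embedding dimension (default 64).
#' @param max_len Maximum sequence length accepted before embedding
#'   (default 1024); longer sequences are rejected unless `truncate = TRUE`.
#' @param seed Integer seed for the synthetic provider.
#' @param jitter Standard deviation of the position-keyed Gaussian jitter
#'   added by the synthetic provider before renormalisation (default 0.05).
#' @param truncate If `TRUE`, sequences longer than `max_len` are truncated
#'   instead of rejected. Off by default.
#' @param fun For `provider = "custom"`: `function(record, config)` returning
#'   the residue embedding matrix.
#' @return An object of class `embedder_config`.
#' @export
embedder_config <- function(provider = c("synthetic", "custom"), dim = 64L,
                            max_len = 1024L, seed = 1L, jitter = 0.05,
                            truncate = FALSE, fun = NULL) {
  provider <- match.arg(provider)
  stopifnot(dim >= 1L, max_len >= 1L, jitter >= 0)
  if (provider == "custom" && !is.function(fun))
    stop("custom provider requires 'fun'", call. = FALSE)
  structure(list(provider = provider, dim = as.integer(dim),
                 max_len = as.integer(max_len), seed = as.integer(seed),
                 jitter = jitter, truncate = isTRUE(truncate), fun = fun),
            class = "embedder_config")
}

# Per-letter base unit vectors, keyed by (seed, dim). Letters outside the
# alphabet never reach here: protein_record() enforces the alphabet.
letter_basis <- function(config) {
  vapply(seq_along(AA_EXTENDED), function(k) {
    with_seed(derive_seed(config$seed, 1000L + k, config$dim),
              unit_vector(config$dim))
  }, numeric(config$dim))
}

#' Embed the residues of a protein record
#'
#' Returns one embedding row per residue. Deterministic: the same record and
#' configuration always yield the same matrix. Sequences longer than
#' `config$max_len` raise a length error (such sequences exceed the context
#' window of the transformer models this mirrors) unless `config$truncate`.
#'
#' @param record A [protein_record()].
#' @param config An [embedder_config()].
#' @return A numeric n x dim matrix with attributes `sequence_id` and `dim`.
#' @export
embed_residues <- function(record, config = embedder_config()) {
  stopifnot(inherits(record, "protein_record"),
            inherits(config, "embedder_config"))
  n <- nchar(record$residues)
  if (n > config$max_len) {
    if (!config$truncate)
      stop("sequence '", record$id, "' has ", n, " residues, exceeding max_len ",
           config$max_len, call. = FALSE)
    record$residues <- substr(record$residues, 1L, config$max_len)
    n <- config$max_len
  }
  if (config$provider == "custom") {
    E <- config$fun(record, config)
    if (!is.matrix(E) || nrow(E) != n || ncol(E) != config$dim)
      stop("custom provider returned a matrix of wrong shape", call. = FALSE)
  } else {
    basis <- letter_basis(config)
    idx <- match(strsplit(record$residues, "", fixed = TRUE)[[1L]], AA_EXTENDED)
    E <- t(basis[, idx, drop = FALSE])
    if (config$jitter > 0) {
      for (p in seq_len(n)) {
        eps <- with_seed(derive_seed(config$seed, 2000L + p, idx[p]),
                         rnorm(config$dim, sd = config$jitter))
        E[p, ] <- E[p, ] + eps
      }
    }
    E <- E / sqrt(rowSums(E * E))
  }
  if (!all(is.finite(E))) stop("non-finite embedding values", call. = FALSE)
  if (any(rowSums(abs(E)) == 0)) stop("all-zero embedding row", call. = FALSE)
  structure(E, sequence_id = record$id)
}

#' Mean-pool a residue embedding matrix
#'
#' Component i of the pooled vector is the arithmetic mean of component i
#' over all residues. Pooling is permutation-invariant in the residues: this
#' information loss is precisely why pooled retrieval is only a candidate
#' heuristic and the residue-level alignment does the real work.
#'
#' @param matrix A residue embedding matrix from [embed_residues()].
#' @return A numeric vector of length `dim` with attribute `sequence_id`.
#' @export
mean_pool <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L)
    stop("cannot pool an empty embedding matrix", call. = FALSE)
  structure(colMeans(matrix), sequence_id = attr(matrix, "sequence_id"))
}

#' Embed a batch of records
#'
#' Order-preserving; per-record failures (e.g. overlong sequences) are
#' collected and reported with their ids rather than aborting the batch.
#'
#' @param records List of [protein_record()] objects.
#' @param config An [embedder_config()].
#' @return A list with `results` (named list of `list(embedding, pooled)`, in
#'   input order, failures omitted) and `errors` (named character vector of
#'   failure messages, possibly empty).
#' @export
embed_batch <- function(records, config = embedder_config()) {
  results <- list()
  errors <- character(0L)
  for (rec in records) {
    E <- tryCatch(embed_residues(rec, config), error = function(e) e)
    if (inherits(E, "error")) {
      errors[[rec$id]] <- conditionMessage(E)
    } else {
      results[[rec$id]] <- list(embedding = E, pooled = mean_pool(E))
    }
  }
  list(results = results, errors = errors)
}
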