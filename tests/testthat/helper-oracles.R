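# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

# Exhaustive max-total-similarity strictly-increasing subset, by recursive
# include/exclude over matches sorted by (i, j). The empty chain scores 0.
brute_chain_score <- function(matches) {
  M <- nrow(matches)
  if (M == 0L) return(0)
  mm <- matches[order(matches$i, matches$j), , drop = FALSE]
  rec <- function(pos, last_i, last_j) {
    if (pos > M) return(0)
    best <- rec(pos + 1L, last_i, last_j)
    if (mm$i[pos] > last_i && mm$j[pos] > last_j)
      best <- max(best, mm$similarity[pos] + rec(pos + 1L, mm$i[pos], mm$j[pos]))
    best
  }
  rec(1L, -Inf, -Inf)
}

# Exhaustive cosine ranking over every database vector.
brute_knn_ids <- function(vectors, ids, query, k) {
  sims <- vapply(vectors, function(v)
    sum(v * query) / sqrt(sum(v * v) * sum(query * query)), numeric(1L))
  ids[head(order(-sims, ids), k)]
}

# Elementwise cosine between two embedding matrices.
brute_cosine_matrix <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      out[i, j] <- sum(A[i, ] * B[j, ]) /
        sqrt(sum(A[i, ]^2) * sum(B[j, ]^2))
  out
}

# A match set directly from (i, j, similarity) triples (0-based indices).
match_set <- function(i, j, similarity, kind = "mutual") {
  data.frame(i = as.integer(i), j = as.integer(j), similarity = similarity,
             kind = rep(kind, length.out = length(i)),
             diagonal = as.integer(j) - as.integer(i))
}

# Classified matches for an explicit similarity matrix.
classify_of <- function(D) classify_matches(D, candidate_lists(D))

tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".faa")
  writeLines(lines, path)
  path
}

# Seeded random residue string over the 20 standard letters.
random_seq <- function(L, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  set.seed(seed)
  paste(sample(aa, L, replace = TRUE), collapse = "")
}

random_match_set <- function(M, n = 12L, m = 12L) {
  cells <- sample(n * m, M)
  match_set(i = (cells - 1L) %/% m, j = (cells - 1L) %% m,
            similarity = runif(M, -0.3, 1))
}
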