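# Combinatorial null model for chance gap-free diagonal runs in an n x n
# residue similarity matrix, plus empirical estimation of the single-match
# probability from presumed-unrelated sequence pairs.

#' Count length-k windows over the diagonals of an n x n matrix
#'
#' A gap-free run of k matches occupies k consecutive cells on one top-left
#' to bottom-right diagonal. An n x n matrix has one diagonal of length n and
#' two of each length 1..n-1, so the number of distinct k-windows is
#' S = (n - k + 1) + 2 * sum_{i=k}^{n-1} (i - k + 1).
#'
#' @param n Matrix side (sequence length).
#' @param k Run length, 1 <= k <= n.
#' @return Integer-valued count S.
#' @export
count_k_windows <- function(n, k) {
  stopifnot(n >= 1L, k >= 1L)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  i <- seq_len(n - 1L)
  i <- i[i >= k]
  (n - k + 1) + 2 * sum(i - k + 1)
}

#' Brute-force enumeration oracle for diagonal k-windows
#'
#' Literally walks every top-left to bottom-right diagonal of the n x n grid
#' and counts its length-k windows. Exists as an independent check on
#' [count_k_windows()]; guarded to small n.
#'
#' @param n Matrix side (<= 500).
#' @param k Run length.
#' @return Count of k-windows.
#' @export
enumerate_k_windows_bruteforce <- function(n, k) {
  stopifnot(n >= 1L, k >= 1L, k <= n)
  if (n > 500L) stop("brute-force enumeration guarded to n <= 500", call. = FALSE)
  total <- 0L
  for (d in seq.int(-(n - 1L), n - 1L)) {
    len <- n - abs(d)
    if (len >= k) total <- total + (len - k + 1L)
  }
  total
}

#' Probability of a chance gap-free run of length k
#'
#' Probability that k positions drawn at random from the n x n matrix form a
#' consecutive run on one diagonal and all k are matches, each independently
#' with probability p: P(k | p, n) = S / C(n^2, k) * p^k. Computed in log
#' space (C(n^2, k) overflows double arithmetic long before n reaches
#' realistic protein lengths).
#'
#' @param n Sequence length (square-matrix model).
#' @param k Run length.
#' @param p Single-match probability in `[0, 1]`.
#' @return A list of class `null_model_result`: `S`, `log10_total_choices`,
#'   `total_choices` (Inf if unrepresentable), `probability` (0 when
#'   underflowed; see `log10_probability`), `log10_probability`, and the
#'   inputs `n`, `k`, `p`.
#' @export
run_probability <- function(n, k, p) {
  stopifnot(n >= 1L, k >= 1L, k <= n, p >= 0, p <= 1)
  S <- count_k_windows(n, k)
  lchoices <- lchoose(as.double(n)^2, k)
  l10 <- if (p == 0) -Inf else
    (log(S) - lchoices + k * log(p)) / log(10)
  structure(list(
    n = n, k = k, p = p, S = S,
    total_choices = exp(lchoices),
    log10_total_choices = lchoices / log(10),
    probability = if (is.infinite(l10)) 0 else 10^l10,
    log10_probability = l10), class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("Chance gap-free run model (n = %d, k = %d, p = %.4g)\n",
              x$n, x$k, x$p))
  cat(sprintf("  S = %.0f k-windows; C(n^2, k) = %.4g (log10 %.3f)\n",
              x$S, x$total_choices, x$log10_total_choices))
  cat(sprintf("  P(k | p, n) = %.4g (log10 %.3f)\n",
              x$probability, x$log10_probability))
  invisible(x)
}

#' Estimate the single-match probability from unrelated pairs
#'
#' Pools classified matches over presumed-unrelated sequence pairs:
#' p-hat = (total mutual + secondary matches) / (sum over pairs of n * m).
#' Also reports the mean match count per pair, the companion statistic for
#' judging how often spurious correspondences arise at all.
#'
#' @param pairs List where each element is either a `soft_alignment` (its
#'   pre-chain `$matches`, `$n`, `$m` are used) or a
#'   `list(matches = <match set>, n = , m = )`.
#' @return List with `p_hat`, `mean_matches_per_pair`, `total_matches`,
#'   `total_cells`, `n_pairs`.
#' @export
estimate_p <- function(pairs) {
  if (!length(pairs)) stop("estimate_p needs at least one pair", call. = FALSE)
  counts <- vapply(pairs, function(x) {
    m <- x$matches
    sum(m$kind %in% c("mutual", "secondary"))
  }, numeric(1L))
  cells <- vapply(pairs, function(x) as.double(x$n) * as.double(x$m),
                  numeric(1L))
  list(p_hat = sum(counts) / sum(cells),
       mean_matches_per_pair = mean(counts),
       total_matches = sum(counts), total_cells = sum(cells),
       n_pairs = length(pairs))
}

#' Null distribution of soft-alignment scores on unrelated pairs
#'
#' Generates independent unrelated sequence pairs (background embeddings,
#' no planted homology), soft-aligns each, and summarises the score
#' distribution and the fraction declared significant at `min_score`.
#'
#' @param length_q,length_s Sequence lengths per replicate.
#' @param replicates Number of pairs.
#' @param seed Base seed; replicate r uses a seed derived from (seed, r).
#' @param dim Embedding dimension (default 64).
#' @param min_score Significance threshold (default 20).
#' @param ... Further arguments to [soft_align()].
#' @return List with `scores`, `quantiles` (0/25/50/75/95/100%),
#'   `fraction_significant`, `min_score`, `replicates`.
#' @export
simulate_null_scores <- function(length_q = 100L, length_s = length_q,
                                 replicates = 100L, seed = 1L, dim = 64L,
                                 min_score = 20, ...) {
  stopifnot(replicates >= 1L)
  scores <- vapply(seq_len(replicates), function(r) {
    fx <- generate_unrelated_pair(length_q, length_s,
                                  seed = derive_seed(seed, 100L, r), dim = dim)
    soft_align(fx$q, fx$s, E_q = fx$E_q, E_s = fx$E_s,
               min_score = min_score, ...)$score
  }, numeric(1L))
  list(scores = scores,
       quantiles = quantile(scores, c(0, .25, .5, .75, .95, 1)),
       fraction_significant = mean(scores >= min_score),
       min_score = min_score, replicates = replicates)
}
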