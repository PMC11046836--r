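# Core soft-alignment algorithm: residue-level cosine similarity matrix,
# mutual/secondary match classification, diagonal filtering, single-gap
# rescue, and maximum-score chaining.
#
# Coordinates are 0-based internally (i over query rows, j over subject
# columns, diagonal offset d = j - i); rendered and reported output is
# 1-based inclusive.

#' Residue-level cosine similarity matrix
#'
#' Entry (i, j) is the cosine similarity between the embedding of query
#' residue i and subject residue j. `similarity_matrix(A, B)` is the
#' transpose of `similarity_matrix(B, A)`.
#'
#' @param E_q,E_s Residue embedding matrices (rows = residues) of equal
#'   column dimension, e.g. from [embed_residues()].
#' @return An n x m numeric matrix with entries in `[-1, 1]`, attributes
#'   `query_id` and `subject_id`.
#' @export
similarity_matrix <- function(E_q, E_s) {
  if (!is.matrix(E_q) || !is.matrix(E_s))
    stop("embedding inputs must be matrices", call. = FALSE)
  if (ncol(E_q) != ncol(E_s))
    stop("embedding dimension mismatch: ", ncol(E_q), " vs ", ncol(E_s),
         call. = FALSE)
  nq <- sqrt(rowSums(E_q * E_q))
  ns <- sqrt(rowSums(E_s * E_s))
  if (any(nq < 1e-12) || any(ns < 1e-12))
    stop("zero-norm embedding row", call. = FALSE)
  D <- tcrossprod(E_q / nq, E_s / ns)
  D <- pmin(pmax(D, -1), 1)  # clamp rounding excursions beyond [-1, 1]
  structure(D, query_id = attr(E_q, "sequence_id"),
            subject_id = attr(E_s, "sequence_id"))
}

#' Top-t candidate lists per row and per column
#'
#' For each query residue, the indices (1-based) of the `t` subject residues
#' with the largest similarity, in descending order; likewise per subject
#' residue over the query. Exact ties are broken by lower index. When a
#' dimension is smaller than `t`, the whole dimension is returned.
#'
#' @param D Similarity matrix from [similarity_matrix()].
#' @param t Candidate list length (default 3).
#' @return `list(C_q = <list of n integer vectors>, C_s = <list of m>)`.
#' @export
candidate_lists <- function(D, t = 3L) {
  stopifnot(t >= 1L)
  top_t <- function(v) head(order(-v, seq_along(v)), min(t, length(v)))
  list(C_q = apply(D, 1L, top_t, simplify = FALSE),
       C_s = apply(D, 2L, top_t, simplify = FALSE))
}

empty_matches <- function() {
  data.frame(i = integer(0L), j = integer(0L), similarity = numeric(0L),
             kind = character(0L), diagonal = integer(0L))
}

#' Classify mutual and secondary residue matches
#'
#' A pair (i, j) is a mutual match when j is the argmax of row i and i is the
#' argmax of column j (each residue is the other's single best match). A pair
#' is a secondary match when it is not mutual, each residue appears in the
#' other's top-`t` candidate list, and neither residue participates in any
#' mutual pair. Mutual matches therefore form a one-to-one partial mapping.
#'
#' @param D Similarity matrix.
#' @param cands Candidate lists from [candidate_lists()]; recomputed when
#'   omitted.
#' @return A match set: data.frame with columns `i`, `j` (0-based), `similarity`,
#'   `kind` (`"mutual"`/`"secondary"`), `diagonal` (= j - i).
#' @export
classify_matches <- function(D, cands = candidate_lists(D)) {
  n <- nrow(D); m <- ncol(D)
  if (n == 0L || m == 0L) return(empty_matches())
  row_best <- vapply(cands$C_q, `[[`, integer(1L), 1L)  # argmax per row
  col_best <- vapply(cands$C_s, `[[`, integer(1L), 1L)  # argmax per column
  mut_i <- which(col_best[row_best] == seq_len(n))
  mut_j <- row_best[mut_i]
  in_mut_row <- seq_len(n) %in% mut_i
  in_mut_col <- seq_len(m) %in% mut_j
  sec_i <- integer(0L); sec_j <- integer(0L)
  for (i in seq_len(n)) {
    if (in_mut_row[i]) next
    for (j in cands$C_q[[i]]) {
      if (in_mut_col[j]) next
      if (i %in% cands$C_s[[j]] && !(i %in% mut_i && j == mut_j[match(i, mut_i)]))
        { sec_i <- c(sec_i, i); sec_j <- c(sec_j, j) }
    }
  }
  ii <- c(mut_i, sec_i); jj <- c(mut_j, sec_j)
  out <- data.frame(
    i = ii - 1L, j = jj - 1L,
    similarity = D[cbind(ii, jj)],
    kind = rep(c("mutual", "secondary"), c(length(mut_i), length(sec_i))),
    diagonal = (jj - 1L) - (ii - 1L))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Filter spurious diagonals
#'
#' Matches off the dominant alignment diagonals are usually noise: a diagonal
#' d is retained only if it carries at least `min_mutual` mutual matches, or
#' lies within `neighbor_window` insertions/deletions of a diagonal carrying
#' strictly more than `min_mutual` mutual matches. All matches (of any kind)
#' on non-retained diagonals are removed; filtering never adds matches.
#'
#' @param matches Match set from [classify_matches()].
#' @param min_mutual Minimum mutual-match count for a diagonal to stand on
#'   its own (default 5).
#' @param neighbor_window Maximum |d - d'| for neighbour rescue (default 5).
#' @param count_secondary If `TRUE`, secondary matches also count toward the
#'   per-diagonal tally (default `FALSE`: mutual only).
#' @return The filtered match set, with retained diagonals in attribute
#'   `retained_diagonals`.
#' @export
filter_diagonals <- function(matches, min_mutual = 5L, neighbor_window = 5L,
                             count_secondary = FALSE) {
  if (nrow(matches) == 0L) {
    attr(matches, "retained_diagonals") <- integer(0L)
    return(matches)
  }
  tallied <- if (count_secondary) matches else
    matches[matches$kind == "mutual", , drop = FALSE]
  counts <- table(factor(tallied$diagonal))
  diags <- as.integer(names(counts))
  cnt <- as.integer(counts)
  strong <- diags[cnt >= min_mutual]
  anchors <- diags[cnt > min_mutual]  # strict, per the asymmetric rule
  near_anchor <- function(d) any(abs(d - anchors) <= neighbor_window)
  retained <- sort(unique(c(
    strong,
    if (length(anchors)) Filter(near_anchor, diags) else integer(0L))))
  out <- matches[matches$diagonal %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_diagonals") <- retained
  out
}

#' Rescue single identical-residue gaps on retained diagonals
#'
#' A lone missing cell (i, j) on a retained diagonal whose two immediate
#' diagonal neighbours (i-1, j-1) and (i+1, j+1) are both retained matches is
#' promoted to a match of kind `"rescued"` when the query and subject
#' residues at those positions are the same amino acid (X equals X). Runs of
#' two or more consecutive missing cells are never rescued.
#'
#' @param matches Filtered match set (from [filter_diagonals()]).
#' @param q,s The query and subject [protein_record()]s.
#' @param D The similarity matrix (supplies the rescued cell's similarity).
#' @return The match set with any rescued matches appended.
#' @export
rescue_single_gaps <- function(matches, q, s, D) {
  retained <- attr(matches, "retained_diagonals")
  if (is.null(retained)) retained <- sort(unique(matches$diagonal))
  if (nrow(matches) == 0L || length(retained) == 0L) return(matches)
  qc <- strsplit(q$residues, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s$residues, "", fixed = TRUE)[[1L]]
  key <- paste(matches$i, matches$j)
  add_i <- integer(0L); add_j <- integer(0L)
  for (d in retained) {
    on_d <- matches[matches$diagonal == d, , drop = FALSE]
    if (nrow(on_d) < 2L) next
    is_match <- function(i) paste(i, i + d) %in% key
    for (i in sort(on_d$i)) {
      g <- i + 1L  # candidate gap cell just below-right of a match
      if (g + 1L > nrow(D) - 1L || g + d + 1L > ncol(D) - 1L) next
      if (g + d < 0L) next
      if (!is_match(g) && is_match(g + 1L) && qc[g + 1L] == sc[g + d + 1L])
        { add_i <- c(add_i, g); add_j <- c(add_j, g + d) }
    }
  }
  if (length(add_i)) {
    rescued <- data.frame(i = add_i, j = add_j,
                          similarity = D[cbind(add_i + 1L, add_j + 1L)],
                          kind = "rescued", diagonal = add_j - add_i)
    rescued <- unique(rescued)
    out <- rbind(matches, rescued)
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "retained_diagonals") <- retained
    return(out)
  }
  matches
}

# Maximum-total-similarity subset of matches strictly increasing in both i
# and j: O(M^2) dynamic program over matches sorted by (i, j).
chain_matches <- function(matches) {
  M <- nrow(matches)
  if (M == 0L) return(matches)
  ord <- order(matches$i, matches$j)
  mm <- matches[ord, , drop = FALSE]
  best <- mm$similarity
  prev <- rep(NA_integer_, M)
  for (v in seq_len(M)) {
    if (v == 1L) next
    u_ok <- which(mm$i[seq_len(v - 1L)] < mm$i[v] &
                  mm$j[seq_len(v - 1L)] < mm$j[v])
    if (length(u_ok)) {
      u <- u_ok[which.max(best[u_ok])]
      if (best[u] > 0) {
        best[v] <- mm$similarity[v] + best[u]
        prev[v] <- u
      }
    }
  }
  end <- which.max(best)
  if (best[end] < 0) return(mm[0L, , drop = FALSE])  # empty chain beats any negative total
  path <- integer(0L)
  v <- end
  while (!is.na(v)) { path <- c(v, path); v <- prev[v] }
  out <- mm[path, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain matches into an optimal soft alignment and score it
#'
#' Selects the subset of matches with maximum total cosine similarity that is
#' strictly increasing in both query and subject position (crossing pairs are
#' mutually exclusive), via dynamic programming. The score is the sum of the
#' chained similarities; the alignment is significant when the score reaches
#' `min_score`. An empty match set scores 0 and is not significant.
#'
#' @param matches Match set (any mix of mutual/secondary/rescued).
#' @param min_score Significance threshold on the summed score (default 20,
#'   calibrated so that reported pairs behave like conventional-aligner hits
#'   at a stringent e-value).
#' @param query_id,subject_id Optional ids recorded in the result.
#' @return An object of class `soft_alignment`: list with `chain` (data.frame),
#'   `score`, `significant`, `counts` (by kind, chained matches only),
#'   `n_matches` (input size), `query_range`/`subject_range` (1-based
#'   inclusive spans of the chain, NULL when empty).
#' @export
chain_and_score <- function(matches, min_score = 20,
                            query_id = NULL, subject_id = NULL) {
  chain <- chain_matches(matches)
  score <- sum(chain$similarity)
  counts <- c(mutual = sum(chain$kind == "mutual"),
              secondary = sum(chain$kind == "secondary"),
              rescued = sum(chain$kind == "rescued"))
  structure(list(
    query_id = query_id, subject_id = subject_id,
    chain = chain, score = score,
    significant = score >= min_score, min_score = min_score,
    counts = counts, n_matches = nrow(matches),
    query_range = if (nrow(chain)) range(chain$i) + 1L else NULL,
    subject_range = if (nrow(chain)) range(chain$j) + 1L else NULL),
    class = "soft_alignment")
}

#' Soft-align two protein sequences
#'
#' The full pipeline on one pair: embed both sequences (or use supplied
#' embeddings), build the residue cosine similarity matrix, classify mutual
#' and secondary matches from top-`t` candidate lists, drop matches on weakly
#' supported diagonals, rescue single identical-residue gaps, and chain the
#' survivors into the maximum-score monotone alignment.
#'
#' Sequences shorter than `min_mutual` can never populate a diagonal well
#' enough to pass filtering; a warning is emitted and, unless
#' `filter = FALSE`, the result is empty.
#'
#' @param q,s [protein_record()] objects.
#' @param config [embedder_config()] used when embeddings are not supplied.
#' @param E_q,E_s Optional precomputed residue embedding matrices.
#' @param t Candidate list length (default 3).
#' @param min_mutual,neighbor_window Diagonal filter parameters (defaults 5, 5).
#' @param min_score Significance threshold (default 20).
#' @param filter Set `FALSE` to skip diagonal filtering and gap rescue
#'   (diagnostics; short sequences).
#' @param count_secondary Passed to [filter_diagonals()].
#' @return A `soft_alignment` object (see [chain_and_score()]), with the
#'   pre-chain match set in `$matches` and matrix dimensions in `$n`, `$m`.
#' @examples
#' q <- protein_record("q1", "MKVLATTHE")
#' s <- protein_record("s1", "MKVLATTHE")
#' soft_align(q, s, filter = FALSE)
#' @export
soft_align <- function(q, s, config = embedder_config(), E_q = NULL, E_s = NULL,
                       t = 3L, min_mutual = 5L, neighbor_window = 5L,
                       min_score = 20, filter = TRUE, count_secondary = FALSE) {
  if (is.null(E_q)) E_q <- embed_residues(q, config)
  if (is.null(E_s)) E_s <- embed_residues(s, config)
  D <- similarity_matrix(E_q, E_s)
  matches <- classify_matches(D, candidate_lists(D, t))
  if (filter) {
    if (min(nrow(D), ncol(D)) < min_mutual)
      warning("sequence pair shorter than min_mutual = ", min_mutual,
              "; no diagonal can pass filtering (use filter = FALSE to inspect)",
              call. = FALSE)
    matches <- filter_diagonals(matches, min_mutual, neighbor_window,
                                count_secondary)
    matches <- rescue_single_gaps(matches, q, s, D)
  }
  res <- chain_and_score(matches, min_score, query_id = q$id, subject_id = s$id)
  res$matches <- matches
  res$n <- nrow(D)
  res$m <- ncol(D)
  res
}

#' @export
print.soft_alignment <- function(x, ...) {
  cat("Soft alignment", x$query_id %||% "?", "vs", x$subject_id %||% "?", "\n")
  cat(sprintf("  score %.3f (threshold %.3g) — %s\n", x$score, x$min_score,
              if (x$significant) "significant" else "not significant"))
  cat(sprintf("  chain: %d matches (%d mutual, %d secondary, %d rescued)\n",
              nrow(x$chain), x$counts[["mutual"]], x$counts[["secondary"]],
              x$counts[["rescued"]]))
  if (!is.null(x$query_range))
    cat(sprintf("  query %d-%d, subject %d-%d\n", x$query_range[1L],
                x$query_range[2L], x$subject_range[1L], x$subject_range[2L]))
  invisible(x)
}

#' @export
summary.soft_alignment <- function(object, ...) {
  chain <- object$chain
  out <- list(
    query_id = object$query_id, subject_id = object$subject_id,
    score = object$score, significant = object$significant,
    counts = object$counts, n_chain = nrow(chain),
    n_candidate_matches = object$n_matches,
    mean_similarity = if (nrow(chain)) mean(chain$similarity) else NA_real_,
    diagonals = sort(unique(chain$diagonal)),
    query_range = object$query_range, subject_range = object$subject_range)
  class(out) <- "summary.soft_alignment"
  out
}

#' @export
print.summary.soft_alignment <- function(x, ...) {
  cat("Soft alignment summary:", x$query_id %||% "?", "vs",
      x$subject_id %||% "?", "\n")
  cat(sprintf("  score %.3f (%ssignificant), %d chained of %d candidate matches\n",
              x$score, if (x$significant) "" else "not ", x$n_chain,
              x$n_candidate_matches))
  if (x$n_chain) {
    cat(sprintf("  mean chained cosine %.3f; diagonals %s\n", x$mean_similarity,
                paste(x$diagonals, collapse = ", ")))
    cat(sprintf("  query %d-%d, subject %d-%d\n", x$query_range[1L],
                x$query_range[2L], x$subject_range[1L], x$subject_range[2L]))
  }
  invisible(x)
}

#' Dot-plot of a soft alignment
#'
#' Plots retained matches in (query, subject) position space (1-based),
#' distinguishing chained matches; co-linear homologous blocks appear as
#' diagonals, as in a classical dot plot.
#'
#' @param x A `soft_alignment` from [soft_align()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.soft_alignment <- function(x, ...) {
  m <- x$matches %||% x$chain
  if (is.null(m) || nrow(m) == 0L) {
    graphics::plot(1, 1, type = "n", xlab = "query position",
                   ylab = "subject position", ...)
    graphics::text(1, 1, "no matches")
    return(invisible(x))
  }
  pch <- c(mutual = 19L, secondary = 1L, rescued = 3L)[m$kind]
  graphics::plot(m$i + 1L, m$j + 1L, pch = pch,
                 xlim = c(1L, max(x$n %||% max(m$i + 1L), 2L)),
                 ylim = c(1L, max(x$m %||% max(m$j + 1L), 2L)),
                 xlab = "query position", ylab = "subject position",
                 main = sprintf("%s vs %s (score %.1f)",
                                x$query_id %||% "query",
                                x$subject_id %||% "subject", x$score), ...)
  ch <- x$chain
  if (nrow(ch)) graphics::lines(ch$i + 1L, ch$j + 1L, col = "grey50")
  invisible(x)
}
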