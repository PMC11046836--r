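# Fixture generators with controlled homology structure. Unrelated pairs are
# background noise (i.i.d. unit-sphere residue embeddings, expected pairwise
# cosine 0); homologous pairs carry a planted co-linear block of
# high-cosine residue correspondences along a chosen diagonal. All output is
# fully determined by the seed.

random_residues <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# Unit vector at a fixed cosine to u: spherical interpolation toward a
# random direction orthogonal to u. cos(angle between result and u) == target.
slerp_at_cosine <- function(u, target) {
  d <- length(u)
  v <- unit_vector(d)
  v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v * v))
  theta <- acos(pmin(pmax(target, -1), 1))
  cos(theta) * u + sin(theta) * v
}

#' Generate an unrelated background sequence pair
#'
#' Residues drawn uniformly from the 20 standard letters; residue embeddings
#' are i.i.d. unit vectors, so the expected cosine between any query/subject
#' residue pair is 0 with spread about 1/sqrt(dim). Emulates sequence pairs
#' with no detectable homology.
#'
#' @param length_q,length_s Sequence lengths.
#' @param seed Integer seed; output is fully determined by it.
#' @param dim Embedding dimension (default 64).
#' @return List with records `q`, `s` and embedding matrices `E_q`, `E_s`.
#' @export
generate_unrelated_pair <- function(length_q, length_s = length_q, seed = 1L,
                                    dim = 64L) {
  stopifnot(length_q >= 1L, length_s >= 1L)
  with_seed(seed, {
    q <- protein_record("query_bg", random_residues(length_q))
    s <- protein_record("subject_bg", random_residues(length_s))
    E_q <- t(vapply(seq_len(length_q), function(i) unit_vector(dim),
                    numeric(dim)))
    E_s <- t(vapply(seq_len(length_s), function(i) unit_vector(dim),
                    numeric(dim)))
    attr(E_q, "sequence_id") <- q$id
    attr(E_s, "sequence_id") <- s$id
    list(q = q, s = s, E_q = E_q, E_s = E_s)
  })
}

#' Generate a homologous pair with planted co-linear blocks
#'
#' Background as in [generate_unrelated_pair()], except that inside each
#' planted block the subject residue embeddings are spherical perturbations
#' of the corresponding query embeddings at a controlled cosine, and the
#' subject residues copy the query residues (so identity-based gap rescue is
#' exercised faithfully). Block pairs lie on the single diagonal
#' `offset = j - i`.
#'
#' @param length_q,length_s Sequence lengths.
#' @param blocks Data frame (or list coercible to one) with columns
#'   `q_start` (1-based query start), `offset` (diagonal, subject start =
#'   q_start + offset) and `length`; optional `cosine` per block.
#' @param block_cosine Cosine between corresponding block embeddings
#'   (default 0.97) when `blocks$cosine` is absent.
#' @param seed Integer seed.
#' @param dim Embedding dimension (default 64).
#' @return List with `q`, `s`, `E_q`, `E_s` and `truth`, a data.frame of the
#'   planted (i, j) residue correspondences (0-based) with their block index.
#' @export
generate_homologous_pair <- function(length_q, length_s = length_q,
                                     blocks = data.frame(q_start = 11L,
                                                         offset = 0L,
                                                         length = 30L),
                                     block_cosine = 0.97, seed = 1L,
                                     dim = 64L) {
  blocks <- as.data.frame(blocks)
  if (is.null(blocks$cosine)) blocks$cosine <- block_cosine
  for (b in seq_len(nrow(blocks))) {
    qs <- blocks$q_start[b]; off <- blocks$offset[b]; len <- blocks$length[b]
    if (len < 1L || qs < 1L || qs + len - 1L > length_q ||
        qs + off < 1L || qs + off + len - 1L > length_s)
      stop("block ", b, " does not fit inside the sequences", call. = FALSE)
  }
  with_seed(seed, {
    qres <- strsplit(random_residues(length_q), "", fixed = TRUE)[[1L]]
    sres <- strsplit(random_residues(length_s), "", fixed = TRUE)[[1L]]
    E_q <- t(vapply(seq_len(length_q), function(i) unit_vector(dim),
                    numeric(dim)))
    E_s <- t(vapply(seq_len(length_s), function(i) unit_vector(dim),
                    numeric(dim)))
    truth <- NULL
    for (b in seq_len(nrow(blocks))) {
      qs <- blocks$q_start[b]; off <- blocks$offset[b]; len <- blocks$length[b]
      qi <- qs:(qs + len - 1L)
      sj <- qi + off
      sres[sj] <- qres[qi]
      for (r in seq_len(len))
        E_s[sj[r], ] <- slerp_at_cosine(E_q[qi[r], ], blocks$cosine[b])
      truth <- rbind(truth, data.frame(i = qi - 1L, j = sj - 1L, block = b))
    }
    q <- protein_record("query_hom", paste(qres, collapse = ""))
    s <- protein_record("subject_hom", paste(sres, collapse = ""))
    attr(E_q, "sequence_id") <- q$id
    attr(E_s, "sequence_id") <- s$id
    list(q = q, s = s, E_q = E_q, E_s = E_s, truth = truth)
  })
}

#' Generate a labelled annotation database fixture
#'
#' Builds `n_subjects` background subjects with category labels, plus
#' designated queries each homologous to one known subject (a planted block
#' spanning most of the pair). Optionally adds pooled decoys: subjects whose
#' residue embeddings all point near the query's pooled direction, so their
#' pooled cosine to the query beats the true homolog's while offering no
#' co-linear residue-level signal. Decoys emulate the information loss of
#' mean pooling that makes small-k candidate retrieval miss true homologs.
#'
#' @param n_subjects Number of ordinary (background) subjects.
#' @param n_queries Number of queries; query t is homologous to subject t.
#' @param categories Character vector of category names cycled over subjects.
#' @param length Sequence length used throughout (default 60).
#' @param block_length Planted block length (default 40).
#' @param block_cosine Planted block cosine (default 0.97).
#' @param n_decoys Number of pooled decoys per query (default 0).
#' @param seed Integer seed.
#' @param dim Embedding dimension (default 64).
#' @return List with `subjects`/`queries` (lists of records),
#'   `embeddings` (named list of residue matrices for all records),
#'   `labels` (named character vector over subjects; decoys labelled
#'   `"Decoy"`), and `truth` (data.frame query_id, subject_id, category).
#' @export
generate_annotation_db <- function(n_subjects = 20L, n_queries = 5L,
                                   categories = c("Capsid Proteins",
                                                  "Envelope Proteins",
                                                  "Replication and Transcription Proteins",
                                                  "Assembly and Release Proteins",
                                                  "Regulatory and Accessory Proteins"),
                                   length = 60L, block_length = 40L,
                                   block_cosine = 0.97, n_decoys = 0L,
                                   seed = 1L, dim = 64L) {
  stopifnot(n_queries <= n_subjects, block_length <= length)
  subjects <- list(); queries <- list(); embeddings <- list()
  labels <- character(0L); truth <- NULL
  for (t in seq_len(n_subjects)) {
    sid <- sprintf("SUBJ_%03d", t)
    cat_t <- categories[((t - 1L) %% length(categories)) + 1L]
    if (t <= n_queries) {
      fx <- generate_homologous_pair(
        length, length,
        blocks = data.frame(q_start = (length - block_length) %/% 2L + 1L,
                            offset = 0L, length = block_length),
        block_cosine = block_cosine, seed = derive_seed(seed, 300L, t),
        dim = dim)
      qid <- sprintf("QUERY_%03d", t)
      q <- protein_record(qid, fx$q$residues)
      s <- protein_record(sid, fx$s$residues)
      attr(fx$E_q, "sequence_id") <- qid
      attr(fx$E_s, "sequence_id") <- sid
      queries[[qid]] <- q
      subjects[[sid]] <- s
      embeddings[[qid]] <- fx$E_q
      embeddings[[sid]] <- fx$E_s
      truth <- rbind(truth, data.frame(query_id = qid, subject_id = sid,
                                       category = cat_t))
    } else {
      fx <- generate_unrelated_pair(length, length,
                                    seed = derive_seed(seed, 400L, t),
                                    dim = dim)
      s <- protein_record(sid, fx$s$residues)
      attr(fx$E_s, "sequence_id") <- sid
      subjects[[sid]] <- s
      embeddings[[sid]] <- fx$E_s
    }
    labels[sid] <- cat_t
  }
  if (n_decoys > 0L) {
    for (t in seq_len(n_queries)) {
      qid <- sprintf("QUERY_%03d", t)
      pq <- mean_pool(embeddings[[qid]])
      pq <- pq / sqrt(sum(pq * pq))
      for (dck in seq_len(n_decoys)) {
        did <- sprintf("DECOY_%03d_%02d", t, dck)
        E_d <- with_seed(derive_seed(seed, 500L, t, dck), {
          # every row hugs the query's pooled direction: pooled cosine ~ 1,
          # but no position-specific diagonal structure
          t(vapply(seq_len(length), function(i)
            slerp_at_cosine(pq, 0.995), numeric(dim)))
        })
        drec <- with_seed(derive_seed(seed, 600L, t, dck),
                          protein_record(did, random_residues(length)))
        attr(E_d, "sequence_id") <- did
        subjects[[did]] <- drec
        embeddings[[did]] <- E_d
        labels[did] <- "Decoy"
      }
    }
  }
  list(subjects = subjects, queries = queries, embeddings = embeddings,
       labels = labels, truth = truth)
}

#' Write an annotation fixture to disk
#'
#' Writes subjects and queries as FASTA, labels and truth as 2-column TSV.
#' Embeddings stay in memory (regenerate from the seed).
#'
#' @param db Output of [generate_annotation_db()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(db$subjects, file.path(dir, "subjects.faa"))
  write_fasta(db$queries, file.path(dir, "queries.faa"))
  write_labels(db$labels, file.path(dir, "labels.tsv"))
  write_labels(setNames(db$truth$category, db$truth$query_id),
               file.path(dir, "truth.tsv"))
  invisible(dir)
}
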