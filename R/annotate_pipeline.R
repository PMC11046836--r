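# End-to-end annotation transfer: pooled-embedding KNN candidate retrieval,
# residue-level soft alignment of the candidates, category transfer from the
# best significant hit, with a second retrieval stage at larger k for
# queries the first stage fails to annotate.

#' Annotation pipeline configuration
#'
#' @param knn_k Candidates retrieved per query at stage one (default 5).
#' @param escalate_k Larger k used once for queries with no significant
#'   alignment at stage one (default 15; 0 disables escalation).
#' @param min_score Soft-alignment significance threshold (default 20).
#' @param pooled_threshold Minimum pooled cosine similarity for the pooled
#'   baseline to make a call (default `NULL`: no threshold).
#' @param exclude_self Skip a database row with the query's own id.
#' @param t,min_mutual,neighbor_window Soft-alignment parameters (see
#'   [soft_align()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(knn_k = 5L, escalate_k = 15L, min_score = 20,
                            pooled_threshold = NULL, exclude_self = FALSE,
                            t = 3L, min_mutual = 5L, neighbor_window = 5L) {
  stopifnot(knn_k >= 1L, escalate_k == 0L || escalate_k >= knn_k)
  structure(list(knn_k = as.integer(knn_k), escalate_k = as.integer(escalate_k),
                 min_score = min_score, pooled_threshold = pooled_threshold,
                 exclude_self = isTRUE(exclude_self), t = as.integer(t),
                 min_mutual = as.integer(min_mutual),
                 neighbor_window = as.integer(neighbor_window)),
            class = "pipeline_config")
}

no_call <- function(query_id, method) {
  data.frame(query_id = query_id, method = method, subject_id = NA_character_,
             category = NA_character_, soft_score = NA_real_,
             pooled_cosine = NA_real_, n_mutual = NA_integer_,
             n_secondary = NA_integer_, n_rescued = NA_integer_,
             q_start = NA_integer_, q_end = NA_integer_,
             s_start = NA_integer_, s_end = NA_integer_,
             knn_rank = NA_integer_, escalated = FALSE, significant = FALSE)
}

call_row <- function(query_id, method, subject_id, category, aln, cosine,
                     rank, escalated) {
  data.frame(query_id = query_id, method = method, subject_id = subject_id,
             category = category,
             soft_score = if (is.null(aln)) NA_real_ else aln$score,
             pooled_cosine = cosine,
             n_mutual = if (is.null(aln)) NA_integer_ else aln$counts[["mutual"]],
             n_secondary = if (is.null(aln)) NA_integer_ else aln$counts[["secondary"]],
             n_rescued = if (is.null(aln)) NA_integer_ else aln$counts[["rescued"]],
             q_start = if (is.null(aln)) NA_integer_ else aln$query_range[1L],
             q_end = if (is.null(aln)) NA_integer_ else aln$query_range[2L],
             s_start = if (is.null(aln)) NA_integer_ else aln$subject_range[1L],
             s_end = if (is.null(aln)) NA_integer_ else aln$subject_range[2L],
             knn_rank = rank, escalated = escalated,
             significant = if (is.null(aln)) NA else aln$significant)
}

align_stage <- function(query, E_q, index, db_embeddings, db_records, k,
                        config) {
  hits <- knn_search(index, mean_pool(E_q), k = k,
                     exclude_self = config$exclude_self, self_id = query$id)
  if (nrow(hits) == 0L) return(NULL)
  results <- vector("list", nrow(hits))
  for (h in seq_len(nrow(hits))) {
    sid <- hits$subject_id[h]
    E_s <- db_embeddings[[sid]]
    if (is.null(E_s)) next
    aln <- suppressWarnings(soft_align(
      query, db_records[[sid]], E_q = E_q, E_s = E_s, t = config$t,
      min_mutual = config$min_mutual, neighbor_window = config$neighbor_window,
      min_score = config$min_score))
    results[[h]] <- list(aln = aln, cosine = hits$cosine_similarity[h],
                         rank = hits$rank[h], subject_id = sid)
  }
  results <- Filter(function(r) !is.null(r) && r$aln$significant, results)
  if (!length(results)) return(NULL)
  # best soft score; ties by pooled cosine, then id
  scores <- vapply(results, function(r) r$aln$score, numeric(1L))
  cosines <- vapply(results, function(r) r$cosine, numeric(1L))
  ids <- vapply(results, function(r) r$subject_id, character(1L))
  results[[order(-scores, -cosines, ids)[1L]]]
}

#' Annotate one query by soft alignment of its KNN candidates
#'
#' Retrieves `knn_k` candidates by pooled cosine, soft-aligns the query
#' against each, and transfers the category of the candidate with the
#' highest significant soft score. If no candidate is significant and
#' `escalate_k > 0`, retrieval is repeated once with `escalate_k`
#' candidates; otherwise no call is made.
#'
#' @param query A [protein_record()].
#' @param E_q The query's residue embedding matrix.
#' @param index A [build_index()] over the subject pooled embeddings.
#' @param db_embeddings Named list of subject residue embedding matrices.
#' @param db_records Named list of subject [protein_record()]s.
#' @param labels Named character vector of subject categories.
#' @param config A [pipeline_config()].
#' @return A one-row data.frame (see [annotate()] for columns).
#' @export
annotate_query_softalign <- function(query, E_q, index, db_embeddings,
                                     db_records, labels,
                                     config = pipeline_config()) {
  best <- align_stage(query, E_q, index, db_embeddings, db_records,
                      config$knn_k, config)
  escalated <- FALSE
  if (is.null(best) && config$escalate_k > 0L) {
    best <- align_stage(query, E_q, index, db_embeddings, db_records,
                        config$escalate_k, config)
    escalated <- !is.null(best)
  }
  if (is.null(best)) return(no_call(query$id, "softalign"))
  call_row(query$id, "softalign", best$subject_id,
           label_for(labels, best$subject_id), best$aln, best$cosine,
           best$rank, escalated)
}

#' Annotate one query by its best pooled-embedding hit
#'
#' The baseline annotator: the category of the subject with the maximum
#' pooled cosine similarity is transferred, provided the similarity passes
#' `pooled_threshold` (when set). Exact ties go to the lexicographically
#' smaller subject id.
#'
#' @inheritParams annotate_query_softalign
#' @return A one-row data.frame.
#' @export
annotate_query_pooled <- function(query, E_q, index, labels,
                                  config = pipeline_config()) {
  hits <- knn_search(index, mean_pool(E_q), k = 1L,
                     exclude_self = config$exclude_self, self_id = query$id)
  if (nrow(hits) == 0L) return(no_call(query$id, "pooled"))
  if (!is.null(config$pooled_threshold) &&
      hits$cosine_similarity[1L] < config$pooled_threshold)
    return(no_call(query$id, "pooled"))
  call_row(query$id, "pooled", hits$subject_id[1L],
           label_for(labels, hits$subject_id[1L]), NULL,
           hits$cosine_similarity[1L], hits$rank[1L], FALSE)
}

#' Annotate a batch of queries
#'
#' Runs [annotate_query_softalign()] and/or [annotate_query_pooled()] over
#' every query. Per-query failures are captured in the `error` column and
#' never abort the batch. Output is deterministic for fixed inputs.
#'
#' @param queries Named list of query [protein_record()]s.
#' @param query_embeddings Named list of their residue embedding matrices.
#' @param index A [build_index()] over subject pooled embeddings.
#' @param db_embeddings,db_records Named lists over subjects.
#' @param labels Named character vector of subject categories.
#' @param config A [pipeline_config()].
#' @param method `"softalign"`, `"pooled"`, or `"both"`.
#' @return A data.frame with columns `query_id`, `method`, `subject_id`,
#'   `category`, `soft_score`, `pooled_cosine`, `n_mutual`, `n_secondary`,
#'   `n_rescued`, `q_start`, `q_end`, `s_start`, `s_end`, `knn_rank`,
#'   `escalated`, `significant`, `error`.
#' @export
annotate <- function(queries, query_embeddings, index, db_embeddings,
                     db_records, labels, config = pipeline_config(),
                     method = c("softalign", "pooled", "both")) {
  method <- match.arg(method)
  methods <- if (method == "both") c("softalign", "pooled") else method
  rows <- list()
  for (qid in names(queries)) {
    for (mth in methods) {
      row <- tryCatch({
        r <- if (mth == "softalign")
          annotate_query_softalign(queries[[qid]], query_embeddings[[qid]],
                                   index, db_embeddings, db_records, labels,
                                   config)
        else
          annotate_query_pooled(queries[[qid]], query_embeddings[[qid]],
                                index, labels, config)
        r$error <- NA_character_
        r
      }, error = function(e) {
        r <- no_call(qid, mth)
        r$error <- conditionMessage(e)
        r
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate annotation calls against ground truth
#'
#' Scores only the called queries (those with a category), as uncalled
#' queries carry no annotation to judge; their count is reported separately.
#'
#' @param calls Data frame from [annotate()] (one method).
#' @param truth Named character vector: query id -> true category.
#' @return List with `confusion` (rows = truth, columns = predicted),
#'   `per_class` (sensitivity TP/(TP+FN), specificity TN/(TN+FP)),
#'   `weighted_precision`, `weighted_recall` (weighted by true class size
#'   over called queries), `n_called`, `n_correct`, `n_uncalled`.
#' @export
evaluate_calls <- function(calls, truth) {
  called <- calls[!is.na(calls$category), , drop = FALSE]
  if (nrow(called) == 0L)
    return(list(confusion = NULL, per_class = NULL,
                weighted_precision = NA_real_, weighted_recall = NA_real_,
                n_called = 0L, n_correct = 0L, n_uncalled = nrow(calls),
                nothing_annotated = TRUE))
  if (anyNA(truth[called$query_id]))
    stop("truth labels missing for called query/queries", call. = FALSE)
  tr <- unname(truth[called$query_id])
  pr <- called$category
  # predicted-only classes (e.g. a decoy label) enter the confusion matrix
  # with zero support rather than aborting the evaluation
  classes <- sort(unique(c(tr, pr)))
  confusion <- table(truth = factor(tr, classes), predicted = factor(pr, classes))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    TP <- sum(tr == cl & pr == cl); FN <- sum(tr == cl & pr != cl)
    FP <- sum(tr != cl & pr == cl); TN <- sum(tr != cl & pr != cl)
    data.frame(class = cl,
               sensitivity = if (TP + FN) TP / (TP + FN) else NA_real_,
               specificity = if (TN + FP) TN / (TN + FP) else NA_real_,
               precision = if (TP + FP) TP / (TP + FP) else NA_real_,
               support = TP + FN)
  }))
  w <- per_class$support / sum(per_class$support)
  list(confusion = confusion, per_class = per_class,
       weighted_precision = sum(w * ifelse(is.na(per_class$precision), 0,
                                           per_class$precision)),
       weighted_recall = sum(w * ifelse(is.na(per_class$sensitivity), 0,
                                        per_class$sensitivity)),
       n_called = nrow(called), n_correct = sum(tr == pr),
       n_uncalled = nrow(calls) - nrow(called))
}

#' Render a soft alignment as BLAST-like text
#'
#' Header with ids, score, chained match counts by kind and 1-based coverage
#' spans, followed by wrapped query/midline/subject lines. Midline glyphs:
#' `|` mutual, `:` secondary, `+` rescued, `.` unaligned column inside the
#' chain span ( `-` marks an insertion in the other sequence). Output is
#' deterministic; glyph counts in the body always equal the header counts.
#'
#' @param result A `soft_alignment` from [soft_align()].
#' @param q,s The aligned [protein_record()]s.
#' @param width Residue columns per line (default 60).
#' @return A single string (embedded newlines).
#' @export
render_alignment <- function(result, q, s, width = 60L) {
  stopifnot(inherits(result, "soft_alignment"))
  header <- sprintf(
    "Query: %s  Subject: %s\nScore: %.3f (%s)  Matches: %d mutual, %d secondary, %d rescued",
    q$id, s$id, result$score,
    if (result$significant) "significant" else "not significant",
    result$counts[["mutual"]], result$counts[["secondary"]],
    result$counts[["rescued"]])
  chain <- result$chain
  if (nrow(chain) == 0L)
    return(paste0(header, "\n(no alignment)\n"))
  header <- paste0(header, sprintf("\nQuery span %d-%d  Subject span %d-%d",
                                   result$query_range[1L], result$query_range[2L],
                                   result$subject_range[1L], result$subject_range[2L]))
  qc <- strsplit(q$residues, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s$residues, "", fixed = TRUE)[[1L]]
  glyph <- c(mutual = "|", secondary = ":", rescued = "+")
  qcol <- character(0L); mcol <- character(0L); scol <- character(0L)
  prev_i <- chain$i[1L] - 1L
  prev_j <- chain$j[1L] - 1L
  for (r in seq_len(nrow(chain))) {
    gi <- (prev_i + 1L):(chain$i[r] - 1L)
    gj <- (prev_j + 1L):(chain$j[r] - 1L)
    gi <- gi[gi <= chain$i[r] - 1L & gi > prev_i]
    gj <- gj[gj <= chain$j[r] - 1L & gj > prev_j]
    both <- min(length(gi), length(gj))
    if (both > 0L) {
      qcol <- c(qcol, qc[gi[seq_len(both)] + 1L])
      scol <- c(scol, sc[gj[seq_len(both)] + 1L])
      mcol <- c(mcol, rep(".", both))
    }
    if (length(gi) > both) {
      extra <- gi[(both + 1L):length(gi)]
      qcol <- c(qcol, qc[extra + 1L])
      scol <- c(scol, rep("-", length(extra)))
      mcol <- c(mcol, rep(".", length(extra)))
    }
    if (length(gj) > both) {
      extra <- gj[(both + 1L):length(gj)]
      qcol <- c(qcol, rep("-", length(extra)))
      scol <- c(scol, sc[extra + 1L])
      mcol <- c(mcol, rep(".", length(extra)))
    }
    qcol <- c(qcol, qc[chain$i[r] + 1L])
    scol <- c(scol, sc[chain$j[r] + 1L])
    mcol <- c(mcol, glyph[[chain$kind[r]]])
    prev_i <- chain$i[r]; prev_j <- chain$j[r]
  }
  # wrap at `width`, tracking 1-based residue coordinates ('-' consumes none)
  lines <- character(0L)
  qpos <- chain$i[1L] + 1L
  spos <- chain$j[1L] + 1L
  for (start in seq(1L, length(qcol), by = width)) {
    idx <- start:min(start + width - 1L, length(qcol))
    nq <- sum(qcol[idx] != "-")
    ns <- sum(scol[idx] != "-")
    lines <- c(lines,
               sprintf("Query   %5d %s %d", qpos, paste(qcol[idx], collapse = ""),
                       qpos + nq - 1L),
               sprintf("              %s", paste(mcol[idx], collapse = "")),
               sprintf("Subject %5d %s %d", spos, paste(scol[idx], collapse = ""),
                       spos + ns - 1L),
               "")
    qpos <- qpos + nq
    spos <- spos + ns
  }
  paste0(header, "\n\n", paste(lines, collapse = "\n"))
}
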