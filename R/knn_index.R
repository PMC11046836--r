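#' Build an exact cosine nearest-neighbour index over pooled embeddings
#'
#' Rows are L2-normalised on insertion so that the inner product of stored
#' rows with a normalised query equals cosine similarity, and retrieval is an
#' exact maximum-inner-product search (no approximate structures).
#'
#' @param pooled Named list of pooled vectors (names = subject ids), or a
#'   numeric matrix with rownames. Vectors of [mean_pool()] carry their
#'   `sequence_id` attribute, which is used when names are missing.
#' @return An object of class `knn_index` with fields `ids`, `matrix`
#'   (N x d, unit rows) and `dim`.
#' @export
build_index <- function(pooled) {
  if (is.matrix(pooled)) {
    ids <- rownames(pooled)
    mat <- unname(pooled)
  } else {
    ids <- names(pooled)
    if (is.null(ids))
      ids <- vapply(pooled, function(v) attr(v, "sequence_id") %||% NA_character_,
                    character(1L))
    if (length(pooled)) {
      d <- unique(lengths(pooled))
      if (length(d) > 1L) stop("pooled vectors differ in dimension", call. = FALSE)
      mat <- do.call(rbind, lapply(pooled, as.numeric))
    } else {
      mat <- matrix(numeric(0L), 0L, 0L)
    }
  }
  if (nrow(mat) > 0L) {
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      stop("every pooled vector needs a subject id", call. = FALSE)
    if (anyDuplicated(ids))
      stop("duplicate subject id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    nrm <- sqrt(rowSums(mat * mat))
    if (any(nrm < 1e-12)) stop("zero-norm pooled vector", call. = FALSE)
    mat <- mat / nrm
  } else {
    ids <- character(0L)
  }
  structure(list(ids = ids, matrix = mat, dim = ncol(mat)), class = "knn_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.knn_index <- function(x, ...) {
  cat("Exact cosine KNN index:", length(x$ids), "subjects, dim", x$dim, "\n")
  invisible(x)
}

#' Retrieve the k nearest neighbours of a query by cosine similarity
#'
#' The query is L2-normalised and compared against every stored row; the k
#' largest cosine similarities are returned. Exact ties are broken by
#' lexicographic subject id for reproducibility.
#'
#' @param index A [build_index()] object.
#' @param query Numeric query vector (a pooled embedding).
#' @param k Number of neighbours (>= 1).
#' @param exclude_self If set, a stored row whose id equals the query's
#'   `sequence_id` attribute (or `self_id`) is skipped.
#' @param self_id Optional explicit id to exclude.
#' @return A data.frame with columns `subject_id`, `cosine_similarity`,
#'   `rank` (1-based, similarity descending). At most `min(k, N_eligible)`
#'   rows; an empty index yields zero rows.
#' @export
knn_search <- function(index, query, k = 5L, exclude_self = FALSE,
                       self_id = NULL) {
  stopifnot(inherits(index, "knn_index"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(index$ids) == 0L)
    return(data.frame(subject_id = character(0L),
                      cosine_similarity = numeric(0L), rank = integer(0L)))
  query <- as.numeric(query)
  if (length(query) != index$dim)
    stop("query dimension ", length(query), " != index dimension ", index$dim,
         call. = FALSE)
  qn <- sqrt(sum(query * query))
  if (qn < 1e-12) stop("zero-norm query vector", call. = FALSE)
  sims <- as.numeric(index$matrix %*% (query / qn))
  keep <- rep(TRUE, length(sims))
  if (exclude_self) {
    sid <- self_id %||% attr(query, "sequence_id")
    if (!is.null(sid)) keep <- index$ids != sid
  }
  ids <- index$ids[keep]
  sims <- sims[keep]
  ord <- order(-sims, ids)
  take <- head(ord, min(k, length(ord)))
  data.frame(subject_id = ids[take], cosine_similarity = sims[take],
             rank = seq_along(take))
}

#' Save / load a KNN index
#'
#' Persistence is bit-stable: `load_index(save_index(x, p))` reproduces ids
#' and the normalised matrix exactly.
#'
#' @param index A [build_index()] object.
#' @param path File path.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   index.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "knn_index"))
  saveRDS(list(format = "softalign_knn_index", version = 1L,
               ids = index$ids, matrix = index$matrix, dim = index$dim),
          path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read index archive: ", conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "softalign_knn_index"))
    stop("not a softalign index archive: ", path, call. = FALSE)
  if (!identical(obj$version, 1L))
    stop("unsupported index archive version", call. = FALSE)
  if (length(obj$ids) != nrow(obj$matrix) ||
      (length(obj$ids) > 0L && ncol(obj$matrix) != obj$dim))
    stop("corrupt index archive: ids/matrix mismatch", call. = FALSE)
  structure(list(ids = obj$ids, matrix = obj$matrix, dim = obj$dim),
            class = "knn_index")
}
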