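#' @importFrom stats quantile rnorm runif setNames
#' @importFrom utils head write.table
NULL

# 20 standard residues plus the common ambiguity/rare codes X, B, Z, U.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXTENDED <- c(AA_LETTERS, "X", "B", "Z", "U")

#' Create a protein record
#'
#' A protein record holds an identifier, an optional free-text description and
#' the residue string, uppercased and restricted to the 20 standard amino-acid
#' letters plus X/B/Z/U.
#'
#' @param id Non-empty identifier string.
#' @param residues Residue string (uppercased on construction).
#' @param description Free-text description, default `""`.
#' @param strict If `TRUE`, residues outside the allowed alphabet are an
#'   error; if `FALSE` they are mapped to `X`.
#' @return An object of class `protein_record` with fields `id`,
#'   `description` and `residues`.
#' @export
protein_record <- function(id, residues, description = "", strict = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string", call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L)
    stop("'residues' must be a single string", call. = FALSE)
  residues <- toupper(residues)
  if (grepl("\\s", residues))
    stop("residues must not contain whitespace (record '", id, "')", call. = FALSE)
  if (nchar(residues) < 1L)
    stop("empty sequence for record '", id, "'", call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% AA_EXTENDED)
  if (any(bad)) {
    if (strict)
      stop("illegal residue(s) ", paste(unique(chars[bad]), collapse = ", "),
           " in record '", id, "'", call. = FALSE)
    chars[bad] <- "X"
    residues <- paste(chars, collapse = "")
  }
  structure(list(id = id, description = description, residues = residues),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(">", x$id, if (nzchar(x$description)) x$description else NULL, "\n")
  cat(substr(x$residues, 1L, 60L),
      if (nchar(x$residues) > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Records are returned in file order with residues uppercased. Duplicate ids
#' are an error. Under `strict = TRUE` residues outside the allowed alphabet
#' (20 standard letters plus X/B/Z/U) are an error; otherwise they are mapped
#' to `X`.
#'
#' @param path Path to a FASTA file.
#' @param strict Alphabet strictness flag (default `TRUE`).
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers))))
    stop("malformed FASTA header in ", path, call. = FALSE)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- as.character(set)
  mapply(function(i, d, s) protein_record(i, s, d, strict = strict),
         ids, desc, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 columns. Round-trips with [read_fasta()]:
#' ids, descriptions and residues are reproduced exactly.
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  ids <- vapply(records, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate ids in records", call. = FALSE)
  seqs <- vapply(records, `[[`, character(1L), "residues")
  desc <- vapply(records, `[[`, character(1L), "description")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a subject-id to category label table
#'
#' Parses a two-column tab-separated file mapping subject ids to functional
#' category strings. Rows with a number of columns other than two are an
#' error; surrounding whitespace is stripped. An empty file yields an empty
#' table.
#'
#' @param path Path to a 2-column TSV file.
#' @param header If `TRUE`, the first line is skipped.
#' @return A named character vector (names = subject ids). Look up with
#'   [label_for()] to get `NA` on a miss rather than an empty string.
#' @export
read_labels <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(character(0L), character(0L)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("label table row(s) with ", paste(unique(nf[nf != 2L]), collapse = "/"),
         " columns (expected 2), first at line ", which(nf != 2L)[1L], call. = FALSE)
  ids <- trimws(vapply(parts, `[[`, character(1L), 1L))
  cats <- trimws(vapply(parts, `[[`, character(1L), 2L))
  if (any(!nzchar(ids))) stop("empty subject id in label table", call. = FALSE)
  setNames(cats, ids)
}

#' Look up a label, returning NA on a miss
#'
#' @param labels Named character vector from [read_labels()].
#' @param id Subject id.
#' @return The category string, or `NA_character_` when `id` is absent.
#' @export
label_for <- function(labels, id) {
  if (id %in% names(labels)) unname(labels[[id]]) else NA_character_
}

#' Write a label table as 2-column TSV
#'
#' @param labels Named character vector (names = subject ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(id = names(labels), category = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
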