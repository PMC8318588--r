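#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a tibble with
#' one row per entry. Sequences are uppercased; the FASTA header is split into
#' an identifier (first whitespace-delimited token) and a free-text
#' description. Duplicate identifiers are rejected because downstream proteome
#' scans and coverage summaries key on `protein_id`.
#'
#' @param path Path to a (possibly multi-entry) FASTA file.
#' @param allow_nonstandard Tolerate the ambiguity codes B/Z/X/U/O/J in
#'   sequences (default `TRUE`). Invalid characters are always rejected with
#'   their position.
#' @return A tibble with columns `protein_id`, `description`, `sequence`,
#'   `length`.
#' @export
read_proteins <- function(path, allow_nonstandard = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'.", path))
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("Duplicate FASTA identifier: '%s'.", dup))
  }
  if (any(!nzchar(ids))) {
    abort("FASTA entry with empty identifier.")
  }
  seqs <- unname(toupper(as.character(set)))
  check_residues(seqs, allow_nonstandard = allow_nonstandard, what = "FASTA entry")
  tibble(
    protein_id = unname(ids),
    description = unname(desc),
    sequence = unname(seqs),
    length = nchar(seqs)
  )
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with `protein_id`, `sequence` and optionally
#'   `description` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  set <- Biostrings::AAStringSet(proteins$sequence)
  desc <- proteins$description %||% rep("", nrow(proteins))
  if (is.null(proteins$description)) desc <- rep("", nrow(proteins))
  names(set) <- ifelse(
    nzchar(desc),
    paste(proteins$protein_id, desc),
    proteins$protein_id
  )
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read an aligned FASTA file as a gapped alignment
#'
#' All entries must have equal aligned length; `-` and `.` are accepted as gap
#' characters (`.` is normalised to `-`).
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id`, `description`, `aligned` (gapped,
#'   uppercase) and `alignment_length`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Alignment file not found: '%s'.", path))
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(gsub(".", "-", toupper(as.character(set)), fixed = TRUE))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    abort(sprintf(
      "Aligned sequences have unequal lengths (entry '%s' has %d columns, expected %d).",
      ids[which(lens != lens[1])[1]], lens[lens != lens[1]][1], lens[1]
    ))
  }
  check_residues(gsub("-", "", seqs), what = "alignment entry")
  tibble(
    id = unname(ids),
    description = unname(desc),
    aligned = unname(seqs),
    alignment_length = lens
  )
}

#' Write a gapped alignment tibble to aligned FASTA
#'
#' @param alignment Tibble with `id` and `aligned` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(all(c("id", "aligned") %in% names(alignment)))
  set <- Biostrings::AAStringSet(alignment$aligned)
  names(set) <- alignment$id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
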