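#' Maximum number of exchangeable backbone amides of a peptide
#'
#' HDX-MS convention for the theoretical uptake ceiling of a peptide: every
#' residue contributes one backbone amide except the N-terminal residue (its
#' deuterium is lost during quench/digestion) and prolines after position 1
#' (no amide hydrogen). The alternative convention that also discounts the
#' second residue's fast-exchanging amide is available via
#' `exclude_first = 2`.
#'
#' @param sequence Character vector of peptide sequences (standard one-letter
#'   codes; ambiguity codes B/Z/X/U/O/J are accepted and counted as ordinary
#'   residues).
#' @param exclude_first Number of N-terminal residues excluded from the count
#'   (1, the default, or 2).
#' @return Integer vector of amide counts, clamped at zero.
#' @examples
#' max_exchangeable_amides("PETGEIL") # 6
#' max_exchangeable_amides("APPLE")   # 2
#' @export
max_exchangeable_amides <- function(sequence, exclude_first = 1) {
  stopifnot(exclude_first %in% c(1L, 2L))
  if (any(!nzchar(sequence))) {
    abort("Empty peptide sequence.")
  }
  check_residues(sequence, what = "peptide")
  n <- nchar(sequence)
  tail_pro <- vapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    sum(chars[-seq_len(min(exclude_first, length(chars)))] == "P")
  }, integer(1), USE.NAMES = FALSE)
  pmax(0L, as.integer(n - exclude_first - tail_pro))
}

# Internal: logical vector marking, for one protein, which residues carry an
# exchangeable amide within a peptide starting at `start` (the peptide's first
# `exclude_first` residues and prolines do not).
peptide_amide_residues <- function(residues, start, end, exclude_first = 1) {
  idx <- seq.int(start + exclude_first, length.out = max(0, end - start + 1 - exclude_first))
  idx[residues[idx] != "P"]
}

#' Validate a peptide table against its parent proteins
#'
#' Checks 1-based inclusive coordinates, that each peptide sequence equals the
#' protein slice, and (re)computes `max_uptake`.
#'
#' @param peptides Tibble with `protein_id`, `start`, `end` and optionally
#'   `sequence`.
#' @param proteins Tibble as returned by [read_proteins()].
#' @param exclude_first Passed to [max_exchangeable_amides()].
#' @return The peptide tibble with `sequence` and `max_uptake` filled in.
#' @export
validate_peptides <- function(peptides, proteins, exclude_first = 1) {
  stopifnot(all(c("protein_id", "start", "end") %in% names(peptides)))
  missing <- setdiff(unique(peptides$protein_id), proteins$protein_id)
  if (length(missing)) {
    abort(sprintf("Peptides reference unknown protein '%s'.", missing[1]))
  }
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  out <- peptides
  plen <- nchar(seqs[out$protein_id])
  bad <- which(out$start < 1 | out$end < out$start | out$end > plen)
  if (length(bad)) {
    abort(sprintf(
      "Peptide %d (%s %d-%d) has coordinates outside 1..%d.",
      bad[1], out$protein_id[bad[1]], out$start[bad[1]], out$end[bad[1]],
      plen[bad[1]]
    ))
  }
  slice <- substr(seqs[out$protein_id], out$start, out$end)
  if ("sequence" %in% names(out)) {
    mism <- which(toupper(out$sequence) != unname(slice))
    if (length(mism)) {
      abort(sprintf(
        "Peptide %d: sequence '%s' does not match protein %s positions %d-%d ('%s').",
        mism[1], out$sequence[mism[1]], out$protein_id[mism[1]],
        out$start[mism[1]], out$end[mism[1]], slice[mism[1]]
      ))
    }
  }
  out$sequence <- unname(slice)
  out$max_uptake <- max_exchangeable_amides(out$sequence, exclude_first = exclude_first)
  as_tibble(out)
}

#' Sequence coverage and redundancy of a peptide map
#'
#' Coverage is the percentage of protein residues covered by at least one
#' peptide; redundancy is the mean peptide depth over covered residues.
#' Duplicate spans (same start and end) count once towards depth by default,
#' mirroring peptide maps where charge states are collapsed.
#'
#' @param peptides Tibble with `protein_id`, `start`, `end`.
#' @param proteins Tibble with `protein_id` and `length` (or `sequence`).
#' @param distinct_spans Count each distinct span once (default `TRUE`).
#' @return Tibble with one row per protein: `protein_id`, `coverage_percent`,
#'   `redundancy`, `residues_covered`, `n_peptides`.
#' @examples
#' prot <- tibble::tibble(protein_id = "P", length = 100)
#' pep <- tibble::tibble(protein_id = "P", start = c(1, 41), end = c(50, 100))
#' coverage_redundancy(pep, prot) # coverage 100%, redundancy 1.10
#' @export
coverage_redundancy <- function(peptides, proteins, distinct_spans = TRUE) {
  if (is.null(proteins$length)) {
    proteins$length <- nchar(proteins$sequence)
  }
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    pid <- proteins$protein_id[i]
    len <- proteins$length[i]
    pep <- dplyr::filter(peptides, .data$protein_id == pid)
    if (distinct_spans) pep <- dplyr::distinct(pep, .data$start, .data$end)
    depth <- integer(len)
    for (j in seq_len(nrow(pep))) {
      idx <- pep$start[j]:pep$end[j]
      depth[idx] <- depth[idx] + 1L
    }
    covered <- sum(depth > 0)
    tibble(
      protein_id = pid,
      coverage_percent = 100 * covered / len,
      redundancy = if (covered > 0) sum(depth) / covered else 0,
      residues_covered = covered,
      n_peptides = nrow(pep)
    )
  })
}

#' Per-residue protected-peptide depth
#'
#' For each residue of each protein, the number of (protected) peptides whose
#' span covers it. Useful for mapping protection onto structures or plotting
#' residue-level protection tracks.
#'
#' @param peptides Tibble with `protein_id`, `start`, `end` (typically the
#'   protected peptides from [call_protected_peptides()]).
#' @param proteins Tibble with `protein_id` and `length` (or `sequence`).
#' @return Tibble with `protein_id`, `position`, `depth`.
#' @export
residue_protection_map <- function(peptides, proteins) {
  if (is.null(proteins$length)) {
    proteins$length <- nchar(proteins$sequence)
  }
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    pid <- proteins$protein_id[i]
    len <- proteins$length[i]
    pep <- dplyr::filter(peptides, .data$protein_id == pid)
    depth <- integer(len)
    for (j in seq_len(nrow(pep))) {
      idx <- pep$start[j]:pep$end[j]
      depth[idx] <- depth[idx] + 1L
    }
    tibble(protein_id = pid, position = seq_len(len), depth = depth)
  })
}

#' Jaccard index of two 1-based inclusive residue intervals
#'
#' @param start1,end1,start2,end2 Interval bounds (vectors recycle).
#' @return Numeric Jaccard index in `[0, 1]`.
#' @export
interval_jaccard <- function(start1, end1, start2, end2) {
  inter <- pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
  union <- (end1 - start1 + 1) + (end2 - start2 + 1) - inter
  ifelse(union > 0, inter / union, 0)
}
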