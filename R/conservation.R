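#' Curate an ortholog alignment before conservation analysis
#'
#' Removes entries that are substantially shorter than the reference sequence
#' or too gappy within the analysis window, the usual manual curation applied
#' before building a conservation logo. The reference entry is always
#' retained.
#'
#' @param alignment Tibble from [read_alignment()].
#' @param reference_id Identifier of the reference entry (must be present).
#' @param min_length_fraction Minimum ungapped length relative to the
#'   reference's ungapped length (default 0.7).
#' @param max_gap_fraction Maximum fraction of gap characters inside `window`
#'   (default 0.2).
#' @param window Optional integer vector of alignment columns over which the
#'   gap fraction is evaluated (default: all columns).
#' @return List with `retained` (alignment tibble) and `removal_log`
#'   (tibble `id`, `reason`, `value`, `threshold`).
#' @export
curate_orthologs <- function(alignment, reference_id,
                             min_length_fraction = 0.7,
                             max_gap_fraction = 0.2,
                             window = NULL) {
  stopifnot(all(c("id", "aligned") %in% names(alignment)))
  if (!reference_id %in% alignment$id) {
    abort(sprintf("Reference '%s' is not present in the alignment.", reference_id))
  }
  aln_len <- nchar(alignment$aligned[1])
  window <- window %||% seq_len(aln_len)
  stopifnot(all(window >= 1), all(window <= aln_len))

  ungapped <- nchar(gsub("-", "", alignment$aligned))
  ref_len <- ungapped[alignment$id == reference_id][1]
  win_str <- vapply(alignment$aligned, function(s) {
    paste(strsplit(s, "")[[1]][window], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  gap_frac <- stringr::str_count(win_str, stringr::fixed("-")) / length(window)

  too_short <- ungapped < min_length_fraction * ref_len
  too_gappy <- gap_frac > max_gap_fraction
  is_ref <- alignment$id == reference_id
  removed <- !is_ref & (too_short | too_gappy)

  removal_log <- tibble(
    id = alignment$id[removed],
    reason = ifelse(too_short[removed], "length", "gaps"),
    value = ifelse(too_short[removed],
      ungapped[removed] / ref_len, gap_frac[removed]
    ),
    threshold = ifelse(too_short[removed], min_length_fraction, max_gap_fraction)
  )
  list(
    retained = alignment[!removed, , drop = FALSE],
    removal_log = removal_log
  )
}

#' Per-column frequency profile and information content
#'
#' Computes, for each requested alignment column, residue counts (gaps and
#' non-standard codes excluded), frequencies, and the information content in
#' bits: `IC = log2(20) - H(frequencies) - e(n)`, where the small-sample
#' correction `e(n) = 19 / (2 ln(2) n)` is subtracted by default, matching
#' common sequence-logo practice. IC is clamped at zero; all-gap columns get
#' `n = 0` and `ic = NA`.
#'
#' @param alignment Tibble from [read_alignment()] (possibly curated).
#' @param columns Integer vector of alignment columns (default: all).
#' @param small_sample_correction Apply `e(n)` (default `TRUE`).
#' @return Long tibble with one row per column x observed residue: `column`,
#'   `residue`, `count`, `frequency`, plus per-column `n` and `ic` (repeated
#'   within a column). Columns with `n = 0` get a single row with
#'   `residue = NA`.
#' @export
column_profile <- function(alignment, columns = NULL,
                           small_sample_correction = TRUE) {
  stopifnot(nrow(alignment) >= 1)
  aln_len <- nchar(alignment$aligned[1])
  columns <- columns %||% seq_len(aln_len)
  stopifnot(all(columns >= 1), all(columns <= aln_len))
  mat <- do.call(rbind, strsplit(alignment$aligned, ""))
  purrr::map_dfr(columns, function(j) {
    res <- mat[, j]
    res <- res[res %in% AA_STANDARD]
    n <- length(res)
    if (n == 0) {
      return(tibble(
        column = j, residue = NA_character_, count = 0L,
        frequency = NA_real_, n = 0L, ic = NA_real_
      ))
    }
    cnt <- table(factor(res, levels = AA_STANDARD))
    cnt <- cnt[cnt > 0]
    freq <- as.numeric(cnt) / n
    h <- -sum(freq * log2(freq))
    ic <- log2(20) - h
    if (small_sample_correction) ic <- ic - 19 / (2 * log(2) * n)
    ic <- max(0, ic)
    tibble(
      column = j,
      residue = names(cnt),
      count = as.integer(cnt),
      frequency = freq,
      n = n,
      ic = ic
    )
  })
}

#' Consensus string from a column profile
#'
#' Per column, the modal residue: uppercase when its frequency reaches the
#' plurality threshold, lowercase otherwise; ties are broken alphabetically;
#' empty (all-gap) columns yield `-`.
#'
#' @param profile Output of [column_profile()].
#' @param plurality_threshold Frequency needed for an uppercase call
#'   (default 0.5).
#' @return A single consensus string with one symbol per profiled column.
#' @export
consensus_sequence <- function(profile, plurality_threshold = 0.5) {
  cols <- split(profile, profile$column)
  symbols <- purrr::map_chr(cols, function(p) {
    if (all(is.na(p$residue)) || p$n[1] == 0) return("-")
    p <- dplyr::arrange(p, dplyr::desc(.data$frequency), .data$residue)
    if (p$frequency[1] >= plurality_threshold) p$residue[1] else tolower(p$residue[1])
  })
  paste(symbols[order(as.integer(names(symbols)))], collapse = "")
}

#' Export a logo matrix consumable by standard logo renderers
#'
#' @param profile Output of [column_profile()].
#' @param path Optional path; when given, the matrix is written as JSON with
#'   fields `alphabet`, `columns` (per-column frequency vectors), `n` and
#'   `ic`.
#' @return The logo list, invisibly when written to `path`.
#' @export
logo_matrix <- function(profile, path = NULL) {
  cols <- split(profile, profile$column)
  cols <- cols[order(as.integer(names(cols)))]
  out <- list(
    alphabet = AA_STANDARD,
    columns = purrr::map(cols, function(p) {
      f <- setNames(rep(0, 20), AA_STANDARD)
      if (!all(is.na(p$residue))) f[p$residue] <- p$frequency
      as.list(f)
    }),
    n = purrr::map_int(cols, function(p) p$n[1]),
    ic = purrr::map_dbl(cols, function(p) p$ic[1])
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
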