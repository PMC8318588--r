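#' Parse a PROSITE-style degenerate motif pattern
#'
#' Supports the pattern subset needed for short linear motif queries over the
#' 20 standard residues: elements separated by `-`, where an element is a
#' single residue, a bracketed ambiguity set such as `[VIL]`, or the wildcard
#' `X`/`x` (any residue). Exclusion sets `{...}` and repetition `x(n)` are
#' rejected with an explicit message rather than silently ignored.
#'
#' @param text Pattern string, e.g. `"[VIL]-D-X-X-T-G-E-[VIL]-[VILT]"`.
#' @return A `degenerate_motif` object: a list with `positions` (one
#'   character vector of allowed residues per position) and `source_text`.
#' @examples
#' m <- parse_motif("[VIL]-D-X-X-T-G-E-[VIL]-[VILT]")
#' motif_length(m) # 9
#' @export
parse_motif <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) {
    abort("Empty motif pattern.")
  }
  if (grepl("-$", text)) {
    abort(sprintf("Empty motif element at column %d.", nchar(text)))
  }
  elements <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(elements) == 0 || any(!nzchar(elements))) {
    # column of the offending separator
    cum <- cumsum(nchar(elements) + 1)
    col <- if (length(elements) == 0) 1 else cum[which(!nzchar(elements))[1] - 1] %||% 1
    abort(sprintf("Empty motif element at column %d.", col))
  }
  offsets <- cumsum(c(1, head(nchar(elements), -1) + 1))
  positions <- purrr::map2(elements, offsets, parse_motif_element)
  new_degenerate_motif(positions, source_text = text)
}

parse_motif_element <- function(el, col) {
  if (grepl("^\\{", el)) {
    abort(sprintf(
      "Exclusion sets '{...}' are not supported (column %d).", col
    ))
  }
  if (grepl("\\(", el)) {
    abort(sprintf(
      "Repetition counts 'x(n)' are not supported (column %d).", col
    ))
  }
  if (el %in% c("X", "x")) {
    return(AA_STANDARD)
  }
  if (grepl("^\\[", el)) {
    if (!grepl("\\]$", el)) {
      abort(sprintf("Unclosed bracket at column %d.", col))
    }
    inner <- toupper(substr(el, 2, nchar(el) - 1))
    if (!nzchar(inner)) {
      abort(sprintf("Empty bracket set at column %d.", col))
    }
    chars <- unique(strsplit(inner, "")[[1]])
    bad <- setdiff(chars, AA_STANDARD)
    if (length(bad)) {
      abort(sprintf(
        "Unknown residue '%s' in bracket set at column %d.", bad[1], col
      ))
    }
    return(sort(chars))
  }
  if (nchar(el) == 1 && toupper(el) %in% AA_STANDARD) {
    return(toupper(el))
  }
  abort(sprintf("Unknown motif element '%s' at column %d.", el, col))
}

new_degenerate_motif <- function(positions, source_text = NULL) {
  stopifnot(length(positions) >= 1)
  positions <- purrr::map(positions, function(p) sort(unique(toupper(p))))
  ok <- purrr::map_lgl(positions, function(p) {
    length(p) >= 1 && all(p %in% AA_STANDARD)
  })
  if (!all(ok)) {
    abort(sprintf("Motif position %d has an empty or invalid residue set.", which(!ok)[1]))
  }
  structure(
    list(positions = positions, source_text = source_text %||% NA_character_),
    class = "degenerate_motif"
  )
}

#' Number of positions of a degenerate motif
#' @param motif A `degenerate_motif`.
#' @return Integer length.
#' @export
motif_length <- function(motif) {
  stopifnot(inherits(motif, "degenerate_motif"))
  length(motif$positions)
}

#' @export
format.degenerate_motif <- function(x, ...) {
  paste(purrr::map_chr(x$positions, function(p) {
    if (length(p) == 20) "X"
    else if (length(p) == 1) p
    else paste0("[", paste(p, collapse = ""), "]")
  }), collapse = "-")
}

#' @export
as.character.degenerate_motif <- function(x, ...) format(x)

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("<degenerate_motif> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @method tidy degenerate_motif
#' @export
tidy.degenerate_motif <- function(x, ...) {
  tibble(
    position = seq_along(x$positions),
    allowed = purrr::map_chr(x$positions, paste, collapse = ""),
    n_allowed = lengths(x$positions)
  )
}

# 256-slot logical lookup tables (by character code) for each motif position.
motif_lookup <- function(motif) {
  purrr::map(motif$positions, function(p) {
    tab <- logical(256)
    tab[utf8ToInt(paste(p, collapse = ""))] <- TRUE
    tab
  })
}

#' Scan a single protein sequence for motif matches
#'
#' Tests every window of motif length; overlapping matches are all reported.
#' Windows containing any non-standard residue (B/Z/X/U/O/J) never match --
#' ambiguity codes are treated conservatively rather than optimistically.
#'
#' @param motif A `degenerate_motif`.
#' @param sequence Protein sequence string.
#' @param protein_id Identifier attached to the matches (default `NA`).
#' @return Tibble of matches in ascending `start` order: `protein_id`,
#'   `start`, `end`, `matched`.
#' @export
scan_sequence <- function(motif, sequence, protein_id = NA_character_) {
  stopifnot(inherits(motif, "degenerate_motif"), is.character(sequence), length(sequence) == 1)
  check_residues(sequence, what = "sequence")
  starts <- scan_codes(motif_lookup(motif), utf8ToInt(sequence))
  m <- motif_length(motif)
  if (length(starts) == 0) {
    return(tibble(
      protein_id = character(), start = integer(), end = integer(),
      matched = character()
    ))
  }
  tibble(
    protein_id = rep(protein_id, length(starts)),
    start = starts,
    end = starts + m - 1L,
    matched = substring(sequence, starts, starts + m - 1L)
  )
}

# Core window test on integer character codes; returns match start positions.
scan_codes <- function(lookup, codes) {
  m <- length(lookup)
  W <- length(codes) - m + 1L
  if (W < 1L) return(integer())
  ok <- lookup[[1]][codes[seq_len(W)]]
  for (j in seq_len(m - 1L)) {
    ok <- ok & lookup[[j + 1L]][codes[seq.int(1L + j, W + j)]]
  }
  which(ok)
}

#' Scan a proteome for motif matches
#'
#' Applies [scan_sequence()] to every entry of a protein collection and
#' summarises the match census: the distinct-protein (carrier) count is the
#' headline statistic for specificity, the total match count includes
#' multiple and overlapping matches per protein.
#'
#' @param motif A `degenerate_motif` (or pattern string, parsed on the fly).
#' @param proteins Tibble from [read_proteins()] (or a FASTA path).
#' @return A `motif_scan` object with elements `matches` (tibble ordered by
#'   protein id then start), `pattern`, `n_proteins`, `distinct_proteins`,
#'   `total_matches`. Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
scan_proteome <- function(motif, proteins) {
  if (is.character(motif)) motif <- parse_motif(motif)
  if (is.character(proteins)) proteins <- read_proteins(proteins)
  if (anyDuplicated(proteins$protein_id)) {
    abort(sprintf(
      "Duplicate protein id '%s' in collection.",
      proteins$protein_id[duplicated(proteins$protein_id)][1]
    ))
  }
  lookup <- motif_lookup(motif)
  m <- motif_length(motif)
  ord <- order(proteins$protein_id)
  matches <- purrr::map_dfr(ord, function(i) {
    starts <- scan_codes(lookup, utf8ToInt(proteins$sequence[i]))
    if (!length(starts)) return(NULL)
    tibble(
      protein_id = proteins$protein_id[i],
      description = proteins$description[i] %||% "",
      start = starts,
      end = starts + m - 1L,
      matched = substring(proteins$sequence[i], starts, starts + m - 1L)
    )
  })
  if (nrow(matches) == 0) {
    matches <- tibble(
      protein_id = character(), description = character(),
      start = integer(), end = integer(), matched = character()
    )
  }
  structure(
    list(
      matches = matches,
      pattern = format(motif),
      motif = motif,
      n_proteins = nrow(proteins),
      distinct_proteins = dplyr::n_distinct(matches$protein_id),
      total_matches = nrow(matches)
    ),
    class = "motif_scan"
  )
}

#' @export
print.motif_scan <- function(x, ...) {
  cat(sprintf(
    "<motif_scan> pattern %s: %d match(es) in %d of %d protein(s)\n",
    x$pattern, x$total_matches, x$distinct_proteins, x$n_proteins
  ))
  print(x$matches, n = 10)
  invisible(x)
}

#' @method tidy motif_scan
#' @export
tidy.motif_scan <- function(x, ...) x$matches

#' @method glance motif_scan
#' @export
glance.motif_scan <- function(x, ...) {
  tibble(
    pattern = x$pattern,
    n_proteins = x$n_proteins,
    distinct_proteins = x$distinct_proteins,
    total_matches = x$total_matches
  )
}

#' Amino-acid background composition of a protein collection
#'
#' Residue frequencies over the 20 standard amino acids; non-standard codes
#' (B/Z/X/U/O/J) are excluded from both numerator and denominator but tallied
#' separately. Window counts for any motif length are derived from the
#' per-protein lengths (no concatenation across proteins, no wrap-around).
#'
#' @param proteins Tibble from [read_proteins()] (or a FASTA path).
#' @return An `aa_composition` object: list with `frequencies` (named numeric
#'   over the 20 standard residues), `total_residues`, `nonstandard_residues`
#'   and `protein_lengths`.
#' @export
background_composition <- function(proteins) {
  if (is.character(proteins)) proteins <- read_proteins(proteins)
  stopifnot(nrow(proteins) >= 1)
  codes <- unlist(lapply(proteins$sequence, utf8ToInt), use.names = FALSE)
  counts <- tabulate(codes, nbins = 256)
  std <- counts[utf8ToInt(paste(AA_STANDARD, collapse = ""))]
  names(std) <- AA_STANDARD
  nonstd <- sum(counts[utf8ToInt(paste(AA_NONSTANDARD, collapse = ""))])
  total <- sum(std)
  if (total == 0) {
    abort("No standard residues in collection; composition undefined.")
  }
  structure(
    list(
      frequencies = std / total,
      counts = std,
      total_residues = total,
      nonstandard_residues = nonstd,
      protein_lengths = nchar(proteins$sequence)
    ),
    class = "aa_composition"
  )
}

#' Construct a background composition from explicit frequencies
#'
#' Used to describe a null model without a concrete protein collection, e.g.
#' a uniform background, together with hypothetical proteome dimensions.
#'
#' @param frequencies Named numeric vector over the 20 standard residues
#'   (normalised internally).
#' @param protein_lengths Integer vector of protein lengths defining the
#'   window counts.
#' @return An `aa_composition` object.
#' @export
aa_composition <- function(frequencies, protein_lengths) {
  stopifnot(setequal(names(frequencies), AA_STANDARD), all(frequencies >= 0))
  f <- frequencies[AA_STANDARD]
  f <- f / sum(f)
  structure(
    list(
      frequencies = f,
      counts = NULL,
      total_residues = sum(protein_lengths),
      nonstandard_residues = 0L,
      protein_lengths = as.integer(protein_lengths)
    ),
    class = "aa_composition"
  )
}

#' @export
print.aa_composition <- function(x, ...) {
  cat(sprintf(
    "<aa_composition> %d residues in %d protein(s); %d non-standard tallied\n",
    x$total_residues, length(x$protein_lengths), x$nonstandard_residues
  ))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' @method tidy aa_composition
#' @export
tidy.aa_composition <- function(x, ...) {
  tibble(residue = names(x$frequencies), frequency = unname(x$frequencies))
}

#' Number of scan windows of a given motif length
#'
#' Sum over proteins of `max(0, length - m + 1)`.
#'
#' @param composition An `aa_composition`.
#' @param m Motif length in positions.
#' @return Integer window count.
#' @export
window_count <- function(composition, m) {
  stopifnot(inherits(composition, "aa_composition"))
  sum(pmax(0L, composition$protein_lengths - as.integer(m) + 1L))
}

#' Chance-expected number of motif matches in a proteome
#'
#' Analytic null model with independent positions: the probability that a
#' random window drawn i.i.d. from the background composition matches the
#' motif is the product over positions of the summed frequencies of the
#' allowed residues, and the expected match count is that probability times
#' the number of windows. Overlap dependence between windows is ignored; the
#' approximation is excellent when the expectation is far below one match per
#' proteome, and can be checked empirically with
#' [empirical_expected_matches()].
#'
#' @param motif A `degenerate_motif` (or pattern string).
#' @param composition An `aa_composition`.
#' @return One-row tibble: `pattern`, `motif_length`, `window_count`,
#'   `p_window`, `expected`.
#' @export
expected_matches <- function(motif, composition) {
  if (is.character(motif)) motif <- parse_motif(motif)
  stopifnot(inherits(composition, "aa_composition"))
  p <- prod(purrr::map_dbl(motif$positions, function(pos) {
    sum(composition$frequencies[pos])
  }))
  W <- window_count(composition, motif_length(motif))
  tibble(
    pattern = format(motif),
    motif_length = motif_length(motif),
    window_count = W,
    p_window = p,
    expected = W * p
  )
}

#' Monte Carlo estimate of the expected motif match count
#'
#' Simulates proteomes of i.i.d. residues drawn from the background
#' composition, scans each with [scan_sequence()], and reports the mean match
#' count with its standard error. Serves as the empirical oracle for
#' [expected_matches()].
#'
#' @param motif A `degenerate_motif` (or pattern string).
#' @param composition An `aa_composition`; its `protein_lengths` define the
#'   simulated proteome shape unless `protein_lengths` is supplied.
#' @param n_proteomes Number of simulated proteomes (default 100).
#' @param protein_lengths Optional override of the simulated protein lengths.
#' @param seed Optional RNG seed.
#' @return One-row tibble: `estimate`, `se`, `n_proteomes`, `window_count`.
#' @export
empirical_expected_matches <- function(motif, composition, n_proteomes = 100,
                                       protein_lengths = NULL, seed = NULL) {
  if (is.character(motif)) motif <- parse_motif(motif)
  stopifnot(n_proteomes >= 1)
  lens <- as.integer(protein_lengths %||% composition$protein_lengths)
  lookup <- motif_lookup(motif)
  freqs <- composition$frequencies
  aa_codes <- utf8ToInt(paste(AA_STANDARD, collapse = ""))
  counts <- with_seed_if(seed, {
    vapply(seq_len(n_proteomes), function(i) {
      draws <- sample(aa_codes, sum(lens), replace = TRUE, prob = freqs)
      offs <- cumsum(c(0L, head(lens, -1)))
      total <- 0L
      for (k in seq_along(lens)) {
        codes <- draws[seq.int(offs[k] + 1L, offs[k] + lens[k])]
        total <- total + length(scan_codes(lookup, codes))
      }
      total
    }, double(1))
  })
  W <- sum(pmax(0L, lens - motif_length(motif) + 1L))
  tibble(
    estimate = mean(counts),
    se = if (n_proteomes > 1) sd(counts) / sqrt(n_proteomes) else NA_real_,
    n_proteomes = n_proteomes,
    window_count = W
  )
}

#' Induce a degenerate motif from equal-length ungapped sequences
#'
#' Generalises a set of aligned motif instances into a degenerate pattern:
#' per column, the allowed set is the residues whose frequency reaches
#' `min_column_frequency`; columns whose allowed set would exceed
#' `max_set_size` residues become wildcards. With `min_column_frequency <=
#' 1/n` the induced motif matches every input sequence.
#'
#' @param sequences Character vector (>= 2) of equal-length, gap-free
#'   sequences over the standard residues.
#' @param min_column_frequency Minimum column frequency for a residue to be
#'   allowed (default 0.1).
#' @param max_set_size Largest allowed-set size before the column becomes a
#'   wildcard (default 4).
#' @return A `degenerate_motif`.
#' @examples
#' format(induce_motif(c("VDPETGEIL", "IDESTGELI"), min_column_frequency = 0.5))
#' @export
induce_motif <- function(sequences, min_column_frequency = 0.1, max_set_size = 4) {
  stopifnot(length(sequences) >= 2)
  sequences <- toupper(sequences)
  if (any(grepl("-", sequences, fixed = TRUE))) {
    abort("Gapped sequences are not supported by motif induction.")
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    abort(sprintf(
      "Sequences must have equal length (sequence %d has %d residues, expected %d).",
      which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1]
    ))
  }
  check_residues(sequences, allow_nonstandard = FALSE, what = "input sequence")
  mat <- do.call(rbind, strsplit(sequences, ""))
  positions <- purrr::map(seq_len(ncol(mat)), function(j) {
    freq <- table(mat[, j]) / nrow(mat)
    allowed <- names(freq)[freq >= min_column_frequency]
    if (length(allowed) == 0 || length(allowed) > max_set_size) AA_STANDARD else allowed
  })
  motif <- new_degenerate_motif(positions)
  motif$source_text <- format(motif)
  motif
}
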