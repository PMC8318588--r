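#' Read a peptide uptake table
#'
#' Reads the native long-format uptake CSV dialect (one row per replicate
#' measurement) or a DynamX-style "state data" export. The native dialect has
#' columns `protein_id`, `start`, `end`, `sequence`, `state`, `exposure_min`,
#' `replicate`, `uptake_da` and optional `intensity`, `ppm_error`,
#' `products_per_aa`. The DynamX adapter maps `Protein`, `Start`, `End`,
#' `Sequence`, `State`, `Exposure` (minutes), `Uptake` and, when present,
#' `File` (replicate) and `Inten` (intensity) onto the native columns.
#'
#' @param path CSV file path.
#' @param dialect `"native"` (default) or `"dynamx_state"`.
#' @param proteins Optional protein tibble (from [read_proteins()]); when
#'   given, peptides are validated against the protein sequences and
#'   mismatches are rejected naming the row.
#' @return Uptake tibble in the native dialect.
#' @export
read_uptake_table <- function(path, dialect = c("native", "dynamx_state"),
                              proteins = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Uptake table not found: '%s'.", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "dynamx_state") {
    required <- c("Protein", "Start", "End", "Sequence", "State", "Exposure", "Uptake")
    missing <- setdiff(required, names(raw))
    if (length(missing)) {
      abort(sprintf("Missing required column '%s' in DynamX export.", missing[1]))
    }
    raw <- tibble(
      protein_id = as.character(raw$Protein),
      start = raw$Start,
      end = raw$End,
      sequence = toupper(raw$Sequence),
      state = as.character(raw$State),
      exposure_min = raw$Exposure,
      replicate = if ("File" %in% names(raw)) {
        as.integer(factor(raw$File))
      } else 1L,
      uptake_da = raw$Uptake,
      intensity = if ("Inten" %in% names(raw)) raw$Inten else NULL
    )
  }
  required <- c(
    "protein_id", "start", "end", "sequence", "state",
    "exposure_min", "replicate", "uptake_da"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("Missing required column '%s' in uptake table.", missing[1]))
  }
  for (col in c("start", "end", "exposure_min", "uptake_da")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric or missing '%s' value at row %d.", col, bad[1]
      ))
    }
    raw[[col]] <- v
  }
  if (any(raw$uptake_da < 0)) {
    abort(sprintf(
      "Negative uptake at row %d.", which(raw$uptake_da < 0)[1]
    ))
  }
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  raw$sequence <- toupper(raw$sequence)
  out <- as_tibble(raw)
  if (!is.null(proteins)) {
    seqs <- setNames(proteins$sequence, proteins$protein_id)
    unknown <- which(!out$protein_id %in% names(seqs))
    if (length(unknown)) {
      abort(sprintf(
        "Row %d references unknown protein '%s'.",
        unknown[1], out$protein_id[unknown[1]]
      ))
    }
    slice <- substr(seqs[out$protein_id], out$start, out$end)
    mism <- which(out$sequence != unname(slice))
    if (length(mism)) {
      abort(sprintf(
        "Row %d: peptide sequence '%s' does not match protein %s positions %d-%d.",
        mism[1], out$sequence[mism[1]], out$protein_id[mism[1]],
        out$start[mism[1]], out$end[mism[1]]
      ))
    }
  }
  out
}

#' Run the full differential HDX protection analysis
#'
#' Chains the peptide-level stages into the standard interface-mapping
#' workflow: identification-quality filtering, replicate summaries,
#' differential uptake with SEM envelopes, time-resolved protection calling,
#' reduction to minimal protected segments, and coverage/redundancy
#' statistics.
#'
#' @param uptake Uptake tibble (native dialect) containing both states.
#' @param state_apo,state_complex State labels. When the table has exactly
#'   two states they default to `"apo"`/`"complex"` if present, otherwise
#'   they must be given.
#' @param proteins Optional protein tibble for validation and coverage.
#' @param filter Apply [filter_peptides()] first (default `TRUE`).
#' @param thresholds Named list overriding [filter_peptides()] defaults.
#' @param scale Significance scale, see [differential_uptake()].
#' @param policy Named list overriding [call_protected_peptides()] defaults.
#' @return An `hdx_protection` object: list with `differential`, `protected`,
#'   `segments` (span-intersection minimal segments), `regions` (residue-level
#'   consensus protected regions, when `proteins` is given), `coverage`,
#'   `summaries`, `rejections` and `config`.
#'   Supports `tidy()`, `glance()`, `autoplot()` and `print()`.
#' @export
run_differential_analysis <- function(uptake,
                                      state_apo = "apo",
                                      state_complex = "complex",
                                      proteins = NULL,
                                      filter = TRUE,
                                      thresholds = list(),
                                      scale = c("da", "relative"),
                                      policy = list()) {
  scale <- match.arg(scale)
  states <- unique(uptake$state)
  if (length(states) < 2) {
    abort(sprintf(
      "Differential analysis needs two states; found %s.",
      paste(states, collapse = ", ")
    ))
  }
  rejections <- NULL
  if (filter) {
    filt <- do.call(filter_peptides, c(list(records = uptake), thresholds))
    uptake <- filt$retained
    rejections <- filt$rejections
    if (nrow(uptake) == 0) {
      abort("All records were removed by the identification filters.")
    }
  }
  summaries <- summarize_uptake(uptake)
  differential <- differential_uptake(summaries, state_apo, state_complex, scale = scale)
  protected <- do.call(
    call_protected_peptides,
    c(list(differentials = differential), policy)
  )
  segments <- minimal_protected_segments(protected, differential)
  regions <- if (!is.null(proteins)) {
    protected_regions(differential, protected, proteins)
  } else NULL
  coverage <- if (!is.null(proteins)) {
    coverage_redundancy(
      dplyr::distinct(uptake, .data$protein_id, .data$start, .data$end),
      proteins
    )
  } else NULL
  structure(
    list(
      differential = differential,
      protected = protected,
      segments = segments,
      regions = regions,
      coverage = coverage,
      summaries = summaries,
      rejections = rejections,
      config = list(
        state_apo = state_apo, state_complex = state_complex,
        scale = scale, filter = filter, thresholds = thresholds,
        policy = policy,
        version = as.character(packageVersion("hdxmotif"))
      )
    ),
    class = "hdx_protection"
  )
}

#' @export
print.hdx_protection <- function(x, ...) {
  cat(sprintf(
    "<hdx_protection> %d peptide-time differentials; %d protected peptide(s); %d segment(s)\n",
    nrow(x$differential), nrow(x$protected), nrow(x$segments)
  ))
  if (nrow(x$segments)) {
    seg <- dplyr::select(
      x$segments, "protein_id", "start", "end", "length", "n_supporting"
    )
    print(seg)
  }
  invisible(x)
}

#' @method tidy hdx_protection
#' @export
tidy.hdx_protection <- function(x, ...) x$differential

#' @method glance hdx_protection
#' @export
glance.hdx_protection <- function(x, ...) {
  tibble(
    n_peptides = dplyr::n_distinct(
      paste(x$differential$protein_id, x$differential$start, x$differential$end)
    ),
    n_times = dplyr::n_distinct(x$differential$exposure_min),
    n_protected = nrow(x$protected),
    n_segments = nrow(x$segments),
    n_regions = if (!is.null(x$regions)) nrow(x$regions) else NA_integer_,
    min_segment_length = if (nrow(x$segments)) min(x$segments$length) else NA_integer_,
    mean_coverage = if (!is.null(x$coverage)) mean(x$coverage$coverage_percent) else NA_real_,
    mean_redundancy = if (!is.null(x$coverage)) mean(x$coverage$redundancy) else NA_real_
  )
}

#' Woods-plot table: per-peptide differential uptake along the sequence
#'
#' @param x An `hdx_protection` object (or a [differential_uptake()] tibble).
#' @return Tibble ready for plotting or TSV export: peptide span, exposure
#'   time, `delta`, `envelope` and significance flags.
#' @export
woods_table <- function(x) {
  d <- if (inherits(x, "hdx_protection")) x$differential else x
  dplyr::select(
    d, "protein_id", "start", "end", "sequence", "exposure_min",
    "delta", "delta_relative", "envelope",
    "significant_protection", "significant_exposure"
  )
}

#' Butterfly-plot table: per-position mean relative uptake per state
#'
#' Expands peptide-level relative uptake onto residues (mean over the
#' peptides covering each residue), per state and exposure time.
#'
#' @param x An `hdx_protection` object (or a [summarize_uptake()] tibble).
#' @return Tibble: `protein_id`, `position`, `state`, `exposure_min`,
#'   `relative_uptake`.
#' @export
butterfly_table <- function(x) {
  s <- if (inherits(x, "hdx_protection")) x$summaries else x
  expanded <- tidyr::unnest(
    dplyr::mutate(s, position = purrr::map2(.data$start, .data$end, seq)),
    "position"
  )
  dplyr::summarise(
    dplyr::group_by(
      expanded, .data$protein_id, .data$position, .data$state, .data$exposure_min
    ),
    relative_uptake = mean(.data$relative_uptake),
    .groups = "drop"
  )
}

#' Write the protection analysis report to a directory
#'
#' Writes Woods tables (one TSV per exposure time), the butterfly table, the
#' coverage table and a JSON report of protected segments with the embedded
#' configuration, so every output is self-describing.
#'
#' @param x An `hdx_protection` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_protection_report <- function(x, dir) {
  stopifnot(inherits(x, "hdx_protection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- woods_table(x)
  for (t in unique(wt$exposure_min)) {
    readr::write_tsv(
      dplyr::filter(wt, .data$exposure_min == t),
      file.path(dir, sprintf("woods_%gmin.tsv", t))
    )
  }
  readr::write_tsv(butterfly_table(x), file.path(dir, "butterfly.tsv"))
  if (!is.null(x$coverage)) {
    readr::write_tsv(x$coverage, file.path(dir, "coverage.tsv"))
  }
  segments <- x$segments
  seg_list <- purrr::map(seq_len(nrow(segments)), function(i) {
    list(
      protein_id = segments$protein_id[i],
      start = segments$start[i],
      end = segments$end[i],
      length = segments$length[i],
      n_supporting = segments$n_supporting[i],
      supporting = segments$supporting[[i]]
    )
  })
  jsonlite::write_json(
    list(config = x$config, segments = seg_list),
    file.path(dir, "protected_segments.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Run the motif discovery and proteome-scan workflow
#'
#' Either parses a supplied PROSITE-style pattern or induces one from aligned
#' instance sequences, scans a proteome, and computes the chance-expected
#' match count from the proteome's own composition (optionally checked by
#' Monte Carlo).
#'
#' @param proteins Protein tibble or FASTA path.
#' @param pattern PROSITE-style pattern string (exclusive with `induce_from`).
#' @param induce_from Character vector of equal-length instances to
#'   generalise with [induce_motif()].
#' @param induce_args Named list of extra arguments for [induce_motif()].
#' @param monte_carlo Number of Monte Carlo proteomes for the empirical check
#'   (0, the default, skips it).
#' @param seed Seed for the Monte Carlo check.
#' @return A `motif_report` object: list with `motif`, `scan`
#'   (a `motif_scan`), `composition`, `expectation` and optionally
#'   `monte_carlo`. Supports `tidy()`, `glance()` and `print()`.
#' @export
run_motif_workflow <- function(proteins, pattern = NULL, induce_from = NULL,
                               induce_args = list(), monte_carlo = 0,
                               seed = NULL) {
  if (is.null(pattern) == is.null(induce_from)) {
    abort("Provide exactly one of `pattern` or `induce_from`.")
  }
  motif <- if (!is.null(pattern)) {
    parse_motif(pattern)
  } else {
    do.call(induce_motif, c(list(sequences = induce_from), induce_args))
  }
  if (is.character(proteins)) proteins <- read_proteins(proteins)
  scan <- scan_proteome(motif, proteins)
  composition <- background_composition(proteins)
  expectation <- expected_matches(motif, composition)
  mc <- if (monte_carlo > 0) {
    empirical_expected_matches(motif, composition, n_proteomes = monte_carlo, seed = seed)
  } else NULL
  structure(
    list(
      motif = motif,
      scan = scan,
      composition = composition,
      expectation = expectation,
      monte_carlo = mc,
      config = list(
        pattern = format(motif),
        induced = is.null(pattern),
        monte_carlo = monte_carlo,
        seed = seed,
        version = as.character(packageVersion("hdxmotif"))
      )
    ),
    class = "motif_report"
  )
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf(
    "<motif_report> pattern %s\n  %d match(es) in %d distinct protein(s) of %d; expected by chance %.3g\n",
    x$expectation$pattern, x$scan$total_matches, x$scan$distinct_proteins,
    x$scan$n_proteins, x$expectation$expected
  ))
  invisible(x)
}

#' @method tidy motif_report
#' @export
tidy.motif_report <- function(x, ...) x$scan$matches

#' @method glance motif_report
#' @export
glance.motif_report <- function(x, ...) {
  tibble(
    pattern = x$expectation$pattern,
    n_proteins = x$scan$n_proteins,
    distinct_proteins = x$scan$distinct_proteins,
    total_matches = x$scan$total_matches,
    window_count = x$expectation$window_count,
    p_window = x$expectation$p_window,
    expected = x$expectation$expected
  )
}

#' Write the motif workflow report to a directory
#'
#' Writes the match table as TSV and a JSON summary with pattern, counts,
#' expectation and proteome statistics.
#'
#' @param x A `motif_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_motif_report <- function(x, dir) {
  stopifnot(inherits(x, "motif_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$scan$matches, file.path(dir, "matches.tsv"))
  jsonlite::write_json(
    list(
      config = x$config,
      pattern = x$expectation$pattern,
      distinct_proteins = x$scan$distinct_proteins,
      total_matches = x$scan$total_matches,
      expected = x$expectation$expected,
      per_window_probability = x$expectation$p_window,
      window_count = x$expectation$window_count,
      n_proteins = x$scan$n_proteins,
      total_residues = x$composition$total_residues
    ),
    file.path(dir, "motif_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
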