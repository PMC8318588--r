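#' Configuration for the HDX-MS forward simulator
#'
#' Bundles and validates every parameter of the synthetic uptake model. The
#' defaults reproduce a typical differential HDX-MS binding experiment:
#' labelling times of 0.5, 2, 5 and 10 minutes, four technical replicates,
#' a deuterium fraction of 135/165 (30 ul protein diluted into 135 ul
#' deuterated buffer), 70% deuterium retention after quench/back-exchange,
#' and homoscedastic Gaussian replicate noise truncated at zero.
#'
#' Per-amide intrinsic exchange rates are drawn from a lognormal distribution
#' (`rate_meanlog`, `rate_sdlog`, in 1/min); inside the protected region the
#' complex-state rates are divided by the protection factor. Sequence-specific
#' intrinsic rate tables can be supplied via `rates` to override the lognormal
#' draw.
#'
#' @param protein Protein sequence string, or `NULL` to generate a random
#'   `protein_length`-mer from [bsubtilis_like_composition].
#' @param protein_length Length of the generated protein when `protein` is
#'   `NULL` (default 120).
#' @param times Exposure times in minutes, strictly increasing
#'   (default `c(0.5, 2, 5, 10)`).
#' @param replicates Technical replicates per state and time (default 4).
#' @param rate_meanlog,rate_sdlog Lognormal parameters of the per-amide
#'   intrinsic exchange rate in 1/min (defaults `log(1)` and 1.2).
#' @param rates Optional numeric vector of per-residue intrinsic rates
#'   (length = protein length) overriding the lognormal model.
#' @param protected_region Integer `c(start, end)` of the planted protected
#'   region (1-based inclusive), or `NULL` for none. Default `c(61, 67)`, a
#'   seven-residue patch mimicking a short interaction epitope.
#' @param protection_factor Fold reduction (>= 1) of exchange rates inside
#'   the protected region in the complex state (default 100).
#' @param deuterium_fraction Fraction of D2O in the labelling mix
#'   (default 135/165).
#' @param back_exchange Fraction of label retained through quench and
#'   chromatography (default 0.7).
#' @param noise_sd Replicate noise standard deviation in Da (default 0.1).
#' @param peptide_map List of peptide-map parameters: `mean_length` (12),
#'   `length_sd` (2), `step` (6), `min_length` (6), `max_length` (25).
#' @param exclude_first Exchangeable-amide convention, see
#'   [max_exchangeable_amides()].
#' @param seed RNG seed (integer) for bit-reproducible simulations.
#' @return A validated `hdx_sim_config` list.
#' @export
hdx_sim_config <- function(protein = NULL,
                           protein_length = 120,
                           times = c(0.5, 2, 5, 10),
                           replicates = 4,
                           rate_meanlog = log(1),
                           rate_sdlog = 1.2,
                           rates = NULL,
                           protected_region = c(61, 67),
                           protection_factor = 100,
                           deuterium_fraction = 135 / 165,
                           back_exchange = 0.7,
                           noise_sd = 0.1,
                           peptide_map = list(),
                           exclude_first = 1,
                           seed = 1) {
  stopifnot(
    protection_factor >= 1,
    deuterium_fraction > 0, deuterium_fraction <= 1,
    back_exchange > 0, back_exchange <= 1,
    noise_sd >= 0,
    replicates >= 1,
    all(diff(times) > 0), all(times > 0)
  )
  pm <- utils::modifyList(
    list(mean_length = 12, length_sd = 2, step = 6, min_length = 6, max_length = 25),
    peptide_map
  )
  if (!is.null(protected_region)) {
    stopifnot(length(protected_region) == 2, protected_region[1] <= protected_region[2])
  }
  structure(
    list(
      protein = protein, protein_length = protein_length,
      times = times, replicates = replicates,
      rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog, rates = rates,
      protected_region = protected_region,
      protection_factor = protection_factor,
      deuterium_fraction = deuterium_fraction,
      back_exchange = back_exchange,
      noise_sd = noise_sd,
      peptide_map = pm,
      exclude_first = exclude_first,
      seed = as.integer(seed)
    ),
    class = "hdx_sim_config"
  )
}

#' Generate an overlapping peptide map over a protein
#'
#' Emulates a pepsin peptide map: peptide starts are laid on a regular grid
#' of spacing `step` and lengths are drawn from a normal distribution,
#' rounded and clipped to `[min_length, max_length]` and to the protein end.
#' A terminal peptide is appended if the grid leaves the C-terminus
#' uncovered, so the map always reaches full coverage.
#'
#' @param protein Protein sequence string.
#' @param mean_length,length_sd,step,min_length,max_length Map geometry (see
#'   [hdx_sim_config()] for defaults).
#' @param protein_id Identifier for the peptide table (default `"sim"`).
#' @param exclude_first Exchangeable-amide convention.
#' @param seed Optional RNG seed.
#' @return Peptide tibble: `protein_id`, `start`, `end`, `sequence`,
#'   `max_uptake`.
#' @export
generate_peptide_map <- function(protein, mean_length = 12, length_sd = 2,
                                 step = 6, min_length = 6, max_length = 25,
                                 protein_id = "sim", exclude_first = 1,
                                 seed = NULL) {
  L <- nchar(protein)
  if (L < min_length) {
    abort(sprintf(
      "Protein of length %d is shorter than the minimum peptide length %d.",
      L, min_length
    ))
  }
  with_seed_if(seed, {
    starts <- seq.int(1L, max(1L, L - min_length + 1L), by = step)
    lens <- pmin(
      pmax(round(rnorm(length(starts), mean_length, length_sd)), min_length),
      max_length
    )
    ends <- pmin(starts + lens - 1L, L)
    # drop degenerate tail duplicates, ensure the C-terminus is covered
    keep <- ends - starts + 1L >= min_length
    starts <- starts[keep]; ends <- ends[keep]
    if (max(ends) < L) {
      starts <- c(starts, L - min(max_length, max(min_length, round(mean_length))) + 1L)
      ends <- c(ends, L)
    }
    pep <- dplyr::distinct(tibble(start = as.integer(starts), end = as.integer(ends)))
    tibble(
      protein_id = protein_id,
      start = pep$start,
      end = pep$end,
      sequence = substring(protein, pep$start, pep$end),
      max_uptake = max_exchangeable_amides(
        substring(protein, pep$start, pep$end),
        exclude_first = exclude_first
      )
    )
  })
}

# Noiseless deuterium uptake of one peptide at time t (minutes):
# back_exchange * deuterium_fraction * sum over exchangeable amides of
# (1 - exp(-k t)). `amide_rates` are the rates of the peptide's amides.
noiseless_uptake <- function(amide_rates, t, deuterium_fraction, back_exchange) {
  back_exchange * deuterium_fraction * sum(1 - exp(-amide_rates * t))
}

#' Forward-simulate a two-state differential HDX-MS experiment
#'
#' Simulates replicate peptide uptake tables for an apo and a complex state
#' of one protein with a planted protected region. Each residue carries an
#' intrinsic exchange rate; in the complex state, rates inside the protected
#' region are divided by the protection factor. The noiseless peptide uptake
#' at exposure time `t` is
#' `back_exchange * deuterium_fraction * sum_i (1 - exp(-k_i t))` over the
#' peptide's exchangeable amides, and replicates add independent Gaussian
#' noise truncated at zero. The output conforms to the native uptake-table
#' dialect accepted by [read_uptake_table()].
#'
#' @param config An [hdx_sim_config()].
#' @return An `hdx_sim` list: `uptake` (long tibble with states `"apo"` and
#'   `"complex"`), `peptides`, `protein` (tibble row), `truth` (planted
#'   region and per-residue rates) and `config`. Bit-reproducible for a fixed
#'   seed.
#' @export
simulate_uptake <- function(config) {
  stopifnot(inherits(config, "hdx_sim_config"))
  with_seed_if(config$seed, {
    protein <- config$protein %||% paste(
      sample(AA_STANDARD, config$protein_length,
        replace = TRUE, prob = bsubtilis_like_composition
      ),
      collapse = ""
    )
    L <- nchar(protein)
    residues <- strsplit(protein, "")[[1]]
    rates <- config$rates %||% rlnorm(L, config$rate_meanlog, config$rate_sdlog)
    stopifnot(length(rates) == L)

    region <- config$protected_region
    protected_res <- if (is.null(region)) integer() else region[1]:region[2]
    rates_complex <- rates
    rates_complex[protected_res] <- rates_complex[protected_res] / config$protection_factor

    peptides <- generate_peptide_map(
      protein,
      mean_length = config$peptide_map$mean_length,
      length_sd = config$peptide_map$length_sd,
      step = config$peptide_map$step,
      min_length = config$peptide_map$min_length,
      max_length = config$peptide_map$max_length,
      exclude_first = config$exclude_first
    )

    grid <- tidyr::expand_grid(
      pep = seq_len(nrow(peptides)),
      state = c("apo", "complex"),
      exposure_min = config$times,
      replicate = seq_len(config$replicates)
    )
    amides <- purrr::map(seq_len(nrow(peptides)), function(i) {
      peptide_amide_residues(
        residues, peptides$start[i], peptides$end[i],
        exclude_first = config$exclude_first
      )
    })
    noiseless <- purrr::pmap_dbl(
      list(grid$pep, grid$state, grid$exposure_min),
      function(i, st, t) {
        k <- if (st == "apo") rates[amides[[i]]] else rates_complex[amides[[i]]]
        noiseless_uptake(k, t, config$deuterium_fraction, config$back_exchange)
      }
    )
    uptake <- tibble(
      protein_id = peptides$protein_id[grid$pep],
      start = peptides$start[grid$pep],
      end = peptides$end[grid$pep],
      sequence = peptides$sequence[grid$pep],
      state = grid$state,
      exposure_min = grid$exposure_min,
      replicate = grid$replicate,
      uptake_da = pmax(0, noiseless + rnorm(nrow(grid), 0, config$noise_sd))
    )
    structure(
      list(
        uptake = uptake,
        peptides = peptides,
        protein = tibble(
          protein_id = "sim", description = "simulated analyte",
          sequence = protein, length = L
        ),
        truth = list(
          protected_region = region,
          protection_factor = config$protection_factor,
          rates_apo = rates,
          rates_complex = rates_complex
        ),
        config = config
      ),
      class = "hdx_sim"
    )
  })
}

#' Generate a synthetic proteome with planted motif instances
#'
#' Proteins are i.i.d. residue strings drawn from a background composition,
#' with lengths drawn from a lognormal distribution. Motif instance strings
#' are planted by overwriting random windows; planted instances never overlap
#' each other, and by default each copy goes to a distinct protein. The
#' manifest records the planted coordinates (the ground truth for scanner
#' completeness checks).
#'
#' @param n_proteins Number of proteins.
#' @param mean_length Mean protein length (default 285, a typical bacterial
#'   proteome mean).
#' @param length_sdlog Lognormal sdlog of the length distribution
#'   (default 0.55).
#' @param min_length Minimum protein length (default 40).
#' @param composition Named residue frequency vector (default
#'   [bsubtilis_like_composition]).
#' @param planted Character vector of motif instance strings to plant, one
#'   copy each (repeat a string for several copies).
#' @param distinct_proteins Plant each instance in a distinct protein
#'   (default `TRUE`).
#' @param seed Optional RNG seed.
#' @return List with `proteins` (tibble as from [read_proteins()]) and
#'   `manifest` (tibble `protein_id`, `start`, `end`, `sequence`).
#' @export
generate_proteome <- function(n_proteins,
                              mean_length = 285,
                              length_sdlog = 0.55,
                              min_length = 40,
                              composition = bsubtilis_like_composition,
                              planted = character(),
                              distinct_proteins = TRUE,
                              seed = NULL) {
  stopifnot(n_proteins >= 1)
  if (length(planted)) check_residues(planted, allow_nonstandard = FALSE, what = "planted instance")
  with_seed_if(seed, {
    meanlog <- log(mean_length) - length_sdlog^2 / 2
    lens <- pmax(min_length, round(rlnorm(n_proteins, meanlog, length_sdlog)))
    draws <- sample(AA_STANDARD, sum(lens), replace = TRUE, prob = composition[AA_STANDARD])
    offs <- cumsum(c(0, head(lens, -1)))
    seqs <- vapply(seq_len(n_proteins), function(i) {
      paste(draws[seq.int(offs[i] + 1, offs[i] + lens[i])], collapse = "")
    }, character(1))
    ids <- sprintf("SYN%05d", seq_len(n_proteins))

    manifest <- tibble(
      protein_id = character(), start = integer(), end = integer(),
      sequence = character()
    )
    if (length(planted)) {
      m <- nchar(planted)
      eligible <- which(lens >= max(m))
      if (distinct_proteins && length(eligible) < length(planted)) {
        abort("Not enough proteins long enough to plant every instance.")
      }
      hosts <- if (distinct_proteins) {
        sample(eligible, length(planted))
      } else {
        sample(eligible, length(planted), replace = TRUE)
      }
      occupied <- purrr::map(seq_len(n_proteins), function(i) integer())
      for (k in seq_along(planted)) {
        i <- hosts[k]
        placed <- FALSE
        for (attempt in seq_len(200)) {
          s <- sample.int(lens[i] - m[k] + 1L, 1L)
          win <- s:(s + m[k] - 1L)
          if (!any(win %in% occupied[[i]])) {
            substr(seqs[i], s, s + m[k] - 1L) <- planted[k]
            occupied[[i]] <- c(occupied[[i]], win)
            manifest <- dplyr::bind_rows(manifest, tibble(
              protein_id = ids[i], start = as.integer(s),
              end = as.integer(s + m[k] - 1L), sequence = planted[k]
            ))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort("Could not place a planted instance without overlap.")
        }
      }
    }
    list(
      proteins = tibble(
        protein_id = ids,
        description = "synthetic protein",
        sequence = seqs,
        length = nchar(seqs)
      ),
      manifest = manifest
    )
  })
}

#' Generate a synthetic ortholog alignment with controlled conservation
#'
#' Derives `n` sequences from a reference: each non-conserved column is
#' substituted independently with probability `substitution_prob` (the
#' replacement is drawn uniformly from the 19 other residues); columns listed
#' in `conserved_columns` are never substituted, so their conservation is 1.0
#' by construction. Optionally, short deletions are introduced as gap runs.
#'
#' @param reference Reference sequence string (gap-free).
#' @param n Number of derived sequences (the reference itself is included as
#'   the first entry).
#' @param substitution_prob Per-column substitution probability.
#' @param indel_prob Per-sequence probability of one deletion run of 1-3
#'   columns (default 0).
#' @param conserved_columns Integer vector of columns never substituted.
#' @param seed Optional RNG seed.
#' @return Alignment tibble as from [read_alignment()], reference first with
#'   id `"ref"`.
#' @export
generate_ortholog_set <- function(reference, n,
                                  substitution_prob = 0.1,
                                  indel_prob = 0,
                                  conserved_columns = NULL,
                                  seed = NULL) {
  stopifnot(n >= 1, substitution_prob >= 0, substitution_prob <= 1)
  check_residues(reference, allow_nonstandard = FALSE, what = "reference")
  L <- nchar(reference)
  ref_chars <- strsplit(reference, "")[[1]]
  mutable <- setdiff(seq_len(L), conserved_columns %||% integer())
  with_seed_if(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      chars <- ref_chars
      hit <- mutable[stats::runif(length(mutable)) < substitution_prob]
      for (j in hit) {
        chars[j] <- sample(setdiff(AA_STANDARD, chars[j]), 1)
      }
      if (indel_prob > 0 && stats::runif(1) < indel_prob) {
        run <- sample.int(3L, 1L)
        at <- sample.int(L - run + 1L, 1L)
        chars[at:(at + run - 1L)] <- "-"
      }
      paste(chars, collapse = "")
    }, character(1))
    tibble(
      id = c("ref", sprintf("ortho%03d", seq_len(n))),
      description = c("reference", rep("synthetic ortholog", n)),
      aligned = c(reference, seqs),
      alignment_length = L
    )
  })
}
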