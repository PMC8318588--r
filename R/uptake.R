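#' Filter peptide uptake records with DynamX-style identification thresholds
#'
#' Applies the standard peptide-identification quality thresholds to an
#' uptake table (long format, one row per replicate measurement). A record is
#' a peptide x state x exposure-time group; it is retained only if every
#' threshold whose quantity is present in the table passes. Missing optional
#' columns (`intensity`, `products_per_aa`, `ppm_error`) skip the
#' corresponding rule, because those quantities may already have been applied
#' upstream by the vendor software and dropped from the export.
#'
#' When a group carries several values of a quality quantity (e.g. one
#' intensity per replicate) the most pessimistic value is tested: minimum
#' intensity, minimum products per amino acid, maximum absolute ppm error.
#'
#' @param records Uptake tibble with at least `protein_id`, `start`, `end`,
#'   `sequence`, `state`, `exposure_min`, `uptake_da`.
#' @param min_intensity Minimum signal intensity (default 1000).
#' @param min_products_per_aa Minimum MS/MS products per amino acid
#'   (default 0.3).
#' @param max_length Maximum peptide length in residues, inclusive
#'   (default 25).
#' @param max_ppm Maximum absolute mass error in ppm (default 6).
#' @param min_replication Minimum number of replicate measurements per record
#'   (default 4).
#' @return A list with `retained` (rows of `records` belonging to passing
#'   groups) and `rejections` (one row per rejected record with the first
#'   failing rule in `reason`).
#' @export
filter_peptides <- function(records,
                            min_intensity = 1000,
                            min_products_per_aa = 0.3,
                            max_length = 25,
                            max_ppm = 6,
                            min_replication = 4) {
  stopifnot(
    min_intensity >= 0, min_products_per_aa >= 0,
    max_length >= 0, max_ppm >= 0, min_replication >= 0
  )
  keys <- c("protein_id", "start", "end", "sequence", "state", "exposure_min")
  stopifnot(all(keys %in% names(records)))

  grouped <- dplyr::group_by(records, dplyr::across(dplyr::all_of(keys)))
  summ <- dplyr::summarise(
    grouped,
    n_replicates = dplyr::n(),
    .min_intensity = if ("intensity" %in% names(records)) {
      suppressWarnings(min(.data$intensity, na.rm = TRUE))
    } else NA_real_,
    .min_ppaa = if ("products_per_aa" %in% names(records)) {
      suppressWarnings(min(.data$products_per_aa, na.rm = TRUE))
    } else NA_real_,
    .max_ppm = if ("ppm_error" %in% names(records)) {
      suppressWarnings(max(abs(.data$ppm_error), na.rm = TRUE))
    } else NA_real_,
    .groups = "drop"
  )
  # all-NA groups yield +-Inf from min/max; treat as absent
  summ$.min_intensity[!is.finite(summ$.min_intensity)] <- NA_real_
  summ$.min_ppaa[!is.finite(summ$.min_ppaa)] <- NA_real_
  summ$.max_ppm[!is.finite(summ$.max_ppm)] <- NA_real_

  # first failing rule, in the order the thresholds are conventionally quoted
  reason <- rep(NA_character_, nrow(summ))
  fail <- function(cond, label) {
    ifelse(is.na(reason) & !is.na(cond) & cond, label, reason)
  }
  reason <- fail(summ$.min_intensity < min_intensity, "min_intensity")
  reason <- fail(summ$.min_ppaa < min_products_per_aa, "min_products_per_aa")
  reason <- fail(nchar(summ$sequence) > max_length, "max_length")
  reason <- fail(summ$.max_ppm > max_ppm, "max_ppm")
  reason <- fail(summ$n_replicates < min_replication, "min_replication")
  summ$reason <- reason

  rejected <- dplyr::filter(summ, !is.na(.data$reason))
  retained_keys <- dplyr::filter(summ, is.na(.data$reason))
  retained <- dplyr::semi_join(records, retained_keys, by = keys)
  rejections <- dplyr::select(
    rejected,
    dplyr::all_of(keys), "n_replicates", "reason"
  )
  list(retained = as_tibble(retained), rejections = as_tibble(rejections))
}

#' Summarise replicate deuterium uptake per peptide, state and exposure time
#'
#' Computes the replicate mean, the standard error of the mean (sample
#' standard deviation with an n-1 denominator divided by sqrt(n)) and the
#' relative uptake (mean divided by the peptide's maximum exchangeable amide
#' count). Records with a single replicate get `sem = NA` -- they cannot be
#' significance-tested and are never silently treated as zero-variance.
#'
#' @param records Uptake tibble (long format) with `protein_id`, `start`,
#'   `end`, `sequence`, `state`, `exposure_min`, `uptake_da`.
#' @param exclude_first Passed to [max_exchangeable_amides()].
#' @return Tibble with one row per peptide x state x time: `mean_uptake`,
#'   `sem`, `n`, `max_uptake`, `relative_uptake` (NA when `max_uptake` is 0).
#' @export
summarize_uptake <- function(records, exclude_first = 1) {
  keys <- c("protein_id", "start", "end", "sequence", "state", "exposure_min")
  stopifnot(all(c(keys, "uptake_da") %in% names(records)))
  if (any(records$uptake_da < 0, na.rm = TRUE)) {
    abort("Negative deuterium uptake value in records.")
  }
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(keys))),
    mean_uptake = mean(.data$uptake_da),
    sem = ifelse(dplyr::n() > 1, sd(.data$uptake_da) / sqrt(dplyr::n()), NA_real_),
    n = dplyr::n(),
    .groups = "drop"
  )
  out$max_uptake <- max_exchangeable_amides(out$sequence, exclude_first = exclude_first)
  out$relative_uptake <- ifelse(
    out$max_uptake > 0, out$mean_uptake / out$max_uptake, NA_real_
  )
  dplyr::arrange(out, .data$protein_id, .data$start, .data$end, .data$state, .data$exposure_min)
}

#' Differential uptake between two states with an SEM envelope
#'
#' For every peptide and exposure time shared by the two states, computes
#' `delta = mean(complex) - mean(apo)` in daltons, the corresponding
#' difference of relative uptakes, and the summed-SEM envelope
#' `sem(apo) + sem(complex)`. A peptide/time is called significantly
#' protected when `delta < -envelope` and significantly exposed when
#' `delta > envelope` (strict inequalities: touching envelopes are not
#' significant, matching the non-overlapping shadowing rule used on
#' differential uptake plots). Significance is evaluated on the dalton scale
#' by default; set `scale = "relative"` to use relative uptake instead.
#'
#' @param summaries Output of [summarize_uptake()] containing exactly the two
#'   states being compared (or more, with the two named explicitly).
#' @param state_apo,state_complex State labels; `delta < 0` means less uptake
#'   (protection) in `state_complex`.
#' @param scale `"da"` (default) or `"relative"`: scale on which the envelope
#'   rule is evaluated.
#' @return Tibble with one row per shared peptide x time: `delta`,
#'   `delta_relative`, `envelope`, `significant_protection`,
#'   `significant_exposure`. Rows where either state has an undefined SEM
#'   (single replicate) carry `NA` flags.
#' @export
differential_uptake <- function(summaries, state_apo, state_complex,
                                scale = c("da", "relative")) {
  scale <- match.arg(scale)
  states <- unique(summaries$state)
  if (!all(c(state_apo, state_complex) %in% states)) {
    abort(sprintf(
      "States '%s' and '%s' must both be present (found: %s).",
      state_apo, state_complex, paste(states, collapse = ", ")
    ))
  }
  keys <- c("protein_id", "start", "end", "sequence", "exposure_min")
  apo <- dplyr::filter(summaries, .data$state == state_apo)
  cpx <- dplyr::filter(summaries, .data$state == state_complex)
  joined <- dplyr::inner_join(
    dplyr::select(apo, dplyr::all_of(keys), "max_uptake",
      mean_apo = "mean_uptake", sem_apo = "sem", rel_apo = "relative_uptake",
      n_apo = "n"
    ),
    dplyr::select(cpx, dplyr::all_of(keys),
      mean_complex = "mean_uptake", sem_complex = "sem",
      rel_complex = "relative_uptake", n_complex = "n"
    ),
    by = keys
  )
  if (nrow(joined) == 0) {
    abort("No peptide/exposure-time pairs are shared between the two states.")
  }
  joined$delta <- joined$mean_complex - joined$mean_apo
  joined$delta_relative <- joined$rel_complex - joined$rel_apo
  joined$envelope <- joined$sem_apo + joined$sem_complex

  if (scale == "da") {
    stat <- joined$delta
    env <- joined$envelope
  } else {
    stat <- joined$delta_relative
    env <- ifelse(joined$max_uptake > 0, joined$envelope / joined$max_uptake, NA_real_)
  }
  joined$significant_protection <- stat < 0 & abs(stat) > env
  joined$significant_exposure <- stat > 0 & stat > env
  if (anyNA(joined$envelope)) {
    warn("Some records have a single replicate; their significance flags are NA.")
  }
  dplyr::arrange(
    joined,
    .data$protein_id, .data$start, .data$end, .data$exposure_min
  )
}
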