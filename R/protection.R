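#' Call protected peptides from time-resolved differential uptake
#'
#' A peptide is called protected when it is significantly protected (by the
#' SEM-envelope rule of [differential_uptake()]) at a minimum number of
#' exposure times, by default including the longest exposure -- binding-site
#' protection grows with exchange time, whereas noise does not. An optional
#' stricter policy additionally requires the magnitude of the uptake
#' difference to be non-decreasing across exposure times, allowing a slack of
#' one envelope per step.
#'
#' @param differentials Output of [differential_uptake()].
#' @param min_significant_times Minimum number of significantly protected
#'   exposure times (default 2).
#' @param require_longest_time Require significance at the longest exposure
#'   time observed for the peptide (default `TRUE`).
#' @param require_nondecreasing Require `|delta|` non-decreasing in time
#'   within one envelope of slack (default `FALSE`).
#' @return Tibble of protected peptides: `protein_id`, `start`, `end`,
#'   `sequence`, `max_uptake`, `n_times`, `n_significant`, `delta_longest`.
#' @export
call_protected_peptides <- function(differentials,
                                    min_significant_times = 2,
                                    require_longest_time = TRUE,
                                    require_nondecreasing = FALSE) {
  keys <- c("protein_id", "start", "end", "sequence")
  grouped <- dplyr::group_by(differentials, dplyr::across(dplyr::all_of(keys)))
  per_pep <- dplyr::summarise(
    grouped,
    max_uptake = .data$max_uptake[1],
    n_times = dplyr::n(),
    n_significant = sum(.data$significant_protection, na.rm = TRUE),
    sig_longest = {
      i <- which.max(.data$exposure_min)
      isTRUE(.data$significant_protection[i])
    },
    delta_longest = .data$delta[which.max(.data$exposure_min)],
    nondecreasing = {
      o <- order(.data$exposure_min)
      d <- abs(.data$delta[o])
      e <- .data$envelope[o]
      if (length(d) < 2) TRUE else all(diff(d) >= -e[-1], na.rm = TRUE)
    },
    .groups = "drop"
  )
  keep <- per_pep$n_significant >= min_significant_times
  if (require_longest_time) keep <- keep & per_pep$sig_longest
  if (require_nondecreasing) keep <- keep & per_pep$nondecreasing
  out <- per_pep[keep, , drop = FALSE]
  dplyr::select(out, -"sig_longest", -"nondecreasing")
}

#' Minimal protected segments from overlapping protected peptides
#'
#' Reduces a set of protected peptides to the smallest protein regions that
#' can explain them: peptide spans are intervals, and because intervals have
#' the Helly property, every maximal group of mutually overlapping spans has a
#' non-empty common intersection. The function returns one segment per such
#' maximal group -- the intersection of its members' spans -- via an endpoint
#' sweep (a maximal group closes every time a span start is immediately
#' followed by a span end in coordinate order). With two overlapping
#' peptides this is simply their span intersection; with dense maps a single
#' protected region is reported as a run of short, overlapping-evidence
#' segments.
#'
#' @param protected_peptides Tibble with `protein_id`, `start`, `end` (e.g.
#'   from [call_protected_peptides()]). Duplicate spans are collapsed.
#' @param differentials Optional [differential_uptake()] table used to
#'   annotate each segment with the mean `delta` of its supporting peptides at
#'   each exposure time (nested in `per_time_delta`).
#' @return Tibble with one row per segment: `protein_id`, `start`, `end`,
#'   `length`, `n_supporting`, `supporting` (list column of span tibbles) and,
#'   when `differentials` is given, `per_time_delta` (list column of
#'   `exposure_min`/`delta` tibbles).
#' @export
minimal_protected_segments <- function(protected_peptides, differentials = NULL) {
  if (nrow(protected_peptides) == 0) {
    return(tibble(
      protein_id = character(), start = integer(), end = integer(),
      length = integer(), n_supporting = integer(), supporting = list()
    ))
  }
  out <- purrr::map_dfr(
    split(protected_peptides, protected_peptides$protein_id),
    function(pep) {
      spans <- dplyr::distinct(pep, .data$start, .data$end)
      spans <- dplyr::arrange(spans, .data$start, .data$end)
      segs <- span_clique_intersections(spans$start, spans$end)
      purrr::map_dfr(segs, function(s) {
        sup <- spans[s$members, , drop = FALSE]
        tibble(
          protein_id = pep$protein_id[1],
          start = s$start, end = s$end,
          length = s$end - s$start + 1L,
          n_supporting = nrow(sup),
          supporting = list(sup)
        )
      })
    }
  )
  out <- dplyr::arrange(out, .data$protein_id, .data$start, .data$end)
  if (!is.null(differentials)) {
    out$per_time_delta <- purrr::map2(
      out$protein_id, out$supporting,
      function(pid, sup) {
        d <- dplyr::semi_join(
          dplyr::filter(differentials, .data$protein_id == pid),
          sup,
          by = c("start", "end")
        )
        dplyr::summarise(
          dplyr::group_by(d, .data$exposure_min),
          delta = mean(.data$delta), .groups = "drop"
        )
      }
    )
  }
  out
}

# Endpoint sweep over inclusive integer intervals. Returns a list of maximal
# cliques of mutually overlapping intervals, each with its common
# intersection [start, end] and member indices. Starts sort before ends at
# the same coordinate because [a, x] and [x, b] overlap at x.
span_clique_intersections <- function(starts, ends) {
  n <- length(starts)
  if (n == 0) return(list())
  ev_pos <- c(starts, ends)
  ev_type <- rep(c(0L, 1L), each = n) # 0 = start, 1 = end
  ev_id <- c(seq_len(n), seq_len(n))
  o <- order(ev_pos, ev_type)
  active <- logical(n)
  last_start <- NA_integer_
  prev_was_start <- FALSE
  cliques <- list()
  for (k in o) {
    if (ev_type[k] == 0L) {
      active[ev_id[k]] <- TRUE
      last_start <- ev_pos[k]
      prev_was_start <- TRUE
    } else {
      if (prev_was_start) {
        cliques[[length(cliques) + 1]] <- list(
          start = last_start,
          end = ev_pos[k],
          members = which(active)
        )
      }
      active[ev_id[k]] <- FALSE
      prev_was_start <- FALSE
    }
  }
  cliques
}

#' Residue-level protected regions by block attribution of uptake differences
#'
#' Localises protection at (near-)residue resolution by deconvolving the
#' peptide-level uptake differences onto residue blocks. Each analysed
#' peptide reports the total protection of the residues carrying its
#' exchangeable amides (its N-terminal residue and prolines carry no amide,
#' hence no information); residues amide-covered by the same set of peptides
#' are indistinguishable and form a block -- the intrinsic resolution limit
#' of an overlapping peptide map. The magnitude of protection at the longest
#' exposure time gives each peptide a budget `max(0, -delta)`, and blocks are
#' greedily assigned protection mass, deepest (most protected peptides)
#' first, never exceeding the remaining budget of any covering peptide.
#' Peptides without significant protection have near-zero budgets, so blocks
#' they cover are automatically exonerated; flank blocks touched only by an
#' edge-clipping protected peptide inherit only that peptide's small residual
#' budget and fall below threshold.
#'
#' A block is called protected when its assigned per-residue protection
#' exceeds `threshold` (by default the mean SEM envelope at the longest
#' exposure, i.e. the measurement uncertainty scale). Uninformative gaps
#' (prolines, peptide N-termini, uncovered positions) flanked by protected
#' blocks are bridged, and maximal protected runs are returned as regions.
#'
#' @param differentials Output of [differential_uptake()] (all analysed
#'   peptides, all times).
#' @param protected_peptides Protected peptides from
#'   [call_protected_peptides()].
#' @param proteins Protein tibble with `sequence` (needed to locate
#'   prolines).
#' @param threshold Per-residue protection call threshold in Da; `NULL`
#'   (default) uses the mean envelope at the longest exposure time.
#' @param exclude_first Exchangeable-amide convention, see
#'   [max_exchangeable_amides()].
#' @return Tibble of regions: `protein_id`, `start`, `end`, `length`,
#'   `n_supporting` (protected peptides overlapping the region).
#' @export
protected_regions <- function(differentials, protected_peptides, proteins,
                              threshold = NULL, exclude_first = 1) {
  purrr::map_dfr(seq_len(nrow(proteins)), function(pi) {
    pid <- proteins$protein_id[pi]
    residues <- strsplit(proteins$sequence[pi], "")[[1]]
    L <- length(residues)
    diffs <- dplyr::filter(differentials, .data$protein_id == pid)
    prot_pep <- dplyr::distinct(
      dplyr::filter(protected_peptides, .data$protein_id == pid),
      .data$start, .data$end
    )
    if (nrow(prot_pep) == 0 || nrow(diffs) == 0) return(NULL)

    # per-peptide delta and envelope at the longest exposure time
    per_pep <- dplyr::summarise(
      dplyr::group_by(diffs, .data$start, .data$end),
      delta_longest = .data$delta[which.max(.data$exposure_min)],
      envelope_longest = .data$envelope[which.max(.data$exposure_min)],
      .groups = "drop"
    )
    th <- threshold %||% mean(per_pep$envelope_longest, na.rm = TRUE)
    budget <- pmax(0, -per_pep$delta_longest)
    is_protected <- paste(per_pep$start, per_pep$end) %in%
      paste(prot_pep$start, prot_pep$end)

    # amide-coverage signature per residue (which analysed peptides report)
    cov <- matrix(FALSE, nrow = nrow(per_pep), ncol = L)
    for (j in seq_len(nrow(per_pep))) {
      idx <- peptide_amide_residues(
        residues, per_pep$start[j], per_pep$end[j], exclude_first = exclude_first
      )
      cov[j, idx] <- TRUE
    }
    informative <- colSums(cov) > 0
    sig <- apply(cov, 2, function(col) paste(which(col), collapse = ","))

    # blocks: maximal runs of identical non-empty signatures
    block_id <- cumsum(c(TRUE, sig[-1] != sig[-L]))
    blocks <- purrr::map_dfr(
      split(seq_len(L)[informative], block_id[informative]),
      function(idx) {
        covering <- which(cov[, idx[1]])
        tibble(
          start = idx[1], end = idx[length(idx)], n_res = length(idx),
          peps = list(covering),
          depth = sum(is_protected[covering])
        )
      }
    )
    blocks <- dplyr::filter(blocks, .data$depth >= 1)
    if (nrow(blocks) == 0) return(NULL)
    blocks <- dplyr::arrange(blocks, dplyr::desc(.data$depth), .data$start)

    remaining <- budget
    blocks$mass <- 0
    for (j in seq_len(nrow(blocks))) {
      peps <- blocks$peps[[j]]
      m <- max(0, min(remaining[peps]))
      blocks$mass[j] <- m
      remaining[peps] <- remaining[peps] - m
    }
    blocks$intensity <- blocks$mass / blocks$n_res
    called <- dplyr::filter(blocks, .data$intensity > th)
    if (nrow(called) == 0) return(NULL)

    is_prot <- logical(L)
    for (j in seq_len(nrow(called))) {
      is_prot[called$start[j]:called$end[j]] <- TRUE
    }
    # bridge uninformative runs flanked by protected residues on both sides
    info_idx <- which(informative)
    if (length(info_idx) >= 2) {
      gaps <- which(diff(info_idx) > 1)
      for (g in gaps) {
        a <- info_idx[g]; b <- info_idx[g + 1]
        if (is_prot[a] && is_prot[b]) is_prot[(a + 1):(b - 1)] <- TRUE
      }
    }
    r <- rle(is_prot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    purrr::map_dfr(keep, function(k) {
      s <- starts[k]; e <- ends[k]
      tibble(
        protein_id = pid, start = as.integer(s), end = as.integer(e),
        length = as.integer(e - s + 1L),
        n_supporting = sum(prot_pep$start <= e & prot_pep$end >= s)
      )
    })
  })
}
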