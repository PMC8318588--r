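# Independent oracles and small fixture builders shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Build an uptake tibble from a compact spec: one row per replicate.
make_uptake <- function(protein_id = "P", start, end, sequence, state,
                        exposure_min, uptakes, ...) {
  tibble::tibble(
    protein_id = protein_id, start = start, end = end, sequence = sequence,
    state = state, exposure_min = exposure_min,
    replicate = seq_along(uptakes), uptake_da = uptakes, ...
  )
}

# Random protein sequence over the standard alphabet.
random_protein <- function(n, extra = character()) {
  paste(sample(c(AA20, extra), n, replace = TRUE), collapse = "")
}

# Regex-engine oracle for motif scanning, built directly from the pattern
# text (independent of the package parser and scanner). Overlapping matches
# via a lookahead.
regex_scan_oracle <- function(pattern_text, sequence) {
  elements <- strsplit(pattern_text, "-", fixed = TRUE)[[1]]
  res <- vapply(elements, function(el) {
    if (el %in% c("X", "x")) "[ACDEFGHIKLMNPQRSTVWY]" else el
  }, character(1))
  re <- paste0("(?=", paste(res, collapse = ""), ")")
  hits <- gregexpr(re, sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

# Brute-force oracle for minimal protected segments: enumerate every subset
# of peptide spans, keep those with a non-empty common intersection that are
# maximal (the subset equals the set of all spans touching its intersection),
# and return the unique intersections.
brute_force_segments <- function(starts, ends) {
  n <- length(starts)
  stopifnot(n >= 1, n <= 14)
  subs <- seq_len(2^n - 1)
  M <- vapply(seq_len(n), function(j) {
    bitwAnd(subs, bitwShiftL(1L, j - 1L)) > 0L
  }, logical(length(subs)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(subs))
  sm <- matrix(rep(starts, each = length(subs)), ncol = n)
  em <- matrix(rep(ends, each = length(subs)), ncol = n)
  sm[!M] <- -Inf
  em[!M] <- Inf
  s_vec <- do.call(pmax, as.data.frame(sm))
  e_vec <- do.call(pmin, as.data.frame(em))
  valid <- s_vec <= e_vec
  touch <- vapply(seq_len(n), function(j) {
    starts[j] <= e_vec & ends[j] >= s_vec
  }, logical(length(subs)))
  if (is.null(dim(touch))) touch <- matrix(touch, nrow = length(subs))
  maximal <- valid & rowSums(M != touch) == 0
  out <- unique(data.frame(start = s_vec[maximal], end = e_vec[maximal]))
  out[order(out$start, out$end), , drop = FALSE]
}

# Paper-style degenerate pattern used throughout.
HIM_PATTERN <- "[VIL]-D-X-X-T-G-E-[VIL]-[VILT]"

# Seven synthetic motif instances conforming to HIM_PATTERN (stand-ins for
# the seven carrier proteins of a real proteome scan).
HIM_INSTANCES <- c(
  "VDPETGEIL", "IDESTGELI", "LDAATGEVV", "VDKLTGEIL",
  "IDPNTGEVT", "LDEQTGELL", "VDGITGEIV"
)
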