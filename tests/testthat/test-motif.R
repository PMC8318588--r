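test_that("pattern parsing handles the degenerate-motif grammar", {
  m <- parse_motif(HIM_PATTERN)
  expect_equal(motif_length(m), 9)
  expect_equal(m$positions[[1]], c("I", "L", "V"))
  expect_equal(length(m$positions[[3]]), 20)
  expect_equal(m$positions[[7]], "E")

  expect_equal(motif_length(parse_motif("A")), 1)
  expect_equal(parse_motif("A")$positions[[1]], "A")

  # canonical form round-trips
  expect_equal(format(parse_motif(format(m))), format(m))
  expect_equal(format(parse_motif("x")), "X")

  expect_error(parse_motif("[]"), "Empty bracket")
  expect_error(parse_motif("A--B"), "Empty motif element")
  expect_error(parse_motif("A-"), "column 2")
  expect_error(parse_motif("[AB"), "Unclosed bracket")
  expect_error(parse_motif("A-[D1]"), "Unknown residue '1'")
  expect_error(parse_motif("{DE}-A"), "Exclusion sets")
  expect_error(parse_motif("A-x(2)"), "Repetition")
  expect_error(parse_motif("A-J"), "Unknown motif element 'J' at column 3")
  expect_error(parse_motif(""), "Empty motif pattern")
})

test_that("scanning finds the canonical instances and rejects violations", {
  m <- parse_motif(HIM_PATTERN)
  hit1 <- scan_sequence(m, "GSAVDPETGEILKQ")
  expect_equal(hit1$matched, "VDPETGEIL")
  expect_equal(hit1$start, 4L)
  hit2 <- scan_sequence(m, "MIDESTGELIW")
  expect_equal(hit2$matched, "IDESTGELI")
  expect_equal(nrow(scan_sequence(m, "VDPETGEIP")), 0)

  # windows containing ambiguity codes never match
  expect_equal(nrow(scan_sequence(m, "VDPXTGEIL")), 0)
  expect_equal(nrow(scan_sequence(m, "VDPETGEIB")), 0)

  # sequence shorter than the motif
  expect_equal(nrow(scan_sequence(m, "VDPET")), 0)
})

test_that("every single-residue violation of the pattern is rejected", {
  m <- parse_motif(HIM_PATTERN)
  base <- "VDPETGEIL"
  for (pos in 1:9) {
    allowed <- m$positions[[pos]]
    for (res in AA20) {
      mutant <- base
      substr(mutant, pos, pos) <- res
      n <- nrow(scan_sequence(m, mutant))
      if (res %in% allowed) {
        expect_equal(n, 1, info = sprintf("pos %d res %s", pos, res))
      } else {
        expect_equal(n, 0, info = sprintf("pos %d res %s", pos, res))
      }
    }
  }
})

test_that("scanner agrees with a regex-engine oracle on random sequences", {
  set.seed(3141593)
  patterns <- c(HIM_PATTERN, "T-G-E", "[ST]-X-[DE]-G", "A")
  for (i in 1:250) {
    pat <- sample(patterns, 1)
    seq <- random_protein(sample(20:200, 1))
    got <- scan_sequence(parse_motif(pat), seq)$start
    expect_identical(got, regex_scan_oracle(pat, seq), info = paste("case", i))
  }
})

test_that("proteome scans count carriers and are complete for planted instances", {
  gp <- generate_proteome(
    30, mean_length = 120, planted = c("VDPETGEIL", "IDESTGELI"), seed = 5
  )
  sc <- scan_proteome(HIM_PATTERN, gp$proteins)
  # every planted instance is recovered at its manifest coordinates
  found <- dplyr::semi_join(
    sc$matches, gp$manifest, by = c("protein_id", "start")
  )
  expect_equal(nrow(found), nrow(gp$manifest))
  expect_gte(sc$distinct_proteins, 2)
  # soundness: every reported match satisfies the pattern (regex oracle)
  seqs <- setNames(gp$proteins$sequence, gp$proteins$protein_id)
  for (j in seq_len(nrow(sc$matches))) {
    expect_true(sc$matches$start[j] %in%
      regex_scan_oracle(HIM_PATTERN, seqs[[sc$matches$protein_id[j]]]))
  }

  # empty proteome and too-short proteins
  empty <- tibble::tibble(
    protein_id = character(), description = character(),
    sequence = character(), length = integer()
  )
  sc0 <- scan_proteome(HIM_PATTERN, empty)
  expect_equal(sc0$total_matches, 0)
  short <- tibble::tibble(
    protein_id = "S", description = "", sequence = "VDPET", length = 5L
  )
  expect_equal(scan_proteome(HIM_PATTERN, short)$total_matches, 0)

  dup <- tibble::tibble(
    protein_id = c("A", "A"), description = "",
    sequence = c("AAAA", "CCCC"), length = 4L
  )
  expect_error(scan_proteome(HIM_PATTERN, dup), "Duplicate protein id 'A'")
})

test_that("background composition excludes non-standard residues", {
  prot <- function(...) {
    s <- c(...)
    tibble::tibble(
      protein_id = paste0("P", seq_along(s)), description = "",
      sequence = s, length = nchar(s)
    )
  }
  c1 <- background_composition(prot("AAAA"))
  expect_equal(unname(c1$frequencies["A"]), 1)
  expect_equal(c1$total_residues, 4)
  expect_equal(window_count(c1, 2), 3)

  c2 <- background_composition(prot("AC", "AC"))
  expect_equal(unname(c2$frequencies["A"]), 0.5)
  expect_equal(window_count(c2, 2), 2)

  c3 <- background_composition(prot("AXA"))
  expect_equal(unname(c3$frequencies["A"]), 1)
  expect_equal(c3$total_residues, 2)
  expect_equal(c3$nonstandard_residues, 1)
  expect_equal(sum(c3$frequencies), 1, tolerance = 1e-9)
})

test_that("analytic expectation matches closed forms", {
  uni <- aa_composition(
    setNames(rep(0.05, 20), AA20),
    protein_lengths = 1e6 + 8
  )
  # wildcard motif: expectation equals the window count
  ew <- expected_matches("X", aa_composition(
    setNames(rep(0.05, 20), AA20), protein_lengths = c(10, 20)
  ))
  expect_equal(ew$expected, 30)
  expect_equal(ew$p_window, 1)

  # hand-derivable product for the nine-position pattern at 1e6 windows:
  # (3*0.05)^2 * (4*0.05) * 0.05^4 * 1e6
  e9 <- expected_matches(HIM_PATTERN, uni)
  expect_equal(e9$window_count, 1e6)
  expect_equal(e9$expected, 0.028125, tolerance = 1e-12)

  # empty proteome
  e0 <- expected_matches("A", aa_composition(
    setNames(rep(0.05, 20), AA20), protein_lengths = integer()
  ))
  expect_equal(e0$expected, 0)
})

test_that("Monte Carlo estimate brackets the analytic expectation", {
  # degenerate single-residue motif with probability 1
  only_a <- aa_composition(
    setNames(c(1, rep(0, 19)), c("A", setdiff(AA20, "A"))),
    protein_lengths = 100
  )
  mc <- empirical_expected_matches("A", only_a, n_proteomes = 5, seed = 1)
  expect_equal(mc$estimate, 100)

  # zero-probability position
  mc0 <- empirical_expected_matches("C", only_a, n_proteomes = 5, seed = 1)
  expect_equal(mc0$estimate, 0)

  # stochastic agreement within 3 SE for a moderate-probability motif
  uni <- aa_composition(setNames(rep(0.05, 20), AA20), protein_lengths = 5000)
  ana <- expected_matches("T-G-E", uni)$expected
  mc2 <- empirical_expected_matches("T-G-E", uni, n_proteomes = 200, seed = 42)
  expect_lt(abs(mc2$estimate - ana), 3 * mc2$se)
})

test_that("expectation and match sets grow monotonically with allowed sets", {
  comp <- background_composition(tibble::tibble(
    protein_id = "P", description = "",
    sequence = {
      set.seed(9); random_protein(3000)
    },
    length = 3000L
  ))
  narrow <- parse_motif("[VI]-D-[ST]")
  wide <- parse_motif("[VIL]-D-[STA]")
  expect_gte(
    expected_matches(wide, comp)$expected,
    expected_matches(narrow, comp)$expected
  )
  s <- tibble::tibble(
    protein_id = "P", description = "",
    sequence = {
      set.seed(9); random_protein(3000)
    }, length = 3000L
  )
  hits_narrow <- scan_proteome(narrow, s)$matches$start
  hits_wide <- scan_proteome(wide, s)$matches$start
  expect_true(all(hits_narrow %in% hits_wide))
})

test_that("motif induction generalises aligned instances", {
  m <- induce_motif(c("VDPETGEIL", "IDESTGELI"), min_column_frequency = 0.5)
  expect_equal(
    purrr::map(m$positions, identity),
    list(
      c("I", "V"), "D", c("E", "P"), c("E", "S"), "T", "G", "E",
      c("I", "L"), c("I", "L")
    )
  )
  # the induced motif matches both inputs
  expect_equal(nrow(scan_sequence(m, "VDPETGEIL")), 1)
  expect_equal(nrow(scan_sequence(m, "IDESTGELI")), 1)

  # identical inputs -> exact-sequence motif
  m2 <- induce_motif(c("TGE", "TGE"))
  expect_equal(format(m2), "T-G-E")

  # a hyper-variable column becomes a wildcard
  seqs <- paste0(AA20, "D")
  m3 <- induce_motif(seqs, min_column_frequency = 0.01, max_set_size = 4)
  expect_equal(length(m3$positions[[1]]), 20)
  expect_equal(m3$positions[[2]], "D")

  expect_error(induce_motif(c("AB", "A")), "equal length")
  expect_error(induce_motif("A"), "length")
})

test_that("induced motifs match all inputs when the threshold permits", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    seqs <- replicate(n, random_protein(7))
    m <- induce_motif(seqs, min_column_frequency = 1 / n)
    for (s in seqs) {
      expect_equal(nrow(scan_sequence(m, s)), 1, info = paste("case", i))
    }
  }
})
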