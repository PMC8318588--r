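# Differential rows for one peptide across exposure times, in tibble form.
diff_rows <- function(start, end, times, deltas, envelopes = 0.2,
                      protein_id = "P") {
  tibble::tibble(
    protein_id = protein_id, start = as.integer(start), end = as.integer(end),
    sequence = strrep("A", end - start + 1), exposure_min = times,
    max_uptake = end - start, delta = deltas,
    delta_relative = deltas / (end - start),
    envelope = envelopes,
    significant_protection = deltas < 0 & abs(deltas) > envelopes,
    significant_exposure = deltas > envelopes
  )
}

test_that("protection calling enforces the time-course policy", {
  times <- c(0.5, 2, 5, 10)
  # significant at 5 and 10 min only -> protected under defaults
  d <- diff_rows(10, 20, times, c(-0.1, -0.15, -0.5, -0.8))
  expect_equal(nrow(call_protected_peptides(d)), 1)

  # significant at 0.5 min only -> not protected
  d2 <- diff_rows(10, 20, times, c(-0.5, -0.1, -0.1, -0.1))
  expect_equal(nrow(call_protected_peptides(d2)), 0)

  # significant at all times -> protected under any policy
  d3 <- diff_rows(10, 20, times, c(-0.5, -0.6, -0.8, -1.2))
  expect_equal(nrow(call_protected_peptides(
    d3, min_significant_times = 4, require_longest_time = TRUE,
    require_nondecreasing = TRUE
  )), 1)

  # significant twice but not at the longest exposure
  d4 <- diff_rows(10, 20, times, c(-0.5, -0.6, -0.5, -0.1))
  expect_equal(nrow(call_protected_peptides(d4)), 0)
  expect_equal(nrow(call_protected_peptides(d4, require_longest_time = FALSE)), 1)

  # non-monotone magnitude beyond one envelope of slack
  d5 <- diff_rows(10, 20, times, c(-0.9, -0.3, -0.5, -0.9))
  expect_equal(nrow(call_protected_peptides(d5, require_nondecreasing = TRUE)), 0)
  expect_equal(nrow(call_protected_peptides(d5)), 1)
})

test_that("minimal segments reproduce the overlapping-peptide fixtures", {
  # two overlapping peptides -> their span intersection (7 residues)
  p <- tibble::tibble(
    protein_id = "rpoB", start = c(296L, 302L), end = c(308L, 312L)
  )
  seg <- minimal_protected_segments(p)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end, seg$length), c(302, 308, 7))
  expect_equal(seg$n_supporting, 2)

  # single peptide -> itself
  seg1 <- minimal_protected_segments(
    tibble::tibble(protein_id = "P", start = 300L, end = 320L)
  )
  expect_equal(c(seg1$start, seg1$end), c(300, 320))

  # two overlap groups -> derived by the exhaustive subset oracle
  p3 <- tibble::tibble(
    protein_id = "P", start = c(1L, 8L, 50L), end = c(10L, 20L, 60L)
  )
  seg3 <- minimal_protected_segments(p3)
  oracle <- brute_force_segments(p3$start, p3$end)
  expect_equal(seg3$start, oracle$start)
  expect_equal(seg3$end, oracle$end)
  expect_equal(seg3$start, c(8L, 50L))
  expect_equal(seg3$end, c(10L, 60L))

  # empty input -> empty result
  expect_equal(nrow(minimal_protected_segments(p[0, ])), 0)
})

test_that("every segment is contained in each of its supporting peptides", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    s <- sample(1:60, n, replace = TRUE)
    p <- tibble::tibble(
      protein_id = "P", start = as.integer(s),
      end = as.integer(s + sample(3:15, n, replace = TRUE))
    )
    seg <- minimal_protected_segments(p)
    for (j in seq_len(nrow(seg))) {
      sup <- seg$supporting[[j]]
      expect_true(all(sup$start <= seg$start[j]))
      expect_true(all(sup$end >= seg$end[j]))
    }
  }
})

test_that("segment caller agrees with the brute-force subset oracle", {
  set.seed(4711)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    s <- sample(1:80, n, replace = TRUE)
    starts <- as.integer(s)
    ends <- as.integer(s + sample(0:20, n, replace = TRUE))
    spans <- unique(data.frame(start = starts, end = ends))
    seg <- minimal_protected_segments(
      tibble::tibble(protein_id = "P", start = spans$start, end = spans$end)
    )
    oracle <- brute_force_segments(spans$start, spans$end)
    expect_equal(seg$start, oracle$start, info = paste("case", i))
    expect_equal(seg$end, oracle$end, info = paste("case", i))
  }
})

test_that("segments carry per-time mean deltas of their supporting peptides", {
  times <- c(2, 10)
  d <- dplyr::bind_rows(
    diff_rows(296, 308, times, c(-0.5, -1.0)),
    diff_rows(302, 312, times, c(-0.3, -0.6))
  )
  prot <- call_protected_peptides(d, min_significant_times = 2)
  seg <- minimal_protected_segments(prot, d)
  expect_equal(nrow(seg), 1)
  ptd <- seg$per_time_delta[[1]]
  expect_equal(ptd$delta[ptd$exposure_min == 10], mean(c(-1.0, -0.6)))
})

test_that("residue-level regions localise protection and exonerate flanks", {
  # protein with no prolines near the site; three peptides: one clean flank,
  # one clipping the region edge, one containing the region
  protein <- tibble::tibble(
    protein_id = "P", description = "",
    sequence = strrep("A", 60), length = 60L
  )
  times <- c(2, 10)
  d <- dplyr::bind_rows(
    diff_rows(5, 20, times, c(0.01, -0.02), envelopes = 0.1),    # clean
    diff_rows(15, 30, times, c(-0.3, -0.55), envelopes = 0.1),   # clips 28-32
    diff_rows(25, 40, times, c(-1.4, -2.6), envelopes = 0.1)     # contains
  )
  prot <- call_protected_peptides(d)
  reg <- protected_regions(d, prot, protein)
  expect_equal(nrow(reg), 1)
  # the clean peptide exonerates 6-20; the region must live within 21-40
  expect_gte(reg$start, 21)
  expect_lte(reg$end, 40)
  # and must include the deep block shared by both protected peptides
  expect_lte(reg$start, 28)
  expect_gte(reg$end, 30)

  # no protected peptides -> no regions
  reg0 <- protected_regions(d, prot[0, ], protein)
  expect_equal(nrow(reg0), 0)
})
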