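test_that("peptide maps tile the protein with the requested geometry", {
  prot <- {
    set.seed(1); random_protein(100)
  }
  # the documented reference geometry: step 5, mean length 12 on a 100-mer
  pep <- generate_peptide_map(prot, mean_length = 12, length_sd = 0, step = 5, seed = 1)
  cs <- coverage_redundancy(
    pep, tibble::tibble(protein_id = "sim", length = 100L)
  )
  expect_equal(cs$coverage_percent, 100)
  expect_equal(cs$redundancy, 2.4, tolerance = 0.1)

  # step = protein length -> a single peptide
  pep1 <- generate_peptide_map(prot, mean_length = 100, length_sd = 0,
    step = 100, max_length = 100, seed = 1)
  expect_equal(nrow(pep1), 1)
  expect_equal(coverage_redundancy(
    pep1, tibble::tibble(protein_id = "sim", length = 100L)
  )$redundancy, 1)

  # seeded reproducibility
  expect_identical(
    generate_peptide_map(prot, seed = 7),
    generate_peptide_map(prot, seed = 7)
  )
  # peptide sequences really are protein slices with the right amide counts
  pepx <- generate_peptide_map(prot, seed = 3)
  expect_equal(pepx$sequence, substring(prot, pepx$start, pepx$end))
  expect_equal(pepx$max_uptake, max_exchangeable_amides(pepx$sequence))

  expect_error(generate_peptide_map("AAA", min_length = 6), "shorter")
})

test_that("noiseless uptake kinetics follow the exchange model", {
  # single amide at k = ln 2 per minute, one minute: half exchanged
  cfg <- hdx_sim_config(
    protein = "AG", times = 1, replicates = 1,
    rates = c(0, log(2)), protected_region = NULL,
    deuterium_fraction = 1, back_exchange = 1, noise_sd = 0,
    peptide_map = list(mean_length = 2, length_sd = 0, step = 2, min_length = 2),
    seed = 1
  )
  sim <- simulate_uptake(cfg)
  expect_equal(unique(round(sim$uptake$uptake_da, 10)), 0.5)

  # no protection factor -> apo and complex identical without noise
  cfg2 <- hdx_sim_config(
    protein_length = 60, protection_factor = 1, noise_sd = 0,
    protected_region = c(21, 27), seed = 2
  )
  sim2 <- simulate_uptake(cfg2)
  wide <- tidyr::pivot_wider(
    sim2$uptake, names_from = "state", values_from = "uptake_da"
  )
  expect_equal(wide$apo, wide$complex)

  # infinite-protection limit: protected amides contribute nothing at any time
  cfg3 <- hdx_sim_config(
    protein_length = 60, protection_factor = 1e12, noise_sd = 0,
    protected_region = c(21, 27), seed = 3,
    rates = rep(50, 60) # fast apo exchange saturates by the longest time
  )
  sim3 <- simulate_uptake(cfg3)
  s3 <- summarize_uptake(sim3$uptake)
  d3 <- differential_uptake(s3, "apo", "complex")
  last <- dplyr::filter(d3, .data$exposure_min == 10)
  for (j in seq_len(nrow(last))) {
    n_prot <- length(intersect(
      (last$start[j] + 1):last$end[j], 21:27
    ))
    expect_equal(
      last$delta[j], -0.7 * (135 / 165) * n_prot,
      tolerance = 1e-6
    )
  }
})

test_that("noiseless uptake is non-decreasing in time and properly bounded", {
  cfg <- hdx_sim_config(protein_length = 80, noise_sd = 0, seed = 5)
  sim <- simulate_uptake(cfg)
  bound <- 0.7 * (135 / 165)
  by_pep <- dplyr::group_by(sim$uptake, .data$start, .data$end, .data$state)
  ordered <- dplyr::arrange(by_pep, .data$exposure_min, .by_group = TRUE)
  chk <- dplyr::summarise(
    ordered,
    monotone = all(diff(.data$uptake_da) >= -1e-12),
    mu = max_exchangeable_amides(.data$sequence[1]),
    below = all(.data$uptake_da <= bound * max_exchangeable_amides(.data$sequence[1]) + 1e-9),
    .groups = "drop"
  )
  expect_true(all(chk$monotone))
  expect_true(all(chk$below))
})

test_that("simulations are bit-reproducible under a fixed seed", {
  a <- simulate_uptake(hdx_sim_config(seed = 99))
  b <- simulate_uptake(hdx_sim_config(seed = 99))
  expect_identical(a$uptake, b$uptake)
  expect_identical(a$protein, b$protein)

  g1 <- generate_proteome(10, planted = "VDPETGEIL", seed = 12)
  g2 <- generate_proteome(10, planted = "VDPETGEIL", seed = 12)
  expect_identical(g1, g2)

  o1 <- generate_ortholog_set("MKTAYIAK", 5, seed = 3)
  o2 <- generate_ortholog_set("MKTAYIAK", 5, seed = 3)
  expect_identical(o1, o2)
})

test_that("proteome planting places instances at manifest coordinates", {
  gp <- generate_proteome(
    20, mean_length = 150, planted = rep("VDPETGEIL", 3), seed = 8
  )
  expect_equal(nrow(gp$manifest), 3)
  for (j in 1:3) {
    prot <- gp$proteins$sequence[gp$proteins$protein_id == gp$manifest$protein_id[j]]
    expect_equal(
      substr(prot, gp$manifest$start[j], gp$manifest$end[j]),
      "VDPETGEIL"
    )
  }
  # distinct proteins by default
  expect_equal(length(unique(gp$manifest$protein_id)), 3)

  # refuses impossible planting
  expect_error(
    generate_proteome(2, mean_length = 50, min_length = 40,
      planted = rep("VDPETGEIL", 3), seed = 1),
    "Not enough proteins"
  )
})

test_that("unplanted match counts are consistent with the analytic null", {
  # moderately probable 3-position pattern so counts are informative
  pat <- "T-G-E"
  counts <- sapply(1:60, function(s) {
    gp <- generate_proteome(10, mean_length = 300, seed = 1000 + s)
    scan_proteome(pat, gp$proteins)$total_matches
  })
  gp1 <- generate_proteome(10, mean_length = 300, seed = 1001)
  ana <- expected_matches(pat, background_composition(gp1$proteins))$expected
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - ana), 4 * se + 0.1 * ana)
})

test_that("ortholog sets honour conserved columns and substitution rates", {
  ref <- strrep("ADEKLYS", 4)
  o0 <- generate_ortholog_set(ref, 10, substitution_prob = 0, seed = 4)
  expect_true(all(o0$aligned == ref))

  oc <- generate_ortholog_set(
    ref, 40, substitution_prob = 0.5, conserved_columns = c(3, 10), seed = 4
  )
  prof <- column_profile(oc, columns = c(3, 10), small_sample_correction = FALSE)
  expect_equal(unique(prof$ic), log2(20))
  expect_equal(unique(prof$frequency), 1)

  # substituted columns carry strictly less information on average
  prof_all <- column_profile(oc, small_sample_correction = FALSE)
  per_col <- dplyr::distinct(prof_all, .data$column, .data$ic)
  sub_cols <- dplyr::filter(per_col, !.data$column %in% c(3, 10))
  expect_lt(mean(sub_cols$ic), log2(20))
})
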