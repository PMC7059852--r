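test_that("recovery tables validate their fractions", {
  expect_error(gene_recovery_table(c("A", "A"), 10, 0.5, 0.3, 0.2),
               "unique")
  expect_error(gene_recovery_table("A", 10, 0.5, 0.3, 0.1),
               "sum to 1")
  expect_error(gene_recovery_table("A", 10, 1.2, -0.1, -0.1),
               "\\[0, 1\\]")
  t <- gene_recovery_table(c("A", "B"), 100, c(0.9, 0), c(0.05, 0),
                           c(0.05, 1))
  expect_s3_class(t, "gene_recovery")
})

test_that("reconstructed fraction adds complete and fragmented genes", {
  t <- gene_recovery_table(c("A", "B", "C"), 100,
                           complete = c(0.9, 0, 0.59),
                           fragmented = c(0.05, 0, 0),
                           missing = c(0.05, 1, 0.41))
  expect_equal(reconstructed_fraction(t, "A"), 0.95)
  expect_equal(reconstructed_fraction(t, "B"), 0)
  expect_equal(reconstructed_fraction(t, "C"), 0.59)
  expect_error(reconstructed_fraction(t, "D"), "not in recovery")
})

test_that("per-sample recovery averages only over detected species", {
  t <- gene_recovery_table(c("A", "B"), 100, c(0.2, 0.8), c(0, 0),
                           c(0.8, 0.2))
  expect_equal(mean_recovery(t, "A"), 0.2)
  expect_equal(mean_recovery(t, c("A", "B")), 0.5)
  expect_error(mean_recovery(t, character()), "no detected")
  expect_error(mean_recovery(t, c("A", "Z")), "not in recovery")
  # mean lies between the per-species extremes
  set.seed(6)
  for (i in 1:10) {
    fc <- runif(4); ff <- runif(4) * (1 - fc)
    tt <- gene_recovery_table(paste0("s", 1:4), 50, fc, ff,
                              1 - fc - ff)
    m <- mean_recovery(tt, paste0("s", 1:4))
    r <- reconstructed_fraction(tt, paste0("s", 1:4))
    expect_gte(m, min(r)); expect_lte(m, max(r))
  }
})

test_that("simulated recovery obeys the coverage model limits", {
  one <- community_spec(c("Solus unus" = 100))
  gs <- c("Solus unus" = 1e6)
  none <- simulate_recovery(one, depth = 0, genome_sizes = gs, seed = 1)
  expect_equal(none$missing, 1)
  # coverage 50: (1 - e^-50)^bins leaves >= 99% of genes complete
  depth_c50 <- 50 * 1e6 / 125
  deep <- simulate_recovery(one, depth = depth_c50, genome_sizes = gs,
                            n_genes = 500, seed = 2)
  expect_gte(deep$complete, 0.99)
  expect_error(simulate_recovery(mock_spec(), 1e6,
                                 genome_sizes = gs), "genome size")
})

test_that("the Lander-Waterman kernel matches uniform read placement", {
  # Monte-Carlo oracle: drop n reads uniformly on a toy genome and
  # measure the fraction of covered bases; compare to 1 - exp(-c).
  set.seed(44)
  G <- 2e5; L <- 125; cov_target <- 1
  n <- round(cov_target * G / L)
  covered <- logical(G)
  starts <- sample.int(G - L + 1, n, replace = TRUE)
  for (s in starts) covered[s:(s + L - 1)] <- TRUE
  expect_equal(mean(covered), 1 - exp(-cov_target), tolerance = 0.03)
})

test_that("recovery is monotone in depth under coupled seeds and
           ordered by abundance tier", {
  spec <- mock_spec()
  gs <- mock_genome_sizes()
  tier18 <- names(spec$declared)[spec$declared == 18]
  tier1.8 <- names(spec$declared)[spec$declared == 1.8]
  wins <- 0L
  for (s in 1:20) {
    lo <- simulate_recovery(spec, 1e6, gs, seed = s)
    hi <- simulate_recovery(spec, 5e6, gs, seed = s)
    expect_true(all(hi$complete + hi$fragmented >=
                      lo$complete + lo$fragmented))
    # fully reconstructed genes separate the 18% and 1.8% tiers
    if (mean(lo$complete[lo$species %in% tier18]) >
          mean(lo$complete[lo$species %in% tier1.8]))
      wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("completeness tables round-trip through TSV", {
  t <- gene_recovery_table(c("A", "B"), c(120, 80), c(0.9, 0.25),
                           c(0.05, 0.25), c(0.05, 0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recovery_tsv(t, f)
  expect_equal(read_recovery_tsv(f), t)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("species\tn_genes\tcomplete", bad)
  expect_error(read_recovery_tsv(bad), "missing column")
})
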