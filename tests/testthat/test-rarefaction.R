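test_that("edge depths behave as identities", {
  p <- toy_profile(c(A = 2, B = 1), unclassified = 1)
  full <- subsample_profile(p, total_reads(p), seed = 1)
  expect_equal(full$counts, p$counts)
  expect_equal(full$unclassified, p$unclassified)
  empty <- subsample_profile(p, 0, seed = 1)
  expect_equal(total_reads(empty), 0)
  expect_error(subsample_profile(p, 5, seed = 1), "exceeds")
})

test_that("the subsampler matches the closed-form hypergeometric
           law on tiny instances", {
  # toy {A:2, B:1}, depth 2: P(A=2) = C(2,2)C(1,0)/C(3,2) = 1/3
  p <- toy_profile(c(A = 2, B = 1))
  n <- 3000
  seeds <- 1:n
  hits <- vapply(seeds, function(s) {
    d <- subsample_profile(p, 2, seed = s)
    identical(unname(d$counts["A"]), 2)
  }, logical(1))
  expect_equal(mean(hits), 1 / 3,
               tolerance = 3 * sqrt((1 / 3) * (2 / 3) / n) / (1 / 3))

  # exhaustive-enumeration oracle on totals <= 8
  counts <- c(A = 3, B = 2, C = 3)
  depth <- 4
  comps <- all_compositions(counts, depth)
  probs <- apply(comps, 1, mvhyper_pmf, counts = counts, depth = depth)
  expect_equal(sum(probs), 1)
  n <- 5000
  draws <- t(vapply(seq_len(n), function(s) {
    d <- subsample_profile(taxon_profile(counts), depth, seed = s)
    v <- setNames(numeric(3), names(counts))
    v[names(d$counts)] <- d$counts
    v
  }, numeric(3)))
  key <- apply(comps, 1, paste, collapse = ",")
  emp <- table(factor(apply(draws, 1, paste, collapse = ","),
                      levels = key)) / n
  for (i in seq_along(key)) {
    se <- sqrt(probs[i] * (1 - probs[i]) / n)
    expect_lt(abs(emp[[i]] - probs[i]), 4 * se + 1e-12)
  }
})

test_that("subsampled counts are unbiased", {
  p <- toy_profile(c(A = 500, B = 300, C = 200))
  depth <- 100
  n <- 1000
  draws <- t(vapply(seq_len(n), function(s) {
    d <- subsample_profile(p, depth, seed = 10000 + s)
    v <- setNames(numeric(3), names(p$counts))
    v[names(d$counts)] <- d$counts
    v
  }, numeric(3)))
  expected <- depth * p$counts / total_reads(p)
  # hypergeometric variance with finite-population correction
  N <- total_reads(p)
  v <- depth * (p$counts / N) * (1 - p$counts / N) *
    (N - depth) / (N - 1)
  se <- sqrt(v / n)
  expect_true(all(abs(colMeans(draws) - expected) < 3 * se))
})

test_that("multinomial draws allow sampling a declared composition", {
  p <- toy_profile(c(A = 60, B = 30, C = 10))
  d <- subsample_profile(p, 1000, seed = 4, method = "multinomial")
  expect_equal(total_reads(d), 1000)
  expect_error(subsample_profile(taxon_profile(), 10, seed = 1,
                                 method = "multinomial"), "empty")
})

test_that("depth series summarise replicates with the requested
           interval", {
  p <- toy_profile(c(A = 5000, B = 3000, C = 2000))
  ds <- depth_series(p, depths = c(100, 1000),
                     metric = function(x) 7, n_reps = 5,
                     seed = 1, metric_name = "const")
  expect_equal(ds$summary$mean, c(7, 7))
  expect_equal(ds$summary$ci_low, c(7, 7))
  expect_equal(ds$summary$ci_high, c(7, 7))
  expect_equal(nrow(ds$values), 10)

  # t-interval oracle at 99%
  ds2 <- depth_series(p, depths = 500, metric = function(x)
    as.double(x$counts["A"]), n_reps = 5, ci_level = 0.99, seed = 2,
    metric_name = "countA")
  v <- ds2$values$value
  half <- qt(0.995, 4) * sd(v) / sqrt(5)
  expect_equal(ds2$summary$ci_low, mean(v) - half)
  expect_equal(ds2$summary$ci_high, mean(v) + half)
  expect_true(ds2$summary$ci_low <= ds2$summary$mean &
                ds2$summary$mean <= ds2$summary$ci_high)

  # percentile intervals stay within the replicate range
  ds3 <- depth_series(p, depths = 500, metric = function(x)
    as.double(x$counts["A"]), n_reps = 5, ci_level = 0.95, seed = 2,
    ci_method = "percentile", metric_name = "countA")
  expect_gte(ds3$summary$ci_low, min(ds3$values$value))
  expect_lte(ds3$summary$ci_high, max(ds3$values$value))
})

test_that("the replicate grid is reproducible from one master seed
           and skips infeasible depths", {
  p <- toy_profile(c(A = 5000, B = 3000, C = 2000))
  m <- function(x) observed_taxa(x, min_reads = 0, min_frac = 0)
  a <- depth_series(p, depths = c(100, 1000), metric = m, n_reps = 4,
                    seed = 99, metric_name = "taxa")
  b <- depth_series(p, depths = c(100, 1000), metric = m, n_reps = 4,
                    seed = 99, metric_name = "taxa")
  expect_identical(a$values, b$values)
  expect_warning(
    ds <- depth_series(p, depths = c(100, 1e6), metric = m,
                       n_reps = 3, seed = 1, metric_name = "taxa"),
    "skipping")
  expect_equal(unique(ds$values$depth), 100)
})

test_that("metric failures carry replicate context", {
  p <- toy_profile()
  expect_error(
    depth_series(p, depths = 10, n_reps = 2, seed = 1,
                 metric = function(x) stop("boom"),
                 metric_name = "bad"),
    "depth 10, replicate 1")
})

test_that("the default evaluation grid is the standard ladder", {
  f <- formals(depth_series)
  expect_equal(eval(f$depths), c(1e4, 2.5e4, 5e4, 1e5, 2.5e5, 5e5, 1e6))
  expect_equal(f$n_reps, 5)
  expect_equal(f$ci_level, 0.99)
})
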