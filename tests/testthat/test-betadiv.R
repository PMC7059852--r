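test_that("Bray-Curtis matches the hand-evaluated formula", {
  p1 <- toy_profile(c(A = 60, B = 40), id = "s1")
  p2 <- toy_profile(c(A = 20, B = 40, C = 40), id = "s2")
  d <- bray_curtis(list(p1, p2), min_reads = 0, min_frac = 0)
  expect_equal(as.numeric(d), 1 - 2 * (20 + 40 + 0) / 200)
  same <- bray_curtis(list(p1, toy_profile(c(A = 6, B = 4), id = "s3")),
                      min_reads = 0, min_frac = 0)
  expect_equal(as.numeric(same), 0)
  disjoint <- bray_curtis(list(p1, toy_profile(c(X = 5, Y = 5),
                                               id = "s4")),
                          min_reads = 0, min_frac = 0)
  expect_equal(as.numeric(disjoint), 1)
  expect_error(
    bray_curtis(list(p1, taxon_profile(unclassified = 10,
                                       sample_id = "bad"))),
    "bad")
})

test_that("principal coordinates recover planted geometry", {
  set.seed(3)
  pts <- matrix(rnorm(20), 10, 2)
  rownames(pts) <- paste0("s", 1:10)
  ord <- ordinate(dist(pts), method = "pcoa", dims = 2)
  expect_equal(as.matrix(dist(ord$coordinates)), as.matrix(dist(pts)),
               tolerance = 1e-8)
  # three equidistant samples embed as an equilateral triangle
  m <- matrix(0.5, 3, 3); diag(m) <- 0
  dimnames(m) <- list(letters[1:3], letters[1:3])
  tri <- ordinate(m, method = "pcoa", dims = 2)
  expect_equal(var(as.numeric(dist(tri$coordinates))), 0,
               tolerance = 1e-12)
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ordinate(bad, "pcoa", dims = 1), "symmetric")
  expect_error(ordinate(dist(pts), "pcoa", dims = 10), "smaller")
})

test_that("NMDS reaches near-zero stress on embeddable
           configurations", {
  set.seed(8)
  pts <- matrix(rnorm(16), 8, 2)
  rownames(pts) <- paste0("s", 1:8)
  suppressWarnings(
    ord <- ordinate(dist(pts), method = "nmds", dims = 2, seed = 5))
  expect_lt(ord$stress, 0.01)
  expect_equal(dim(ord$coordinates), c(8, 2))
})

test_that("Procrustes correlation is invariant to similarity
           transforms and matches a grid-search oracle", {
  set.seed(21)
  X <- as_ordination(matrix(rnorm(20), 10, 2))
  theta <- 37 * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- as_ordination(3 * X$coordinates %*% R + 5,
                     ids = rownames(X$coordinates))
  fit <- procrustes_fit(X, Y)
  expect_equal(fit$correlation, 1, tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-10)
  expect_equal(procrustes_fit(X, X)$correlation, 1)
  # reflections are allowed
  Yr <- as_ordination(X$coordinates %*% diag(c(1, -1)),
                      ids = rownames(X$coordinates))
  expect_equal(procrustes_fit(X, Yr)$correlation, 1,
               tolerance = 1e-10)
  # independent angle-scan oracle on small noisy configurations
  for (s in 1:3) {
    set.seed(100 + s)
    A <- matrix(rnorm(8), 4, 2)
    B <- matrix(rnorm(8), 4, 2)
    ids <- paste0("s", 1:4)
    fit <- procrustes_fit(as_ordination(A, ids), as_ordination(B, ids))
    expect_equal(fit$correlation, procrustes_oracle_2d(A, B),
                 tolerance = 1e-4)
  }
})

test_that("Procrustes alignment is by sample id, not row order", {
  set.seed(12)
  A <- matrix(rnorm(20), 10, 2)
  ids <- paste0("s", 1:10)
  X <- as_ordination(A, ids)
  perm <- sample(10)
  Y <- as_ordination(A[perm, ], ids[perm])
  expect_equal(procrustes_fit(X, Y)$correlation, 1, tolerance = 1e-10)
  Z <- as_ordination(A, paste0("other", 1:10))
  expect_error(procrustes_fit(X, Z), "different samples")
})

test_that("the permutation test hits its floor on self-comparison and
           is calibrated under the null", {
  set.seed(33)
  X <- as_ordination(matrix(rnorm(20), 10, 2))
  pt <- protest(X, X, n_perm = 999, seed = 1)
  expect_equal(pt$p_value, 0.001)
  expect_equal(pt$correlation, 1)
  # null calibration: independent configurations rarely score small p
  ps <- vapply(1:50, function(s) {
    set.seed(500 + s)
    A <- as_ordination(matrix(rnorm(16), 8, 2))
    B <- as_ordination(matrix(rnorm(16), 8, 2),
                       ids = rownames(A$coordinates))
    protest(A, B, n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_true(all(ps > 0 & ps <= 1))
  expect_gte(mean(ps > 0.05), 0.9)
})
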