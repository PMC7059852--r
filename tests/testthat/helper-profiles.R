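# Shared builders and independent oracles used across the test files.

toy_profile <- function(counts = c(A = 60, B = 30, C = 10),
                        unclassified = 0, id = "toy") {
  taxon_profile(counts, unclassified = unclassified, sample_id = id)
}

random_profile <- function(n_species = 8, depth = 1e4) {
  w <- rexp(n_species)
  counts <- rmultinom(1, depth, w / sum(w))[, 1]
  names(counts) <- sprintf("Testus sp%02d", seq_len(n_species))
  taxon_profile(counts[counts > 0], sample_id = "rand")
}

# Exact multivariate hypergeometric pmf: the closed-form oracle for
# the subsampler. x and counts are parallel integer vectors.
mvhyper_pmf <- function(x, counts, depth) {
  prod(choose(counts, x)) / choose(sum(counts), depth)
}

# All compositions of `depth` over bins capped at `counts`.
all_compositions <- function(counts, depth) {
  grids <- lapply(counts, function(m) 0:m)
  g <- do.call(expand.grid, grids)
  g[rowSums(g) == depth, , drop = FALSE]
}

# Independent Shannon oracle: direct summation at high precision.
shannon_oracle <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

# Brute-force 2-D Procrustes correlation: scan rotation angle (both
# reflections) for centred, unit-normalised configurations.
procrustes_oracle_2d <- function(X, Y, n_angles = 20000) {
  norm_cfg <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    M / sqrt(sum(M^2))
  }
  X <- norm_cfg(X); Y <- norm_cfg(Y)
  best <- -Inf
  for (refl in list(diag(2), diag(c(1, -1)))) {
    Yr <- Y %*% refl
    th <- seq(0, 2 * pi, length.out = n_angles)
    # trace(X' Y R) maximised over rotations R(theta)
    for (t in th) {
      R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
      best <- max(best, sum(X * (Yr %*% R)))
    }
  }
  best
}

# An ordination object from raw coordinates (for Procrustes tests).
as_ordination <- function(coords, ids = NULL) {
  if (!is.null(ids)) rownames(coords) <- ids
  if (is.null(rownames(coords)))
    rownames(coords) <- paste0("s", seq_len(nrow(coords)))
  structure(list(coordinates = coords, method = "pcoa",
                 stress = NA_real_),
            class = "ordination")
}
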