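#' Pairwise dissimilarity between sample profiles
#'
#' Builds the sample-by-species relative-abundance matrix (species
#' passing the detection rule, renormalised per sample) and computes
#' pairwise dissimilarities: Bray-Curtis
#' `BC(a, b) = 1 - 2 sum(min(a_i, b_i)) / sum(a_i + b_i)` by default,
#' or Euclidean distance on Hellinger-transformed abundances.
#'
#' @param profiles list of [taxon_profile()]s (>= 2), named or carrying
#'   their own `sample_id`s.
#' @inheritParams detect_species
#' @param measure `"bray"` or `"hellinger"`. Set `min_reads = 0,
#'   min_frac = 0` to skip the detection filter.
#' @return A `dist` object labelled by sample id; Bray-Curtis values
#'   lie in `[0, 1]`.
#' @examples
#' d <- study_design(c("S1", "S2", "S3"), richness = c(5, 10, 15),
#'                   depth = 1e5)
#' profs <- simulate_study(d, seed = 1)
#' bray_curtis(profs)
#' @export
bray_curtis <- function(profiles, min_reads = 10, min_frac = 0.1,
                        measure = c("bray", "hellinger")) {
  measure <- match.arg(measure)
  stopifnot(is.list(profiles), length(profiles) >= 2)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  abunds <- lapply(profiles, function(p) {
    if (sum(p$counts) == 0)
      stop("sample '", p$sample_id, "' has no classified reads",
           call. = FALSE)
    sp <- detect_species(p, min_reads = min_reads, min_frac = min_frac)
    if (!length(sp))
      stop("sample '", p$sample_id,
           "' has no species passing the detection rule", call. = FALSE)
    x <- p$counts[sp]
    100 * x / sum(x)
  })
  species <- sort(unique(unlist(lapply(abunds, names))))
  mat <- t(vapply(abunds, function(a) {
    v <- numeric(length(species))
    v[match(names(a), species)] <- a
    v
  }, numeric(length(species))))
  dimnames(mat) <- list(ids, species)
  if (measure == "bray")
    vegan::vegdist(mat, method = "bray")
  else
    stats::dist(vegan::decostand(mat, method = "hellinger"))
}

#' Ordinate a dissimilarity matrix
#'
#' Embeds samples in `dims` dimensions. `method = "pcoa"` (principal
#' coordinates: eigendecomposition of the double-centred squared
#' dissimilarities) is deterministic and the default; `"nmds"`
#' (non-metric multidimensional scaling, Kruskal stress-1 with monotone
#' regression and seeded multi-start) matches common practice for
#' community data but is iterative.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param method `"pcoa"` or `"nmds"`.
#' @param dims number of dimensions (< number of samples).
#' @param seed integer seed for the NMDS random starts.
#' @param try_starts number of NMDS random starts.
#' @return An `ordination` object: list with `coordinates` (samples x
#'   dims matrix, rownames = sample ids), `method`, and `stress` (NMDS
#'   only, Kruskal stress-1 as a fraction).
#' @export
ordinate <- function(d, method = c("pcoa", "nmds"), dims = 2,
                     seed = NULL, try_starts = 20) {
  method <- match.arg(method)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)))
      stop("dissimilarity matrix must be symmetric", call. = FALSE)
    d <- stats::as.dist(d)
  }
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (dims >= n)
    stop("dims must be smaller than the number of samples",
         call. = FALSE)
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (method == "pcoa") {
    coords <- stats::cmdscale(d, k = dims)
    # pad if degenerate geometry yields fewer axes
    if (ncol(coords) < dims)
      coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
    stress <- NA_real_
  } else {
    fit <- with_seed(seed, withCallingHandlers(
      vegan::metaMDS(d, k = dims, try = try_starts,
                     trymax = try_starts, trace = 0),
      # informational notice from post-hoc axis scaling of small,
      # well-separated configurations; harmless here
      warning = function(w) {
        if (grepl("half-change scaling", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))
    coords <- fit$points
    stress <- fit$stress
  }
  rownames(coords) <- ids
  colnames(coords) <- paste0("Dim", seq_len(ncol(coords)))
  structure(list(coordinates = coords, method = method,
                 stress = stress),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination>", x$method, "-", nrow(x$coordinates), "samples x",
      ncol(x$coordinates), "dims")
  if (!is.na(x$stress)) cat(sprintf("  stress = %.4f", x$stress))
  cat("\n")
  invisible(x)
}

.align_ordinations <- function(X, Y) {
  stopifnot(inherits(X, "ordination"), inherits(Y, "ordination"))
  a <- X$coordinates; b <- Y$coordinates
  if (ncol(a) != ncol(b))
    stop("ordinations have different dimensionality", call. = FALSE)
  if (!setequal(rownames(a), rownames(b)))
    stop("ordinations cover different samples", call. = FALSE)
  list(a = a, b = b[rownames(a), , drop = FALSE])
}

#' Procrustes superimposition of two ordinations
#'
#' Centres both configurations, finds the rotation (reflections
#' allowed) and uniform scaling that best superimposes `Y` on `X`, and
#' reports the agreement. In symmetric mode (the convention of the
#' permutation test) both configurations are scaled to unit sum of
#' squares and the correlation statistic is `sqrt(1 - m2)`, where `m2`
#' is the standardised residual sum of squares.
#'
#' `protest()` adds a permutation test: the rows of `Y` are permuted
#' `n_perm` times and `p = (1 + #{permuted r >= observed r}) /
#' (n_perm + 1)`, so with 999 permutations the smallest attainable p is
#' 0.001. When the sample count is so small that fewer than `n_perm`
#' distinct row orders exist, the permutation engine enumerates them
#' all and the p-value is exact instead.
#'
#' @param X,Y [ordinate()] results over the same samples (matched by
#'   sample id, order-independent).
#' @param symmetric scale both configurations (symmetric statistic)?
#' @return A `procrustes_result`: list with `correlation`, `rss`
#'   (residual sum of squares), `rotation`, `scale`, and (from
#'   `protest()`) `p_value` and `n_perm`.
#' @examples
#' pts <- matrix(rnorm(20), 10, 2,
#'               dimnames = list(paste0("s", 1:10), NULL))
#' X <- ordinate(dist(pts), dims = 2)
#' Y <- ordinate(dist(pts %*% matrix(c(0, 1, -1, 0), 2, 2)), dims = 2)
#' procrustes_fit(X, Y)$correlation
#' @export
procrustes_fit <- function(X, Y, symmetric = TRUE) {
  al <- .align_ordinations(X, Y)
  pr <- vegan::procrustes(al$a, al$b, symmetric = symmetric)
  # the correlation statistic is defined under symmetric scaling
  ss_sym <- if (symmetric) pr$ss
            else vegan::procrustes(al$a, al$b, symmetric = TRUE)$ss
  structure(list(correlation = sqrt(max(0, 1 - ss_sym)),
                 rss = pr$ss, rotation = pr$rotation,
                 scale = pr$scale, p_value = NULL, n_perm = NULL),
            class = "procrustes_result")
}

#' @rdname procrustes_fit
#' @param n_perm number of row permutations.
#' @param seed integer seed for the permutations.
#' @export
protest <- function(X, Y, n_perm = 999, seed = NULL) {
  stopifnot(is_count(n_perm), n_perm >= 1)
  al <- .align_ordinations(X, Y)
  pt <- with_seed(seed,
    vegan::protest(al$a, al$b, permutations = n_perm))
  structure(list(correlation = unname(pt$t0), rss = pt$ss,
                 rotation = pt$rotation, scale = pt$scale,
                 p_value = unname(pt$signif),
                 n_perm = as.integer(n_perm)),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> correlation = %.4f, rss = %.4g",
              x$correlation, x$rss))
  if (!is.null(x$p_value))
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}
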