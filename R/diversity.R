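#' Alpha-diversity statistics of a profile
#'
#' `observed_taxa()` is the species richness after the detection rule:
#' the number of species passing the read-support and relative-
#' abundance thresholds. `shannon()` is the Shannon diversity index
#' `H = -sum(p_i * ln p_i)` in nats, and `pielou()` the evenness
#' `J = H / ln S`, where `S` is the number of species with positive
#' abundance and `ln S` is the maximum attainable `H` (all species
#' equifrequent).
#'
#' By default the indices are computed on the species that pass the
#' detection rule, with abundances renormalised over that set — the
#' same species list that defines the observed-taxa count — so that the
#' three statistics describe the same community. Set `min_reads = 0,
#' min_frac = 0` in [profile_diversity()] to use the raw species list.
#'
#' @inheritParams detect_species
#' @return `observed_taxa()`: integer count.
#' @examples
#' p <- simulate_profile(mock_spec(), depth = 1e6, seed = 1)
#' observed_taxa(p)
#' shannon(relative_abundances(p))
#' @export
observed_taxa <- function(profile, min_reads = 10, min_frac = 0.1) {
  length(detect_species(profile, min_reads = min_reads,
                        min_frac = min_frac))
}

#' @rdname observed_taxa
#' @param p an [abundance_vector()] or a named numeric vector of
#'   non-negative abundances (any scale; renormalised internally).
#'   Zero entries are excluded before computing the index.
#' @return `shannon()`: H in nats, in `[0, ln S]`.
#' @export
shannon <- function(p) {
  x <- unclass(p)
  x <- x[!is.na(x) & x > 0]
  if (!length(x))
    stop("Shannon index undefined: no species with positive abundance",
         call. = FALSE)
  # vegan normalises internally; our tests check the closed form
  as.double(vegan::diversity(x, index = "shannon"))
}

#' @rdname observed_taxa
#' @return `pielou()`: J in `(0, 1]`.
#' @export
pielou <- function(p) {
  x <- unclass(p)
  x <- x[!is.na(x) & x > 0]
  s <- length(x)
  if (s < 2)
    stop("Pielou evenness undefined for fewer than 2 species",
         call. = FALSE)
  shannon(x) / log(s)
}

#' Detection-filtered diversity summary of a profile
#'
#' Applies the detection rule, renormalises abundances over the
#' detected species, and returns the three alpha-diversity statistics
#' together. Used as the per-replicate metric of the diversity depth
#' curves.
#'
#' @inheritParams detect_species
#' @return Named numeric vector `c(observed_taxa, shannon, pielou)`;
#'   `shannon` is `NA` when no species is detected and `pielou` is `NA`
#'   when fewer than two are.
#' @export
profile_diversity <- function(profile, min_reads = 10, min_frac = 0.1) {
  sp <- detect_species(profile, min_reads = min_reads,
                       min_frac = min_frac)
  out <- c(observed_taxa = length(sp), shannon = NA_real_,
           pielou = NA_real_)
  if (length(sp) >= 1) {
    x <- profile$counts[sp]
    out["shannon"] <- shannon(x)
    if (length(sp) >= 2) out["pielou"] <- pielou(x)
  }
  out
}

#' Correlation between two abundance vectors
#'
#' Agreement between two estimates of the same community, e.g. declared
#' versus observed abundances, or a full versus a depth-reduced sample.
#' With `union_rule = "union_zeros"` (default) the correlation runs
#' over the union of the two species sets with absent species at zero —
#' the right choice for full-versus-reduced comparisons where reduced
#' samples legitimately lose rare species. `"intersection"` restricts
#' to shared species.
#'
#' @param a,b [abundance_vector()]s (or named numeric vectors, percent).
#' @param method `"spearman"` (rank) or `"pearson"` (linear, on the
#'   percent scale).
#' @param union_rule how to align the two species sets.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' a <- abundance_vector(c(A = 60, B = 30, C = 10))
#' b <- abundance_vector(c(A = 55, B = 35, C = 10))
#' abundance_correlation(a, b, method = "pearson")
#' @export
abundance_correlation <- function(a, b,
                                  method = c("spearman", "pearson"),
                                  union_rule = c("union_zeros",
                                                 "intersection")) {
  method <- match.arg(method)
  union_rule <- match.arg(union_rule)
  av <- unclass(a); bv <- unclass(b)
  if (is.null(names(av)) || is.null(names(bv)))
    stop("abundance vectors must be named by species", call. = FALSE)
  species <- switch(union_rule,
                    union_zeros = union(names(av), names(bv)),
                    intersection = intersect(names(av), names(bv)))
  if (length(species) < 3)
    stop("fewer than 3 species after the '", union_rule,
         "' rule; correlation not meaningful", call. = FALSE)
  x <- ifelse(species %in% names(av), av[species], 0)
  y <- ifelse(species %in% names(bv), bv[species], 0)
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  stats::cor(x, y, method = method)
}
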