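#' The 20-species staggered mock community
#'
#' Declared composition of the ATCC MSA-1003 "20 Strain Staggered Mix"
#' genomic mock community: 20 bacterial species, five each at 0.02%,
#' 0.18%, 1.8% and 18% relative abundance. This defined community is
#' the ground truth for detection-threshold calibration.
#'
#' @return A [community_spec()] with 20 species summing to 100%.
#' @examples
#' spec <- mock_spec()
#' sum(spec$declared)
#' @export
mock_spec <- function() {
  community_spec(c(
    "Acinetobacter baumannii"      = 0.18,
    "Actinomyces odontolyticus"    = 0.02,
    "Bacillus cereus"              = 1.80,
    "Bacteroides vulgatus"         = 0.02,
    "Bifidobacterium adolescentis" = 0.02,
    "Clostridium beijerinckii"     = 1.80,
    "Cutibacterium acnes"          = 0.18,
    "Deinococcus radiodurans"      = 0.02,
    "Enterococcus faecalis"        = 0.02,
    "Escherichia coli"             = 18.0,
    "Helicobacter pylori"          = 0.18,
    "Lactobacillus gasseri"        = 0.18,
    "Neisseria meningitidis"       = 0.18,
    "Porphyromonas gingivalis"     = 18.0,
    "Pseudomonas aeruginosa"       = 1.80,
    "Rhodobacter sphaeroides"      = 18.0,
    "Staphylococcus aureus"        = 1.80,
    "Staphylococcus epidermidis"   = 18.0,
    "Streptococcus agalactiae"     = 1.80,
    "Streptococcus mutans"         = 18.0))
}

#' Read misclassification model
#'
#' Describes how a classifier relabels reads: for every true species, a
#' set of emitted labels with probabilities, plus a per-read probability
#' of remaining unclassified. For each true species,
#' `unclassified_rate + sum(emission probabilities) = 1`.
#'
#' The default model built by [default_misclass_model()] is the
#' identity kernel with a single sister-species leak: reads from one
#' species are emitted under a closely related label with probability
#' `p` (default, Escherichia coli to Shigella flexneri at 0.007 — the
#' kind of leak that produces the characteristic one false positive in
#' mock-community profiles).
#'
#' @param kernel named list: for each true species, a data frame with
#'   columns `label` and `prob`.
#' @param unclassified_rate probability in `[0, 1]` that a read is
#'   dropped to unclassified, shared across species.
#' @return A `misclass_model` object.
#' @export
misclass_model <- function(kernel, unclassified_rate = 0) {
  stopifnot(is.list(kernel), !is.null(names(kernel)),
            unclassified_rate >= 0, unclassified_rate <= 1)
  for (sp in names(kernel)) {
    k <- kernel[[sp]]
    if (!is.data.frame(k) || !all(c("label", "prob") %in% names(k)))
      stop("kernel entry for ", sp,
           " must be a data frame with columns label, prob",
           call. = FALSE)
    if (any(k$prob < 0) || any(k$prob > 1))
      stop("emission probabilities for ", sp, " outside [0,1]",
           call. = FALSE)
    if (abs(unclassified_rate + sum(k$prob) - 1) > 1e-9)
      stop("emissions for ", sp,
           " plus unclassified rate must sum to 1", call. = FALSE)
  }
  structure(list(kernel = kernel,
                 unclassified_rate = as.double(unclassified_rate)),
            class = "misclass_model")
}

#' @rdname misclass_model
#' @param species character vector of true species names the model must
#'   cover.
#' @param leak_from,leak_to,leak_p optional single leak: reads of
#'   `leak_from` are emitted as `leak_to` with probability `leak_p`.
#'   Set `leak_p = 0` (or `leak_from = NULL`) for a pure identity
#'   kernel.
#' @export
default_misclass_model <- function(species,
                                   leak_from = "Escherichia coli",
                                   leak_to = "Shigella flexneri",
                                   leak_p = 0.007,
                                   unclassified_rate = 0) {
  kernel <- lapply(species, function(sp) {
    p_self <- 1 - unclassified_rate
    if (!is.null(leak_from) && leak_p > 0 && identical(sp, leak_from))
      data.frame(label = c(sp, leak_to),
                 prob = c(p_self - leak_p, leak_p),
                 stringsAsFactors = FALSE)
    else
      data.frame(label = sp, prob = p_self, stringsAsFactors = FALSE)
  })
  names(kernel) <- species
  misclass_model(kernel, unclassified_rate = unclassified_rate)
}

#' Simulate classifier output for a defined community
#'
#' Draws `depth` reads multinomially from the declared composition and
#' passes every read through the misclassification kernel, which may
#' relabel it (e.g. sister-species leakage) or drop it to unclassified.
#' This emulates the species-level read-count table a k-mer classifier
#' with abundance re-estimation would report for the community, without
#' generating sequence.
#'
#' @param spec a [community_spec()].
#' @param model a [misclass_model()] covering every species in `spec`;
#'   `NULL` for the identity kernel.
#' @param depth number of reads to simulate.
#' @param seed integer seed for reproducibility (`NULL` = use current
#'   RNG stream).
#' @param sample_id sample name of the returned profile.
#' @return A [taxon_profile()] whose counts plus unclassified sum to
#'   `depth`.
#' @examples
#' p <- simulate_profile(mock_spec(), depth = 1e5, seed = 1)
#' total_reads(p)
#' @export
simulate_profile <- function(spec, model = NULL, depth, seed = NULL,
                             sample_id = "sim") {
  stopifnot(inherits(spec, "community_spec"), is_count(depth))
  if (is.null(model))
    model <- default_misclass_model(spec$species, leak_from = NULL)
  stopifnot(inherits(model, "misclass_model"))
  missing <- setdiff(spec$species, names(model$kernel))
  if (length(missing))
    stop("misclassification kernel missing species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (depth == 0)
    return(taxon_profile(sample_id = sample_id))
  with_seed(seed, {
    true_counts <- stats::rmultinom(1L, depth, spec$declared / 100)[, 1L]
    names(true_counts) <- spec$species
    emitted <- new.env(parent = emptyenv())
    unclassified <- 0
    for (sp in spec$species) {
      n <- true_counts[[sp]]
      if (n == 0) next
      k <- model$kernel[[sp]]
      probs <- c(k$prob, model$unclassified_rate)
      draws <- stats::rmultinom(1L, n, probs)[, 1L]
      unclassified <- unclassified + draws[length(draws)]
      for (j in seq_len(nrow(k))) {
        if (draws[j] == 0) next
        lab <- k$label[j]
        emitted[[lab]] <- (emitted[[lab]] %||% 0) + draws[j]
      }
    }
    labs <- sort(ls(emitted))
    counts <- vapply(labs, function(l) emitted[[l]], numeric(1))
    taxon_profile(counts, unclassified = unclassified,
                  sample_id = sample_id)
  })
}

#' Multi-sample study design and simulation
#'
#' `study_design()` declares a panel of samples by target richness
#' (species detectable at the 0.1% abundance rule) and sequencing
#' depth, emulating the heterogeneous sample panels of real
#' coverage-reduction studies (richness spanning roughly 4-138 species
#' at 1.3-12.5 million reads). `simulate_study()` draws each sample's
#' species from a shared pool with abundances from a log-normal (or
#' log-series) species-abundance distribution, then samples reads
#' multinomially at the design depth.
#'
#' @param sample_id character vector of sample names.
#' @param richness integer vector of target species richness per sample
#'   (after the 10-read / 0.1% detection rule at ample depth).
#' @param depth integer vector of total reads per sample.
#' @param distribution species-abundance distribution, `"lognormal"`
#'   (parameter `sigma`, the log-scale standard deviation) or
#'   `"logseries"` (parameter `theta` in (0,1)).
#' @param sigma,theta distribution parameters, recycled per sample.
#' @return `study_design()` returns a data frame of class
#'   `study_design`.
#' @examples
#' d <- study_design(c("S1", "S2"), richness = c(4, 20),
#'                   depth = c(2e5, 2e5))
#' profs <- simulate_study(d, seed = 1)
#' @export
study_design <- function(sample_id, richness, depth,
                         distribution = "lognormal",
                         sigma = 1, theta = 0.95) {
  n <- length(sample_id)
  d <- data.frame(sample_id = as.character(sample_id),
                  richness = as.integer(richness),
                  depth = as.double(depth),
                  distribution = rep_len(distribution, n),
                  sigma = rep_len(sigma, n),
                  theta = rep_len(theta, n),
                  stringsAsFactors = FALSE)
  if (any(d$richness < 1))
    stop("richness must be >= 1", call. = FALSE)
  if (any(d$depth < d$richness))
    stop("depth must be at least the target richness", call. = FALSE)
  # a sample cannot hold more than 1000 species all at >= 0.1%
  if (any(d$richness * 0.1 > 100))
    stop("infeasible richness: more species than can each exceed 0.1%",
         call. = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

# Pick k pool weights whose normalised top-k composition has a number
# of species >= min_frac% closest to the richness target.
.calibrate_weights <- function(weights, target, min_frac = 0.1) {
  w <- sort(weights, decreasing = TRUE)
  detected <- function(k) {
    p <- 100 * w[1:k] / sum(w[1:k])
    sum(p >= min_frac)
  }
  ks <- seq.int(target, length(w))
  d <- vapply(ks, detected, numeric(1))
  best <- ks[which.min(abs(d - target))]
  w[1:best]
}

#' @rdname study_design
#' @param design a `study_design`.
#' @param seed master seed; each sample derives its own child seed.
#' @param pool_size number of species names in the shared pool from
#'   which samples draw their communities (controls cross-sample
#'   overlap).
#' @return `simulate_study()` returns a named list of
#'   [taxon_profile()]s, one per design row.
#' @export
simulate_study <- function(design, seed = NULL, pool_size = 300) {
  stopifnot(inherits(design, "study_design"))
  pool <- sprintf("Synthetibacter sp%03d", seq_len(pool_size))
  seeds <- derive_seeds(seed, nrow(design))
  profs <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    with_seed(seeds[[i]], {
      n_cand <- min(pool_size, max(3L * row$richness, row$richness + 20L))
      weights <- switch(row$distribution,
        lognormal = stats::rlnorm(n_cand, meanlog = 0,
                                  sdlog = row$sigma),
        logseries = {
          x <- seq_len(n_cand)
          # log-series expected abundances, randomly jittered ranks
          (row$theta ^ x / x)[sample.int(n_cand)]
        },
        stop("unknown distribution: ", row$distribution, call. = FALSE))
      w <- .calibrate_weights(weights, row$richness)
      sp <- sample(pool, length(w))
      p <- w / sum(w)
      counts <- stats::rmultinom(1L, row$depth, p)[, 1L]
      names(counts) <- sp
      taxon_profile(counts[counts > 0], unclassified = 0,
                    sample_id = row$sample_id)
    })
  })
  names(profs) <- design$sample_id
  profs
}
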