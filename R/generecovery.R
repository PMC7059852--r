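#' Per-species gene-recovery (completeness) tables
#'
#' A `gene_recovery` table summarises, per species, the outcome of a
#' conserved single-copy-orthologue completeness assessment of an
#' assembly: the fractions of genes found complete, fragmented and
#' missing (summing to 1), and the number of genes assessed.
#'
#' @param species character vector of species names (unique).
#' @param n_genes integer vector (or scalar) of genes assessed.
#' @param complete,fragmented,missing numeric fractions in `[0, 1]`,
#'   summing to 1 per species (tolerance `1e-9`).
#' @return A data frame of class `gene_recovery`.
#' @examples
#' t <- gene_recovery_table("Escherichia coli", 100, 0.9, 0.05, 0.05)
#' reconstructed_fraction(t, "Escherichia coli")
#' @export
gene_recovery_table <- function(species, n_genes, complete, fragmented,
                                missing) {
  if (anyDuplicated(species))
    stop("species names must be unique", call. = FALSE)
  d <- data.frame(species = as.character(species),
                  n_genes = as.integer(n_genes),
                  complete = as.double(complete),
                  fragmented = as.double(fragmented),
                  missing = as.double(missing),
                  stringsAsFactors = FALSE)
  fr <- d[c("complete", "fragmented", "missing")]
  if (any(fr < 0) || any(fr > 1))
    stop("completeness fractions must lie in [0, 1]", call. = FALSE)
  bad <- abs(rowSums(fr) - 1) > 1e-9
  if (any(bad))
    stop("fractions must sum to 1 for: ",
         paste(d$species[bad], collapse = ", "), call. = FALSE)
  class(d) <- c("gene_recovery", "data.frame")
  d
}

#' Proportion of genes reconstructed for a species
#'
#' The reconstructed proportion counts a gene as recovered whether it
#' was fully or only partially reconstructed:
#' `fraction_complete + fraction_fragmented`.
#'
#' @param t a [gene_recovery_table()].
#' @param species species name present in `t`.
#' @return Fraction in `[0, 1]`.
#' @export
reconstructed_fraction <- function(t, species) {
  stopifnot(inherits(t, "gene_recovery"))
  i <- match(species, t$species)
  if (anyNA(i))
    stop("species not in recovery table: ",
         paste(species[is.na(i)], collapse = ", "), call. = FALSE)
  t$complete[i] + t$fragmented[i]
}

#' Average reconstructed proportion over detected species
#'
#' Per-sample summary: the unweighted mean of
#' [reconstructed_fraction()] over the species detected in the sample.
#' A detected species absent from the table is an error, never a silent
#' zero.
#'
#' @inheritParams reconstructed_fraction
#' @param detected character vector of detected species (non-empty,
#'   subset of `t$species`).
#' @return Fraction in `[0, 1]`.
#' @export
mean_recovery <- function(t, detected) {
  if (!length(detected))
    stop("no detected species to average over", call. = FALSE)
  mean(reconstructed_fraction(t, detected))
}

#' Simulate gene recovery at a given sequencing depth
#'
#' Synthetic stand-in for the assemble-then-assess step
#' (assembly + orthologue completeness), capturing its depth
#' dependence. Each species gets a mean per-base coverage
#' `c = depth * fraction * read_length / genome_size`; a gene is
#' discretised into read-length bins, each independently covered with
#' the Lander-Waterman probability `1 - exp(-c)`. A gene with all bins
#' covered is complete, with some covered fragmented, with none
#' missing. Under a fixed seed the same uniform draws are reused at
#' every depth, so recovery is monotone non-decreasing in depth
#' seed-for-seed.
#'
#' This model ignores assembly contiguity and repeat structure, so it
#' is optimistic about fragmented recovery at low coverage; its purpose
#' is the qualitative depth/abundance dependence, not literal
#' completeness values.
#'
#' @param spec a [community_spec()].
#' @param depth total reads sequenced.
#' @param genome_sizes named numeric vector of genome sizes (bases)
#'   covering every species in `spec`; see [mock_genome_sizes()].
#' @param read_length read length in bases.
#' @param n_genes genes assessed per species.
#' @param gene_length gene length in bases.
#' @param seed integer seed.
#' @return A [gene_recovery_table()] with one row per species of
#'   `spec`.
#' @examples
#' t <- simulate_recovery(mock_spec(), depth = 1e6,
#'                        genome_sizes = mock_genome_sizes(), seed = 1)
#' mean_recovery(t, "Escherichia coli")
#' @export
simulate_recovery <- function(spec, depth, genome_sizes,
                              read_length = 125, n_genes = 100,
                              gene_length = 1000, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"), is_count(depth),
            read_length > 0, n_genes >= 1, gene_length > 0)
  missing_gs <- setdiff(spec$species, names(genome_sizes))
  if (length(missing_gs))
    stop("no genome size for: ", paste(missing_gs, collapse = ", "),
         call. = FALSE)
  if (any(genome_sizes <= 0))
    stop("genome sizes must be positive", call. = FALSE)
  bins <- max(1L, ceiling(gene_length / read_length))
  rows <- with_seed(seed, lapply(spec$species, function(sp) {
    cov <- depth * (spec$declared[[sp]] / 100) * read_length /
      genome_sizes[[sp]]
    p_bin <- 1 - exp(-cov)
    u <- matrix(stats::runif(n_genes * bins), n_genes, bins)
    covered <- u < p_bin
    hit <- rowSums(covered)
    data.frame(species = sp, n_genes = n_genes,
               complete = sum(hit == bins) / n_genes,
               fragmented = sum(hit > 0 & hit < bins) / n_genes,
               missing = sum(hit == 0) / n_genes,
               stringsAsFactors = FALSE)
  }))
  d <- do.call(rbind, rows)
  gene_recovery_table(d$species, d$n_genes, d$complete, d$fragmented,
                      d$missing)
}

#' Approximate genome sizes for the mock-community species
#'
#' Round approximations (in bases) of the genome sizes of the 20
#' staggered-mock species, used by [simulate_recovery()] to convert
#' read fractions into per-base coverage. Precision beyond the first
#' digits is irrelevant to the simulated depth dependence.
#'
#' @return Named numeric vector of genome sizes in bases.
#' @export
mock_genome_sizes <- function() {
  c("Acinetobacter baumannii"      = 4.0e6,
    "Actinomyces odontolyticus"    = 2.4e6,
    "Bacillus cereus"              = 5.4e6,
    "Bacteroides vulgatus"         = 5.2e6,
    "Bifidobacterium adolescentis" = 2.1e6,
    "Clostridium beijerinckii"     = 6.0e6,
    "Cutibacterium acnes"          = 2.5e6,
    "Deinococcus radiodurans"      = 3.3e6,
    "Enterococcus faecalis"        = 2.9e6,
    "Escherichia coli"             = 4.6e6,
    "Helicobacter pylori"          = 1.7e6,
    "Lactobacillus gasseri"        = 1.9e6,
    "Neisseria meningitidis"       = 2.2e6,
    "Porphyromonas gingivalis"     = 2.3e6,
    "Pseudomonas aeruginosa"       = 6.3e6,
    "Rhodobacter sphaeroides"      = 4.6e6,
    "Staphylococcus aureus"        = 2.8e6,
    "Staphylococcus epidermidis"   = 2.5e6,
    "Streptococcus agalactiae"     = 2.2e6,
    "Streptococcus mutans"         = 2.0e6)
}

#' @rdname gene_recovery_table
#' @param path tab-delimited file with columns species, n_genes,
#'   complete, fragmented, missing (fractions).
#' @export
read_recovery_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("species", "n_genes", "complete", "fragmented", "missing")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("recovery table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  gene_recovery_table(tab$species, tab$n_genes, tab$complete,
                      tab$fragmented, tab$missing)
}

#' @rdname gene_recovery_table
#' @param t a `gene_recovery` table to write.
#' @export
write_recovery_tsv <- function(t, path) {
  stopifnot(inherits(t, "gene_recovery"))
  utils::write.table(t, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
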