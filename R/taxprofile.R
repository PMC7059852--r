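#' Species-level taxonomic profile of one sample
#'
#' A `taxon_profile` holds the per-species read counts of a single
#' sequencing sample, as estimated by a read classifier with Bayesian
#' abundance re-estimation (the Bracken report is the interchange
#' format, see [read_bracken_tsv()]), together with the number of reads
#' the classifier could not assign.
#'
#' @param counts named numeric vector of non-negative integer read
#'   counts, one entry per species (binomial name). Species names must
#'   be unique. May be empty.
#' @param unclassified non-negative integer count of unclassified reads.
#' @param sample_id character scalar identifying the sample.
#'
#' @return An object of class `taxon_profile`: a list with elements
#'   `sample_id`, `counts` (named numeric) and `unclassified`.
#' @seealso [relative_abundances()], [detect_species()],
#'   [subsample_profile()]
#' @examples
#' p <- taxon_profile(c("Escherichia coli" = 90, "Shigella flexneri" = 10),
#'                    unclassified = 25, sample_id = "toy")
#' total_reads(p)
#' @export
taxon_profile <- function(counts = numeric(), unclassified = 0,
                          sample_id = "sample") {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("all species counts must be named", call. = FALSE)
    if (anyDuplicated(names(counts)))
      stop("species names must be unique", call. = FALSE)
    if (any(is.na(counts)) || any(counts < 0))
      stop("read counts must be non-negative", call. = FALSE)
    if (any(abs(counts - round(counts)) > 1e-6))
      stop("read counts must be whole numbers", call. = FALSE)
  }
  if (!is_count(unclassified))
    stop("`unclassified` must be a single non-negative integer",
         call. = FALSE)
  cnt <- round(as.double(counts))
  names(cnt) <- names(counts)
  structure(
    list(sample_id = as.character(sample_id),
         counts = cnt,
         unclassified = round(as.double(unclassified))),
    class = "taxon_profile")
}

#' @rdname taxon_profile
#' @param x,profile a `taxon_profile`.
#' @export
total_reads <- function(profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  sum(profile$counts) + profile$unclassified
}

#' @rdname taxon_profile
#' @param ... ignored.
#' @export
print.taxon_profile <- function(x, ...) {
  cat("<taxon_profile> sample:", x$sample_id, "\n")
  cat("  species:", length(x$counts),
      " classified reads:", format(sum(x$counts), big.mark = ","),
      " unclassified:", format(x$unclassified, big.mark = ","), "\n")
  if (length(x$counts)) {
    top <- sort(x$counts, decreasing = TRUE)
    top <- utils::head(top, 5L)
    for (i in seq_along(top))
      cat(sprintf("  %-30s %12s\n", names(top)[i],
                  format(top[i], big.mark = ",")))
    if (length(x$counts) > 5L) cat("  ...\n")
  }
  invisible(x)
}

# Bracken-style report columns, in file order.
.bracken_cols <- c("name", "taxonomy_id", "taxonomy_lvl",
                   "kraken_assigned_reads", "added_reads",
                   "new_est_reads", "fraction_total_reads")

#' Read and write Bracken-style abundance reports
#'
#' `read_bracken_tsv()` parses a tab-delimited Bracken species report
#' into a [taxon_profile()]. Species-level rows (`taxonomy_lvl == "S"`)
#' become count entries; a reserved `unclassified` row (level `"U"`),
#' when present, supplies the unclassified read count.
#'
#' @param path path to a tab-delimited report. The header must contain
#'   at least `name`, `taxonomy_lvl`, `new_est_reads` and
#'   `fraction_total_reads`.
#' @param sample_id sample identifier for the returned profile;
#'   defaults to the file name without extension.
#' @return `read_bracken_tsv()` returns a [taxon_profile()];
#'   `write_bracken_tsv()` returns `path` invisibly.
#' @examples
#' p <- taxon_profile(c(A = 25, B = 25), unclassified = 50)
#' f <- tempfile(fileext = ".tsv")
#' write_bracken_tsv(p, f)
#' read_bracken_tsv(f)$counts
#' @export
read_bracken_tsv <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("name", "taxonomy_lvl", "new_est_reads",
                "fraction_total_reads")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("malformed Bracken report, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(tab$new_est_reads < 0, na.rm = TRUE))
    stop("negative read counts in ", path, call. = FALSE)
  is_unc <- tab$taxonomy_lvl == "U" | tolower(tab$name) == "unclassified"
  unclassified <- if (any(is_unc)) sum(tab$new_est_reads[is_unc]) else 0
  sp <- tab[!is_unc & tab$taxonomy_lvl == "S", , drop = FALSE]
  taxon_profile(stats::setNames(sp$new_est_reads, sp$name),
                unclassified = unclassified,
                sample_id = sample_id %||%
                  sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_bracken_tsv
#' @param profile a [taxon_profile()] to serialise. The
#'   `fraction_total_reads` column is recomputed from the counts.
#' @export
write_bracken_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "taxon_profile"))
  total <- total_reads(profile)
  n <- length(profile$counts)
  rows <- data.frame(
    name = names(profile$counts) %||% character(),
    taxonomy_id = rep("", n),
    taxonomy_lvl = rep("S", n),
    kraken_assigned_reads = unname(profile$counts),
    added_reads = rep(0, n),
    new_est_reads = unname(profile$counts),
    fraction_total_reads = if (total > 0)
      unname(profile$counts) / total else rep(0, n),
    stringsAsFactors = FALSE)
  if (profile$unclassified > 0) {
    rows <- rbind(rows, data.frame(
      name = "unclassified", taxonomy_id = "", taxonomy_lvl = "U",
      kraken_assigned_reads = profile$unclassified, added_reads = 0,
      new_est_reads = profile$unclassified,
      fraction_total_reads = profile$unclassified / total))
  }
  ok <- tryCatch({
    utils::write.table(rows[, .bracken_cols], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write Bracken report to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Relative species abundances of a profile
#'
#' Converts read counts to percentages, either of the classified
#' species-level reads (`basis = "classified"`, summing to 100) or of
#' all reads including unclassified (`basis = "total"`).
#'
#' @inheritParams total_reads
#' @param basis denominator for the percentages.
#' @return An `abundance_vector`: a named numeric vector of percentages
#'   with attributes `basis` and `sample_id`.
#' @examples
#' p <- taxon_profile(c(A = 18, B = 82), unclassified = 100)
#' relative_abundances(p, basis = "classified")
#' relative_abundances(p, basis = "total")
#' @export
relative_abundances <- function(profile, basis = c("classified", "total")) {
  stopifnot(inherits(profile, "taxon_profile"))
  basis <- match.arg(basis)
  denom <- switch(basis, classified = sum(profile$counts),
                  total = total_reads(profile))
  if (denom <= 0)
    stop("profile '", profile$sample_id,
         "' has no reads to normalise by", call. = FALSE)
  abundance_vector(100 * profile$counts / denom, basis = basis,
                   sample_id = profile$sample_id)
}

#' @rdname relative_abundances
#' @param fractions named numeric vector of percentages.
#' @param sample_id sample identifier carried along for reporting.
#' @export
abundance_vector <- function(fractions, basis = c("classified", "total"),
                             sample_id = "sample") {
  basis <- match.arg(basis)
  if (length(fractions)) {
    if (is.null(names(fractions)))
      stop("abundances must be named by species", call. = FALSE)
    if (any(fractions < 0)) stop("abundances must be >= 0", call. = FALSE)
    if (sum(fractions) > 100 + 1e-6)
      stop("abundances sum above 100%", call. = FALSE)
  }
  fr <- as.double(fractions)
  names(fr) <- names(fractions)
  structure(fr, basis = basis, sample_id = as.character(sample_id),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("<abundance_vector> basis:", attr(x, "basis"),
      " sample:", attr(x, "sample_id"), "\n")
  print(round(unclass(x)[order(-unclass(x))], 4), ...)
  invisible(x)
}

#' Apply the species detection rule
#'
#' A species is declared present when it is supported by at least
#' `min_reads` reads and its relative abundance is at least `min_frac`
#' percent. Both comparisons are inclusive, so a species at exactly the
#' threshold is detected. The defaults (10 reads, 0.1%) are the rule
#' calibrated on the staggered mock community via [best_threshold()].
#'
#' @inheritParams relative_abundances
#' @param min_reads minimum supporting read count (inclusive).
#' @param min_frac minimum relative abundance in percent (inclusive).
#' @return Character vector of detected species names (possibly empty).
#' @examples
#' p <- taxon_profile(c(A = 996, B = 4), sample_id = "toy")
#' detect_species(p, min_reads = 10, min_frac = 0.1)
#' @export
detect_species <- function(profile, min_reads = 10, min_frac = 0.1,
                           basis = c("classified", "total")) {
  stopifnot(inherits(profile, "taxon_profile"),
            is_count(min_reads), min_frac >= 0, min_frac <= 100)
  basis <- match.arg(basis)
  if (!length(profile$counts) || sum(profile$counts) == 0)
    return(character())
  frac <- relative_abundances(profile, basis = basis)
  names(profile$counts)[profile$counts >= min_reads &
                          unclass(frac) >= min_frac]
}
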