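# Benchmark reference tables shipped with the package.
#
# Three small TSVs transcribe the published mock-community benchmark:
# the detection-threshold performance sweep, the per-sample summary of
# the ten-sample study panel (read counts and species richness), and
# the database-comparison table of estimated mock abundances (with the
# "NP" marker for species below the 0.1% detection rule and "ND" for
# species not declared in the mock). Checksums guard the transcription.

.fixture_files <- c(
  table1 = "table1_threshold_sweep.tsv",
  table2 = "table2_sample_summary.tsv",
  table3 = "table3_database_comparison.tsv")

.fixture_md5 <- c(
  table1 = "ea849ce954111ba19669e5359d0b97ac",
  table2 = "07faaead4d705a5f4820f516ba2dd341",
  table3 = "49da0dd4cf16eddfe666ce942636fb3b")

#' Load a packaged benchmark reference table
#'
#' @param table_id one of `"table1"` (threshold-sweep performance:
#'   threshold, TP, FP, FN, F1), `"table2"` (study-panel summary:
#'   sample, n_reads, n_species), `"table3"` (mock abundances by
#'   classifier database; `"NP"` marks species below the 0.1%
#'   detection rule, `"ND"` in the abundance column marks species not
#'   declared in the mock).
#' @return A data frame of class `benchmark_fixture` with attribute
#'   `table_id`. Columns of `table3` other than `species` are kept as
#'   printed (character), so the NP/ND sentinels survive; use
#'   [fixture_to_profile()] or [fixture_column()] for numeric access.
#' @examples
#' load_fixture("table1")
#' @export
load_fixture <- function(table_id = c("table1", "table2", "table3")) {
  table_id <- match.arg(table_id)
  path <- system.file("extdata", .fixture_files[[table_id]],
                      package = "shallowmeta", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), .fixture_md5[[table_id]]))
    stop("fixture ", table_id, " failed its checksum", call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = if (table_id == "table3")
                             "character" else NA)
  attr(tab, "table_id") <- table_id
  class(tab) <- c("benchmark_fixture", "data.frame")
  tab
}

#' Numeric view of a database column of the comparison table
#'
#' @param column one of the database columns of `table3` (`"v1_100"`,
#'   `"v1_150"`, `"v2_100"`, `"v2_150"`, `"standard"`, `"nt"`).
#' @param drop_np drop species marked NP (below detection)? Otherwise
#'   they appear as `NA`.
#' @return Named numeric vector of estimated abundances in percent,
#'   with attribute `declared` (numeric, `NA` for non-declared
#'   species).
#' @export
fixture_column <- function(column, drop_np = TRUE) {
  tab <- load_fixture("table3")
  if (!column %in% names(tab)[-(1:2)])
    stop("unknown database column: ", column, call. = FALSE)
  vals <- suppressWarnings(as.numeric(tab[[column]]))  # NP -> NA
  names(vals) <- tab$species
  declared <- suppressWarnings(as.numeric(tab$abundance))  # ND -> NA
  names(declared) <- tab$species
  if (drop_np) {
    keep <- !is.na(vals)
    vals <- vals[keep]
    declared <- declared[keep]
  }
  attr(vals, "declared") <- declared
  vals
}

#' Convert a comparison-table column into a read-count profile
#'
#' Turns the printed percentages of one database column into an
#' integer-count [taxon_profile()] at a stated sequencing total
#' (half-up rounding); species marked NP are omitted and the remainder
#' of the total becomes the unclassified count, so relative abundances
#' on the `"total"` basis reproduce the printed percentages.
#'
#' @inheritParams fixture_column
#' @param total_reads full-sample read total used for the conversion;
#'   the default is the mock sample's full sequencing depth from
#'   `table2`.
#' @return A [taxon_profile()].
#' @examples
#' p <- fixture_to_profile("nt")
#' relative_abundances(p, basis = "total")[["Escherichia coli"]]
#' @export
fixture_to_profile <- function(column, total_reads = 4969245) {
  stopifnot(is_count(total_reads), total_reads > 0)
  vals <- fixture_column(column, drop_np = TRUE)
  counts <- floor(vals / 100 * total_reads + 0.5)
  pct_after <- 100 * counts / total_reads
  flipped <- (vals >= 0.1) != (pct_after >= 0.1)
  if (any(flipped))
    warning("rounding changed detection status at 0.1% for: ",
            paste(names(vals)[flipped], collapse = ", "),
            call. = FALSE)
  taxon_profile(counts,
                unclassified = total_reads - sum(counts),
                sample_id = paste0("mock_", column))
}
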