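#' Subsample a profile to a fixed read depth
#'
#' Emulates a shallower sequencing run by drawing `depth` reads from
#' the profile. The default draw is multivariate hypergeometric
#' (without replacement over the observed reads, the direct analogue of
#' subsampling raw reads with seqtk); `method = "multinomial"` instead
#' treats the profile's composition as an infinite pool, appropriate
#' when sampling from a declared composition rather than a finite read
#' set. The unclassified reads are one category of the draw, so
#' `total_reads()` of the result equals `depth` exactly.
#'
#' @inheritParams relative_abundances
#' @param depth number of reads to draw; must not exceed
#'   `total_reads(profile)` for the hypergeometric method (shallow
#'   sequencing is emulated by reduction, never by upsampling).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param method `"hypergeometric"` (without replacement) or
#'   `"multinomial"` (with replacement).
#' @return A [taxon_profile()] at the requested depth; species drawn
#'   zero times are dropped.
#' @examples
#' p <- simulate_profile(mock_spec(), depth = 1e5, seed = 1)
#' total_reads(subsample_profile(p, 1e4, seed = 2))
#' @export
subsample_profile <- function(profile, depth, seed = NULL,
                              method = c("hypergeometric",
                                         "multinomial")) {
  stopifnot(inherits(profile, "taxon_profile"), is_count(depth))
  method <- match.arg(method)
  total <- total_reads(profile)
  if (method == "hypergeometric" && depth > total)
    stop("requested depth ", format(depth, big.mark = ","),
         " exceeds the ", format(total, big.mark = ","),
         " reads of sample '", profile$sample_id, "'", call. = FALSE)
  cats <- c(profile$counts, .unclassified. = profile$unclassified)
  drawn <- with_seed(seed, switch(method,
    hypergeometric = rmvhyper1(cats, depth),
    multinomial = {
      if (total == 0 && depth > 0)
        stop("cannot draw from an empty profile", call. = FALSE)
      if (depth == 0) numeric(length(cats))
      else stats::rmultinom(1L, depth, cats / total)[, 1L]
    }))
  names(drawn) <- names(cats)
  unclassified <- drawn[[length(drawn)]]
  counts <- drawn[-length(drawn)]
  taxon_profile(counts[counts > 0], unclassified = unclassified,
                sample_id = profile$sample_id)
}

#' Evaluate a summary statistic along a depth gradient
#'
#' Runs the replicated subsampling experiment behind every depth curve:
#' for each depth, draw `n_reps` independent subsamples, evaluate
#' `metric` on each, and summarise the replicates by their mean and a
#' two-sided confidence interval.
#'
#' Defaults follow the standard evaluation grid: depths of 10,000 to
#' 1,000,000 reads, five replicates per depth, and 99% confidence
#' limits. The interval is a Student-t interval on the replicate mean
#' (df = `n_reps` - 1), the minimal defensible choice at five
#' replicates; `ci_method = "percentile"` gives empirical quantiles
#' instead. Depths exceeding the profile's total are skipped with a
#' warning. Replicate seeds derive deterministically from the master
#' seed and the (depth, replicate) cell, so the whole grid is
#' reproducible.
#'
#' @inheritParams subsample_profile
#' @param depths read depths to evaluate.
#' @param metric function mapping a [taxon_profile()] to a single
#'   numeric value (e.g. [observed_taxa()], or a wrapper around
#'   [shannon()]).
#' @param n_reps replicates per depth (>= 2 for confidence intervals).
#' @param ci_level two-sided confidence level.
#' @param ci_method `"t"` or `"percentile"`.
#' @param metric_name label stored in the result.
#' @return A `depth_series` object: list with `values` (long data frame
#'   depth/replicate/value), `summary` (depth/mean/ci_low/ci_high),
#'   `metric`, `n_replicates`, `ci_level`.
#' @examples
#' p <- simulate_profile(mock_spec(), depth = 1e5, seed = 1)
#' depth_series(p, depths = c(1e3, 1e4), metric = observed_taxa,
#'              n_reps = 3, seed = 7)
#' @export
depth_series <- function(profile, depths = c(1e4, 2.5e4, 5e4, 1e5,
                                             2.5e5, 5e5, 1e6),
                         metric, n_reps = 5, ci_level = 0.99,
                         seed = NULL, ci_method = c("t", "percentile"),
                         metric_name = NULL) {
  stopifnot(inherits(profile, "taxon_profile"), is.function(metric),
            is_count(n_reps), n_reps >= 2,
            ci_level > 0, ci_level < 1)
  ci_method <- match.arg(ci_method)
  metric_name <- metric_name %||% deparse(substitute(metric))[1]
  total <- total_reads(profile)
  feasible <- depths <= total
  if (any(!feasible))
    warning("skipping depth(s) exceeding sample total: ",
            paste(format(depths[!feasible], big.mark = ","),
                  collapse = ", "), call. = FALSE)
  depths <- sort(depths[feasible])
  seeds <- derive_seeds(seed, length(depths) * n_reps)
  rows <- vector("list", length(depths) * n_reps)
  k <- 0L
  for (di in seq_along(depths)) {
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      sub <- subsample_profile(profile, depths[di], seed = seeds[[k]])
      val <- tryCatch(metric(sub), error = function(e)
        stop("metric '", metric_name, "' failed at depth ",
             format(depths[di], big.mark = ","), ", replicate ", r,
             ": ", conditionMessage(e), call. = FALSE))
      rows[[k]] <- data.frame(depth = depths[di], replicate = r,
                              value = as.double(val))
    }
  }
  values <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(values, factor(values$depth,
                                                        levels = depths)),
                                   function(d) {
    m <- mean(d$value)
    if (ci_method == "t") {
      se <- stats::sd(d$value) / sqrt(nrow(d))
      q <- stats::qt(1 - (1 - ci_level) / 2, df = nrow(d) - 1)
      lo <- m - q * se; hi <- m + q * se
    } else {
      a <- (1 - ci_level) / 2
      qs <- stats::quantile(d$value, c(a, 1 - a), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(depth = d$depth[1], mean = m, ci_low = lo, ci_high = hi)
  }))
  rownames(summary) <- NULL
  structure(list(metric = metric_name, values = values,
                 summary = summary, n_replicates = as.integer(n_reps),
                 ci_level = ci_level),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat("<depth_series> metric:", x$metric, " (", x$n_replicates,
      "replicates,", paste0(100 * x$ci_level, "%"), "CI )\n")
  print(transform(x$summary, mean = signif(mean, 5),
                  ci_low = signif(ci_low, 5),
                  ci_high = signif(ci_high, 5)),
        row.names = FALSE)
  invisible(x)
}

#' @rdname depth_series
#' @param x a `depth_series`.
#' @param path_values,path_summary output paths for the long-format and
#'   summary tab-delimited exports (either may be `NULL` to skip).
#' @export
write_depth_series_tsv <- function(x, path_values = NULL,
                                   path_summary = NULL) {
  stopifnot(inherits(x, "depth_series"))
  if (!is.null(path_values))
    utils::write.table(cbind(metric = x$metric, x$values), path_values,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_summary))
    utils::write.table(cbind(metric = x$metric, x$summary),
                       path_summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}
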