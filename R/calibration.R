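#' Declared composition of a defined (mock) community
#'
#' A `community_spec` records the ground-truth species list and their
#' declared relative abundances (in percent, summing to 100). It is the
#' reference against which classifier output is scored, and the
#' sampling distribution of the community simulator.
#'
#' @param declared named numeric vector: declared abundance in percent
#'   per species. Names must be unique, values strictly positive and
#'   summing to 100 (tolerance `1e-6`).
#' @return An object of class `community_spec` with fields `species`
#'   and `declared`.
#' @seealso [mock_spec()] for the packaged 20-species staggered mix.
#' @examples
#' community_spec(c(A = 60, B = 30, C = 10))
#' @export
community_spec <- function(declared) {
  if (is.null(names(declared)) || anyDuplicated(names(declared)))
    stop("declared abundances must be uniquely named by species",
         call. = FALSE)
  if (any(declared <= 0))
    stop("declared abundances must be > 0", call. = FALSE)
  if (abs(sum(declared) - 100) > 1e-6)
    stop("declared abundances must sum to 100%, got ",
         format(sum(declared)), call. = FALSE)
  dec <- as.double(declared)
  names(dec) <- names(declared)
  structure(list(species = names(dec), declared = dec),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec>", length(x$species), "species\n")
  tiers <- sort(unique(x$declared))
  for (t in rev(tiers))
    cat(sprintf("  %6g%% : %d species\n", t, sum(x$declared == t)))
  invisible(x)
}

#' @rdname community_spec
#' @param spec a `community_spec`.
#' @return `declared_abundances()` returns the declared composition as
#'   an [abundance_vector()] (basis `"classified"`).
#' @export
declared_abundances <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  abundance_vector(spec$declared, basis = "classified",
                   sample_id = "declared")
}

#' Confusion counts of a profile against a known composition
#'
#' Scores an observed abundance vector against the declared community:
#' a declared species observed at or above `threshold` percent is a
#' true positive, a declared species below it (or absent) a false
#' negative, and any non-declared species at or above it a false
#' positive. True negatives are unknowable in an open species universe,
#' which is why performance is summarised by the F1 score.
#'
#' @param observed an [abundance_vector()] of observed percentages.
#' @param reference a [community_spec()].
#' @param threshold detection threshold in percent, inclusive.
#' @return A `confusion_counts` object (fields `tp`, `fp`, `fn`).
#' @examples
#' ref <- community_spec(c(A = 60, B = 30, C = 10))
#' obs <- abundance_vector(c(A = 59, B = 31, D = 10))
#' confusion_counts(obs, ref, threshold = 5)
#' @export
confusion_counts <- function(observed, reference, threshold) {
  stopifnot(inherits(reference, "community_spec"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 100)
  obs <- unclass(observed)
  called <- names(obs)[obs >= threshold]
  tp <- sum(reference$species %in% called)
  fp <- sum(!(called %in% reference$species))
  fn <- length(reference$species) - tp
  confusion(tp, fp, fn)
}

#' @rdname confusion_counts
#' @param tp,fp,fn non-negative integer counts.
#' @export
confusion <- function(tp, fp, fn) {
  stopifnot(is_count(tp), is_count(fp), is_count(fn))
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d  F1=%.3f\n",
              x$tp, x$fp, x$fn, f1_score(x)))
  invisible(x)
}

#' F1 score of a confusion-count triple
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and
#' recall, used because true negatives are unknowable when scoring an
#' open-universe classifier.
#'
#' @param x a [confusion()] object.
#' @return F1 score in `[0, 1]`, at full precision.
#' @examples
#' f1_score(confusion(14, 1, 6))   # 0.8
#' f1_score(confusion(19, 188, 1)) # ~0.17
#' @export
f1_score <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  denom <- 2 * x$tp + x$fp + x$fn
  if (denom == 0)
    stop("F1 undefined: TP, FP and FN are all zero", call. = FALSE)
  2 * x$tp / denom
}

#' Sweep the detection threshold and score each value
#'
#' Computes confusion counts and F1 for a set of candidate detection
#' thresholds, the calibration table from which the operating threshold
#' is chosen.
#'
#' @inheritParams confusion_counts
#' @param thresholds numeric vector of candidate thresholds (percent);
#'   duplicates are an error. Defaults to the standard calibration grid.
#' @return A `threshold_sweep`: a data frame with columns `threshold`,
#'   `tp`, `fp`, `fn`, `f1`, sorted by ascending threshold.
#' @seealso [best_threshold()]
#' @export
threshold_sweep <- function(observed, reference,
                            thresholds = c(0.001, 0.005, 0.01,
                                           0.05, 0.1, 0.5)) {
  if (!length(thresholds)) stop("no thresholds supplied", call. = FALSE)
  if (anyDuplicated(thresholds))
    stop("duplicate thresholds", call. = FALSE)
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(th) {
    cc <- confusion_counts(observed, reference, th)
    data.frame(threshold = th, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               f1 = f1_score(cc))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' @rdname threshold_sweep
#' @param tp,fp,fn integer vectors of confusion counts, one value per
#'   threshold: builds a sweep from already-tabulated counts (e.g. a
#'   published performance table), recomputing F1 from the counts.
#' @export
sweep_from_confusion <- function(thresholds, tp, fp, fn) {
  stopifnot(length(tp) == length(thresholds),
            length(fp) == length(thresholds),
            length(fn) == length(thresholds))
  if (anyDuplicated(thresholds))
    stop("duplicate thresholds", call. = FALSE)
  o <- order(thresholds)
  f1 <- mapply(function(a, b, c) f1_score(confusion(a, b, c)),
               tp[o], fp[o], fn[o])
  if (is.unsorted(-tp[o]) || is.unsorted(fn[o]))
    warning("counts are not monotone in threshold", call. = FALSE)
  out <- data.frame(threshold = thresholds[o], tp = tp[o], fp = fp[o],
                    fn = fn[o], f1 = as.double(f1))
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Threshold with the best F1 score
#'
#' @param sweep a [threshold_sweep()].
#' @return The threshold (percent) maximising F1; ties are broken
#'   toward the smallest threshold.
#' @export
best_threshold <- function(sweep) {
  stopifnot(inherits(sweep, "threshold_sweep"), nrow(sweep) >= 1L)
  sweep$threshold[which.max(sweep$f1)]
}

#' @rdname threshold_sweep
#' @param path file path for a tab-delimited export with columns
#'   Threshold, TP, FP, FN, F1.
#' @param sweep a `threshold_sweep`.
#' @export
write_sweep_tsv <- function(sweep, path) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  out <- data.frame(Threshold = sweep$threshold, TP = sweep$tp,
                    FP = sweep$fp, FN = sweep$fn, F1 = round(sweep$f1, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
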