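#' Match detections to ground truth for one image
#'
#' Detections are taken in order of decreasing score.  Each detection is
#' matched to the nearest not-yet-matched ground-truth object whose centre
#' lies within the position tolerance (and scale tolerance, when both
#' carry a scale).  A matched detection is a true positive; a detection
#' whose eligible objects are all already matched, or which matches
#' nothing, is a false positive (so duplicate detections of one object
#' count as false positives); unmatched objects are false negatives.
#'
#' @param dets data frame with columns `row`, `col`, `score` and
#'   optionally `scale_index` (as returned by [detect()]).
#' @param truths data frame with columns `row`, `col`, `width` and
#'   optionally `scale_index` (see [read_annotations()]).
#' @param tol_pos position tolerance in pixels; defaults to 25% of each
#'   object's annotated width.
#' @param tol_scale scale tolerance in scale-index units; default 0.5.
#' @return list with counts `tp`, `fp`, `fn` and `pairs` (matrix of
#'   detection/truth row indices).
#' @export
match_detections <- function(dets, truths, tol_pos = NULL, tol_scale = 0.5) {
  nd <- if (is.null(dets)) 0L else nrow(dets)
  nt <- if (is.null(truths)) 0L else nrow(truths)
  pairs <- matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("detection", "truth")))
  if (nd == 0L || nt == 0L) {
    return(list(tp = 0L, fp = nd, fn = nt, pairs = pairs))
  }
  tol <- if (is.null(tol_pos)) 0.25 * truths$width else rep(tol_pos, nt)
  taken <- rep(FALSE, nt)
  ord <- order(-dets$score)
  tp <- 0L; fp <- 0L
  for (i in ord) {
    d2 <- (dets$row[i] - truths$row)^2 + (dets$col[i] - truths$col)^2
    ok <- d2 <= tol^2
    if (!is.null(dets$scale_index) && !is.null(truths$scale_index) &&
        any(!is.na(dets$scale_index))) {
      ok <- ok & (is.na(dets$scale_index[i]) |
                    abs(dets$scale_index[i] - truths$scale_index) <= tol_scale)
    }
    cand <- which(ok & !taken)
    if (length(cand) > 0L) {
      j <- cand[which.min(d2[cand])]
      taken[j] <- TRUE
      tp <- tp + 1L
      pairs <- rbind(pairs, c(i, j))
    } else {
      fp <- fp + 1L  # includes duplicate matches to an already-taken truth
    }
  }
  list(tp = tp, fp = fp, fn = sum(!taken), pairs = pairs)
}

#' Precision-recall curve over a score-threshold sweep
#'
#' For each threshold, detections scoring below it are dropped, matching
#' is redone per image, counts are pooled over images, and recall
#' `TP/(TP+FN)` and precision `TP/(TP+FP)` are computed.  When there are
#' no detections at a threshold, precision is reported as 1.
#'
#' @param detections list of per-image detection data frames.
#' @param truths list of per-image ground-truth data frames (same length).
#' @param thresholds sweep values; defaults to every distinct detection
#'   score plus one value above the maximum.
#' @param ... passed to [match_detections()].
#' @return data frame with columns `threshold`, `tp`, `fp`, `fn`,
#'   `recall`, `precision`, ordered by increasing threshold.
#' @export
pr_curve <- function(detections, truths, thresholds = NULL, ...) {
  stopifnot(length(detections) == length(truths))
  n_truth <- sum(vapply(truths, function(t) if (is.null(t)) 0L else nrow(t),
                        integer(1L)))
  if (n_truth == 0L) stop("no ground-truth objects in any image")
  if (is.null(thresholds)) {
    sc <- unlist(lapply(detections, function(d) d$score))
    thresholds <- if (length(sc) == 0L) 1 else sort(unique(c(sc, max(sc) * 1.01 + 1e-9)))
  }
  rows <- lapply(sort(thresholds), function(th) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(detections)) {
      d <- detections[[i]]
      d <- d[d$score >= th, , drop = FALSE]
      m <- match_detections(d, truths[[i]], ...)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    data.frame(threshold = th, tp = tp, fp = fp, fn = fn,
               recall = tp / (tp + fn),
               precision = if (tp + fp == 0L) 1 else tp / (tp + fp))
  })
  do.call(rbind, rows)
}

#' f score from match counts
#'
#' `2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall.
#'
#' @param tp,fp,fn non-negative counts, not all zero.
#' @return scalar in `[0, 1]`.
#' @export
f_score <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fp + fn == 0) stop("f score undefined when tp = fp = fn = 0")
  2 * tp / (2 * tp + fp + fn)
}

#' Equal error rate of a precision-recall sweep
#'
#' The percent error at the score threshold where the number of false
#' positives equals the number of false negatives, reported as
#' `100 * fn / (tp + fn)` at that threshold.  When no row of the curve has
#' an exact crossing, the bracketing thresholds are interpolated linearly.
#'
#' @param curve data frame from [pr_curve()].
#' @return scalar percent.
#' @export
equal_error_rate <- function(curve) {
  if (is.null(curve) || nrow(curve) < 2L) {
    stop("need a curve spanning at least two thresholds")
  }
  curve <- curve[order(curve$threshold), , drop = FALSE]
  diffs <- curve$fp - curve$fn  # decreasing in threshold (more fp at low t)
  err <- 100 * curve$fn / (curve$tp + curve$fn)
  exact <- which(diffs == 0)
  if (length(exact) > 0L) return(err[exact[1L]])
  # fp > fn at low thresholds, fp < fn at high: find the sign change
  cross <- which(diffs[-length(diffs)] > 0 & diffs[-1L] < 0)
  if (length(cross) == 0L) {
    # no crossing inside the sweep: take the threshold minimizing |fp - fn|
    return(err[which.min(abs(diffs))])
  }
  i <- cross[1L]
  w <- diffs[i] / (diffs[i] - diffs[i + 1L])
  (1 - w) * err[i] + w * err[i + 1L]
}

#' Percent classification error
#' @param predictions predicted labels.
#' @param labels true labels (same length).
#' @return percent of mismatches (`NA` predictions count as errors).
#' @export
classification_error <- function(predictions, labels) {
  if (length(predictions) == 0L) stop("empty prediction list")
  if (length(predictions) != length(labels)) {
    stop("predictions and labels have different lengths")
  }
  good <- !is.na(predictions) & as.character(predictions) == as.character(labels)
  100 * sum(!good) / length(labels)
}

#' Read ground-truth annotations from a whitespace-delimited text file
#'
#' Columns: `image` (id), `row`, `col` (object centre), `width`, `height`
#' (pixels) and `scale_index`.  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return data frame with one row per annotated object.
#' @export
read_annotations <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("image", "row", "col", "width", "height", "scale_index")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write ground-truth annotations
#' @param annotations data frame as in [read_annotations()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
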