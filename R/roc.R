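# ROC analysis over the normalized-intensity threshold. Candidate thresholds
# are midpoints between consecutive distinct scores plus one sentinel below
# the minimum and one above the maximum, so the curve always includes both
# degenerate endpoints (sens 1 / spec 0 and sens 0 / spec 1). Presence is
# score > t (strict), matching the detection rule.

# operating point of the rule "positive iff score > t": (sens, spec)
.op_point <- function(scores, labels, t) {
  c(mean(scores[labels] > t), mean(scores[!labels] <= t))
}

#' Build an ROC curve from per-slice scores and truth labels
#'
#' @param scores numeric vector of per-slice detection scores
#'   (see [slice_score()]).
#' @param labels logical vector of histological truth, same length.
#' @return object of class `iph_roc`: `points` (data frame `threshold`,
#'   `sensitivity`, `specificity`, thresholds strictly increasing), `auc`
#'   (trapezoidal area under sensitivity vs 1 - specificity), `n_positive`,
#'   `n_negative`, and the input `scores`/`labels` (kept so operating points
#'   can be recomputed on other thresholds).
#' @export
roc_from_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || length(scores) < 2L)
    stop("scores and labels must have equal length >= 2")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (anyNA(labels)) stop("labels must not contain NA")
  if (!any(labels) || all(labels))
    stop("labels must contain both a positive and a negative slice")
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  pts <- t(vapply(thr, function(t) .op_point(scores, labels, t), numeric(2)))
  points <- data.frame(threshold = thr, sensitivity = pts[, 1],
                       specificity = pts[, 2])
  # threshold ascending => fpr = 1 - spec descending; integrate over fpr
  fpr <- 1 - points$specificity
  sens <- points$sensitivity
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) * (sens[-length(sens)] + sens[-1]) / 2)
  structure(
    list(points = points, auc = auc,
         n_positive = sum(labels), n_negative = sum(!labels),
         scores = as.numeric(scores), labels = labels),
    class = "iph_roc"
  )
}

#' @export
print.iph_roc <- function(x, ...) {
  cat(sprintf("<iph_roc> %d+ / %d- slices, %d operating points, AUC = %.3f\n",
              x$n_positive, x$n_negative, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.iph_roc <- function(x, ...) {
  plot(1 - x$points$specificity, x$points$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Youden-optimal threshold on a grid
#'
#' ROC candidate thresholds are snapped to the nearest multiple of
#' `grid_step` (duplicates merged, operating points recomputed at the lattice
#' value); the returned threshold maximizes Youden's J = sensitivity +
#' specificity - 1, with ties broken toward the LARGER threshold (higher
#' specificity, i.e. fewer false positives). The 0.1 default lattice matches
#' the one-decimal precision at which optimized thresholds are conventionally
#' reported and stabilizes ties.
#'
#' @param roc an [roc_from_scores()] result.
#' @param grid_step positive lattice step for candidate thresholds
#'   (default 0.1).
#' @return object of class `threshold_choice`: `threshold`, `youden`,
#'   `sensitivity`, `specificity`, and the evaluated `candidates` data frame.
#' @export
youden_optimal <- function(roc, grid_step = 0.1) {
  stopifnot(inherits(roc, "iph_roc"))
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("grid_step must be positive")
  cand <- sort(unique(round(roc$points$threshold / grid_step) * grid_step))
  pts <- t(vapply(cand, function(t) .op_point(roc$scores, roc$labels, t),
                  numeric(2)))
  j <- pts[, 1] + pts[, 2] - 1
  best <- max(which(j == max(j)))   # ties -> larger threshold
  structure(
    list(threshold = cand[best], youden = j[best],
         sensitivity = pts[best, 1], specificity = pts[best, 2],
         grid_step = grid_step,
         candidates = data.frame(threshold = cand, sensitivity = pts[, 1],
                                 specificity = pts[, 2], youden = j)),
    class = "threshold_choice"
  )
}

#' @export
print.threshold_choice <- function(x, ...) {
  cat(sprintf(
    "<threshold_choice> t = %.4g (J = %.3f; sens %.3f, spec %.3f; grid %.3g)\n",
    x$threshold, x$youden, x$sensitivity, x$specificity, x$grid_step))
  invisible(x)
}
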