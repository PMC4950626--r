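# The core estimator: fit the IPH presence threshold to labeled slices.
# `iph_fit()` wraps ROC construction + Youden-index maximization into a
# classed model object with the usual methods.

#' Fit the IPH detection threshold by Youden-index maximization
#'
#' Builds an ROC curve of slice-level IPH presence over the normalized
#' intensity threshold and picks the lattice threshold maximizing Youden's
#' J = sensitivity + specificity - 1 (ties toward the larger threshold).
#'
#' @param x per-slice detection scores (numeric), or a formula
#'   `truth ~ score` evaluated in `data`.
#' @param ... passed between methods.
#' @return an object of class `iph_fit` with components `threshold`, `youden`,
#'   `sensitivity`, `specificity`, `auc`, `roc` (the [roc_from_scores()]
#'   curve), `choice` (the [youden_optimal()] result) and `call`. Supports
#'   `print()`, `summary()`, `coef()` (the threshold), `predict()` (presence
#'   calls for new scores) and `plot()` (ROC with the operating point).
#' @examples
#' set.seed(1)
#' score <- c(rnorm(30, 1.05, 0.05), rnorm(30, 1.65, 0.08))
#' truth <- rep(c(FALSE, TRUE), each = 30)
#' fit <- iph_fit(score, truth)
#' coef(fit)
#' table(predicted = predict(fit, score), truth)
#' @export
iph_fit <- function(x, ...) UseMethod("iph_fit")

#' @rdname iph_fit
#' @param truth logical vector of histological IPH presence.
#' @param grid_step threshold lattice step (default 0.1), see
#'   [youden_optimal()].
#' @export
iph_fit.default <- function(x, truth, grid_step = 0.1, ...) {
  roc <- roc_from_scores(x, truth)
  choice <- youden_optimal(roc, grid_step)
  structure(
    list(threshold = choice$threshold, youden = choice$youden,
         sensitivity = choice$sensitivity, specificity = choice$specificity,
         auc = roc$auc, roc = roc, choice = choice, grid_step = grid_step,
         call = match.call()),
    class = "iph_fit"
  )
}

#' @rdname iph_fit
#' @param formula a formula `truth ~ score`.
#' @param data data frame containing the formula variables.
#' @export
iph_fit.formula <- function(formula, data, grid_step = 0.1, ...) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) stop("formula must be of the form truth ~ score")
  fit <- iph_fit.default(mf[[2L]], mf[[1L]], grid_step = grid_step)
  fit$call <- match.call()
  fit
}

#' @export
print.iph_fit <- function(x, ...) {
  cat("IPH threshold fit (Youden-optimal)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  slices: %d positive / %d negative   AUC: %.3f\n",
              x$roc$n_positive, x$roc$n_negative, x$auc))
  cat(sprintf("  threshold: %.4g x reference   J = %.3f (sens %.3f, spec %.3f)\n",
              x$threshold, x$youden, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
summary.iph_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.iph_fit")
}

#' @export
print.summary.iph_fit <- function(x, ...) {
  print(x$fit)
  cat("\nLattice candidates:\n")
  print(x$fit$choice$candidates, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.iph_fit <- function(object, ...) c(threshold = object$threshold)

#' @rdname iph_fit
#' @param object a fitted `iph_fit`.
#' @param newdata numeric vector of new slice scores; defaults to the
#'   training scores.
#' @param type `"presence"` (logical calls, score strictly above the fitted
#'   threshold) or `"score"` (the scores, unchanged).
#' @export
predict.iph_fit <- function(object, newdata = NULL,
                            type = c("presence", "score"), ...) {
  type <- match.arg(type)
  s <- if (is.null(newdata)) object$roc$scores else as.numeric(newdata)
  if (type == "score") s else s > object$threshold
}

#' @export
plot.iph_fit <- function(x, ...) {
  plot(x$roc, ...)
  points(1 - x$specificity, x$sensitivity, pch = 19, col = "red")
  invisible(x)
}
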