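# Patient-level leave-one-out cross-validation: each patient's slices are
# classified with the threshold fitted on all OTHER patients, and the held-out
# predictions are pooled (micro-averaged) before computing sensitivity,
# specificity and the Pearson correlation of detected vs histological IPH
# area. Pooling, rather than averaging per-fold metrics, is used because a
# one-patient fold often has a single truth class.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient; `NA` with a warning when either
#'   vector has zero variance (correlation undefined).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Sensitivity, specificity and Youden's index of binary predictions
#'
#' @param pred,truth logical vectors of equal length; `truth` must contain
#'   both classes.
#' @return named numeric vector `(sensitivity, specificity, youden)` with
#'   sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#'   youden = sensitivity + specificity - 1.
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  if (!any(truth) || all(truth)) stop("truth must contain both classes")
  sens <- sum(pred & truth) / sum(truth)
  spec <- sum(!pred & !truth) / sum(!truth)
  c(sensitivity = sens, specificity = spec, youden = sens + spec - 1)
}

#' Patient-level leave-one-out cross-validation of the detection pipeline
#'
#' For each patient, the threshold is fitted ([iph_fit()]) on every other
#' patient's included slices and applied to the held-out patient's slices;
#' predictions are pooled across folds. Detected areas are recomputed per
#' held-out slice with [detect_iph()] at the fold threshold.
#'
#' @param dataset an `iph_dataset` from [prepare_dataset()].
#' @param subset a [subset_spec()] selecting the analysis subset; filtering by
#'   histological truth is applied to training and held-out slices alike.
#' @param grid_step threshold lattice step (default 0.1).
#' @param min_area_px presence rule passed to [detect_iph()].
#' @return object of class `iph_cv`: pooled `sensitivity` and `specificity`,
#'   `pearson_r_all` (detected vs truth area over all pooled slices),
#'   `pearson_r_positive` (truth-positive slices only), `fold_thresholds`
#'   (named per patient), `threshold_spread` (max - min over folds),
#'   `n_slices`, `n_positive`, and the pooled per-slice `predictions`.
#' @export
iph_loocv <- function(dataset, subset = subset_spec(), grid_step = 0.1,
                      min_area_px = 0L) {
  stopifnot(inherits(dataset, "iph_dataset"))
  tab <- apply_subset(dataset$table, subset)
  patients <- unique(tab$patient_id)
  if (length(patients) < 2L)
    stop("leave-one-out cross-validation needs >= 2 patients with included slices")

  folds <- numeric(0)
  preds <- list()
  for (p in patients) {
    train <- tab[tab$patient_id != p, , drop = FALSE]
    if (!any(train$truth_present) || all(train$truth_present))
      stop("training fold for held-out patient ", p,
           " has a single truth class; cannot fit a threshold")
    fit <- iph_fit(train$score, train$truth_present, grid_step = grid_step)
    folds[p] <- fit$threshold
    test <- tab[tab$patient_id == p, , drop = FALSE]
    det_area <- vapply(seq_len(nrow(test)), function(i) {
      key <- paste(test$patient_id[i], test$slice_index[i], sep = "/")
      ref <- reference_measurement(dataset$ref_kind, test$ref_value[i],
                                   test$ref_n[i], valid = TRUE)
      detect_iph(dataset$slices[[key]], dataset$annotations[[key]], ref,
                 fit$threshold, min_area_px = min_area_px)$area_mm2
    }, numeric(1))
    preds[[p]] <- data.frame(
      patient_id = test$patient_id, slice_index = test$slice_index,
      threshold = fit$threshold, score = test$score,
      pred_present = test$score > fit$threshold,
      detected_area_mm2 = det_area,
      truth_present = test$truth_present,
      truth_area_mm2 = test$truth_area_mm2,
      stringsAsFactors = FALSE
    )
  }
  pooled <- do.call(rbind, preds)
  rownames(pooled) <- NULL

  tp <- sum(pooled$pred_present & pooled$truth_present)
  fn <- sum(!pooled$pred_present & pooled$truth_present)
  tn <- sum(!pooled$pred_present & !pooled$truth_present)
  fp <- sum(pooled$pred_present & !pooled$truth_present)
  r_all <- if (nrow(pooled) >= 3L)
    pearson_r(pooled$detected_area_mm2, pooled$truth_area_mm2) else NA_real_
  pos <- pooled[pooled$truth_present, , drop = FALSE]
  r_pos <- if (nrow(pos) >= 3L)
    pearson_r(pos$detected_area_mm2, pos$truth_area_mm2) else NA_real_

  structure(
    list(
      reference_kind = dataset$ref_kind,
      subset = subset,
      fold_thresholds = folds,
      threshold_spread = max(folds) - min(folds),
      pooled_sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      pooled_specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      pearson_r_all = r_all,
      pearson_r_positive = r_pos,
      n_slices = nrow(pooled),
      n_positive = sum(pooled$truth_present),
      predictions = pooled
    ),
    class = "iph_cv"
  )
}

#' @export
print.iph_cv <- function(x, ...) {
  cat(sprintf(
    "IPH leave-one-out cross-validation (%s reference)\n", x$reference_kind))
  print(x$subset)
  cat(sprintf("  %d slices (%d IPH+), %d folds\n",
              x$n_slices, x$n_positive, length(x$fold_thresholds)))
  cat(sprintf("  fold thresholds: %.4g-%.4g (spread %.4g)\n",
              min(x$fold_thresholds), max(x$fold_thresholds),
              x$threshold_spread))
  cat(sprintf("  pooled sensitivity %.3f, specificity %.3f\n",
              x$pooled_sensitivity, x$pooled_specificity))
  cat(sprintf("  Pearson r (area): %.3f all slices, %.3f IPH+ only\n",
              x$pearson_r_all, x$pearson_r_positive))
  invisible(x)
}

#' @export
summary.iph_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold thresholds:\n")
  print(object$fold_thresholds)
  invisible(object)
}
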