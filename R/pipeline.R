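# Wiring: cohort -> matched, reference-normalized, scored dataset -> full-data
# threshold table and cross-validated performance table (the two summary
# tables of a threshold-optimization study).

#' Prepare the labeled per-slice dataset for one reference kind
#'
#' Matches histology onto slices, computes the chosen reference and the
#' per-slice detection score, and drops slices whose reference is invalid
#' (e.g. SCM outside the reference ROI) with a message stating how many.
#'
#' @param cohort an `iph_cohort`.
#' @param ref_kind `"scm"`, `"adjacent_muscle"` or `"local_median"`.
#' @param roi_diameter_mm reference ROI diameter, mm (default 40).
#' @param half_window_mm histology matching window, mm (default 0.5).
#' @return object of class `iph_dataset`: `table` (one row per included
#'   matched slice, with truth fields, `ref_value`, `ref_n`, `score`), the
#'   cohort's `slices`/`annotations`, `ref_kind`, `roi_diameter_mm`, and
#'   `n_excluded_invalid_ref`.
#' @export
prepare_dataset <- function(cohort, ref_kind = "adjacent_muscle",
                            roi_diameter_mm = 40, half_window_mm = 0.5) {
  stopifnot(inherits(cohort, "iph_cohort"))
  ref_kind <- match.arg(ref_kind, REFERENCE_KINDS)
  matched <- match_sections(slice_table(cohort), cohort$histology,
                            half_window_mm = half_window_mm)
  if (!nrow(matched)) stop("no slice matched a histology section")
  ref_value <- ref_n <- score <- numeric(nrow(matched))
  valid <- logical(nrow(matched))
  for (i in seq_len(nrow(matched))) {
    key <- paste(matched$patient_id[i], matched$slice_index[i], sep = "/")
    sl <- cohort$slices[[key]]; an <- cohort$annotations[[key]]
    if (is.null(sl) || is.null(an)) stop("no image/annotation for ", key)
    ref <- compute_reference(sl, an, ref_kind, roi_diameter_mm)
    valid[i] <- ref$valid
    if (ref$valid) {
      ref_value[i] <- ref$value
      ref_n[i] <- ref$n_pixels
      score[i] <- slice_score(sl, an, ref)
    }
  }
  if (any(!valid))
    message(sum(!valid), " of ", length(valid), " matched slices excluded: ",
            ref_kind, " reference invalid")
  tab <- matched[valid, , drop = FALSE]
  tab$ref_value <- ref_value[valid]
  tab$ref_n <- as.integer(ref_n[valid])
  tab$score <- score[valid]
  rownames(tab) <- NULL
  structure(
    list(table = tab, slices = cohort$slices,
         annotations = cohort$annotations, ref_kind = ref_kind,
         roi_diameter_mm = roi_diameter_mm,
         n_excluded_invalid_ref = sum(!valid)),
    class = "iph_dataset"
  )
}

#' @export
print.iph_dataset <- function(x, ...) {
  cat(sprintf(
    "<iph_dataset> %s reference | %d slices (%d IPH+), %d excluded (invalid reference)\n",
    x$ref_kind, nrow(x$table), sum(x$table$truth_present),
    x$n_excluded_invalid_ref))
  invisible(x)
}

#' Full evaluation over references and analysis subsets
#'
#' For every reference kind and every subset (area cutoffs crossed with
#' with/without heavily-calcified exclusion), fits the full-data
#' Youden-optimal threshold with its AUC, and runs patient-level leave-one-out
#' cross-validation.
#'
#' @param cohort an `iph_cohort`.
#' @param ref_kinds reference kinds to evaluate.
#' @param area_cutoffs_mm2 minimum-IPH-area cutoffs; the defaults are 0 plus
#'   [area_cutoff()] at x = 1 and x = 1.5.
#' @param exclude_ca logical values of the heavily-calcified exclusion to
#'   cross with the cutoffs.
#' @param grid_step,roi_diameter_mm,half_window_mm,calcified_cutoff see the
#'   underlying functions.
#' @return object of class `iph_evaluation` with data frames `thresholds`
#'   (subset x reference: n, n_positive, auc, threshold), `performance`
#'   (subset x reference: pooled LOOCV sensitivity, specificity, Pearson r
#'   over all and over IPH-positive slices, fold-threshold spread) and
#'   `folds` (per reference x subset x patient threshold).
#' @export
evaluate_cohort <- function(cohort,
                            ref_kinds = REFERENCE_KINDS,
                            area_cutoffs_mm2 = c(0, area_cutoff(1),
                                                 area_cutoff(1.5)),
                            exclude_ca = c(FALSE, TRUE),
                            grid_step = 0.1, roi_diameter_mm = 40,
                            half_window_mm = 0.5, calcified_cutoff = 0.5) {
  stopifnot(inherits(cohort, "iph_cohort"))
  ref_kinds <- match.arg(ref_kinds, REFERENCE_KINDS, several.ok = TRUE)
  thr_rows <- perf_rows <- fold_rows <- list()
  for (rk in ref_kinds) {
    ds <- prepare_dataset(cohort, rk, roi_diameter_mm, half_window_mm)
    for (ca in exclude_ca) {
      for (amin in area_cutoffs_mm2) {
        sp <- subset_spec(amin, exclude_heavily_calcified = ca,
                          calcified_cutoff = calcified_cutoff)
        tab <- apply_subset(ds$table, sp)
        key <- sprintf("%s|ca=%s|min=%.4g", rk, ca, amin)
        fit <- iph_fit(tab$score, tab$truth_present, grid_step = grid_step)
        cv <- iph_loocv(ds, subset = sp, grid_step = grid_step)
        thr_rows[[key]] <- data.frame(
          reference = rk, exclude_calcified = ca, min_area_mm2 = amin,
          n = nrow(tab), n_positive = sum(tab$truth_present),
          auc = fit$auc, threshold = fit$threshold,
          stringsAsFactors = FALSE)
        perf_rows[[key]] <- data.frame(
          reference = rk, exclude_calcified = ca, min_area_mm2 = amin,
          sensitivity = cv$pooled_sensitivity,
          specificity = cv$pooled_specificity,
          pearson_r_all = cv$pearson_r_all,
          pearson_r_positive = cv$pearson_r_positive,
          threshold_spread = cv$threshold_spread,
          stringsAsFactors = FALSE)
        fold_rows[[key]] <- data.frame(
          reference = rk, exclude_calcified = ca, min_area_mm2 = amin,
          patient_id = names(cv$fold_thresholds),
          threshold = unname(cv$fold_thresholds),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(thresholds = .rbind_reset(thr_rows),
         performance = .rbind_reset(perf_rows),
         folds = .rbind_reset(fold_rows)),
    class = "iph_evaluation"
  )
}

.rbind_reset <- function(rows) {
  if (!length(rows)) return(data.frame())
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' @export
print.iph_evaluation <- function(x, ...) {
  cat("Full-data optimized thresholds:\n")
  print(x$thresholds, digits = 3, row.names = FALSE)
  cat("\nCross-validated performance:\n")
  print(x$performance, digits = 3, row.names = FALSE)
  invisible(x)
}
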