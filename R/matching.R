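# Histology-to-MR fusion. MR slices are 1 mm thick while histology sections
# are cut every 0.5-1 mm, so one slice may own several sections. Both carry a
# signed longitudinal distance to the carotid bifurcation; a section goes to
# the nearest slice of the same patient within a tolerance window, and slice
# truth is fused as: present if ANY matched section has IPH, area = mean of
# section areas, calcified fraction = IPH-area-weighted mean.

#' Match histology sections onto MR slices by longitudinal position
#'
#' @param slices data frame with columns `patient_id`, `slice_index`,
#'   `position_mm` (one row per MR slice), or an `iph_cohort`.
#' @param sections histology data frame as from [read_histology()].
#' @param half_window_mm maximum |position difference| for a match, mm.
#'   Default 0.5, half the 1 mm MR slice thickness (nearest-slab rule).
#' @return data frame with one row per matched slice: `patient_id`,
#'   `slice_index`, `position_mm`, `truth_present`, `truth_area_mm2`,
#'   `truth_calcified_fraction`, `n_sections`. Sections that fall in no
#'   slice's window are reported via a message and attached as
#'   `attr(, "unmatched")`; slices with no section are dropped.
#' @export
match_sections <- function(slices, sections, half_window_mm = 0.5) {
  if (inherits(slices, "iph_cohort")) slices <- slice_table(slices)
  stopifnot(is.data.frame(slices),
            all(c("patient_id", "slice_index", "position_mm") %in% names(slices)))
  sections <- .validate_histology(sections)
  if (!is.numeric(half_window_mm) || half_window_mm <= 0)
    stop("half_window_mm must be positive")
  dup <- duplicated(sections[c("patient_id", "position_mm")])
  if (any(dup))
    stop("duplicate (patient, position) histology sections at row(s): ",
         paste(which(dup), collapse = ", "))

  assigned <- rep(NA_integer_, nrow(sections))   # index into slices
  for (k in seq_len(nrow(sections))) {
    cand <- which(slices$patient_id == sections$patient_id[k])
    if (!length(cand)) next
    d <- abs(slices$position_mm[cand] - sections$position_mm[k])
    i <- cand[which.min(d)]
    if (min(d) <= half_window_mm) assigned[k] <- i
  }
  unmatched <- sections[is.na(assigned), , drop = FALSE]
  if (nrow(unmatched))
    message(nrow(unmatched), " histology section(s) matched no slice within ",
            half_window_mm, " mm and were dropped")

  rows <- lapply(unique(assigned[!is.na(assigned)]), function(i) {
    sec <- sections[which(assigned == i), , drop = FALSE]
    tot_area <- sum(sec$iph_area_mm2)
    data.frame(
      patient_id = slices$patient_id[i],
      slice_index = slices$slice_index[i],
      position_mm = slices$position_mm[i],
      truth_present = any(sec$iph_present),
      truth_area_mm2 = mean(sec$iph_area_mm2),
      truth_calcified_fraction = if (tot_area > 0)
        sum(sec$iph_area_mm2 * sec$calcified_fraction) / tot_area else 0,
      n_sections = nrow(sec),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), slice_index = integer(),
                      position_mm = numeric(), truth_present = logical(),
                      truth_area_mm2 = numeric(),
                      truth_calcified_fraction = numeric(),
                      n_sections = integer())
  } else {
    out <- out[order(out$patient_id, out$slice_index), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Specify an analysis subset
#'
#' The six analysis subsets cross a minimum histological IPH area (0, or the
#' cutoffs from [area_cutoff()]) with exclusion of heavily calcified IPH.
#' Comparisons follow the source rules exactly: a slice is removed when IPH is
#' present with area strictly below `min_iph_area_mm2`, or (when enabled)
#' calcified fraction strictly above `calcified_cutoff`. IPH-absent slices
#' are never removed.
#'
#' @param min_iph_area_mm2 minimum histological IPH area retained, mm^2.
#' @param exclude_heavily_calcified drop slices whose IPH is more than
#'   `calcified_cutoff` calcified.
#' @param calcified_cutoff calcified-fraction cutoff in (0, 1], default 0.5.
#' @return object of class `subset_spec`.
#' @export
subset_spec <- function(min_iph_area_mm2 = 0, exclude_heavily_calcified = FALSE,
                        calcified_cutoff = 0.5) {
  if (!is.numeric(min_iph_area_mm2) || min_iph_area_mm2 < 0)
    stop("min_iph_area_mm2 must be >= 0")
  if (!is.numeric(calcified_cutoff) || calcified_cutoff <= 0 ||
      calcified_cutoff > 1)
    stop("calcified_cutoff must be in (0, 1]")
  structure(
    list(min_iph_area_mm2 = as.numeric(min_iph_area_mm2),
         exclude_heavily_calcified = isTRUE(exclude_heavily_calcified),
         calcified_cutoff = as.numeric(calcified_cutoff)),
    class = "subset_spec"
  )
}

#' @export
print.subset_spec <- function(x, ...) {
  cat(sprintf("<subset> IPH area >= %.4g mm^2%s\n", x$min_iph_area_mm2,
              if (x$exclude_heavily_calcified)
                sprintf(", excluding IPH > %.0f%% calcified",
                        100 * x$calcified_cutoff) else ""))
  invisible(x)
}

#' Filter a matched dataset to an analysis subset
#'
#' Idempotent; the two exclusion rules commute; retained rows are unchanged.
#'
#' @param matched data frame from [match_sections()].
#' @param spec a [subset_spec()].
#' @return the filtered data frame.
#' @export
apply_subset <- function(matched, spec = subset_spec()) {
  stopifnot(inherits(spec, "subset_spec"))
  drop <- matched$truth_present &
    (matched$truth_area_mm2 < spec$min_iph_area_mm2 |
       (spec$exclude_heavily_calcified &
          matched$truth_calcified_fraction > spec$calcified_cutoff))
  out <- matched[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Small-IPH area cutoff
#'
#' The area of a disk `x` acquired-resolution pixels in radius,
#' `pi * (resolution * x)^2`: the histological IPH size below which in-vivo
#' detection is not expected, given the acquired (not reconstructed) in-plane
#' resolution. With the 0.63 mm acquisition, `x = 1` and `x = 1.5` give
#' about 1.25 and 2.81 mm^2.
#'
#' @param x resolution multiplier (> 0).
#' @param acquired_resolution_mm acquired in-plane resolution, mm
#'   (default 0.63).
#' @return cutoff area in mm^2.
#' @export
area_cutoff <- function(x, acquired_resolution_mm = 0.63) {
  if (!is.numeric(x) || any(x <= 0)) stop("x must be positive")
  if (!is.numeric(acquired_resolution_mm) || acquired_resolution_mm <= 0)
    stop("acquired_resolution_mm must be positive")
  pi * (acquired_resolution_mm * x)^2
}
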