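# Reference intensities used to normalize each slice. Surface coils make raw
# MP-RAGE intensities incomparable across slices and patients, so a pixel is
# only meaningful as a ratio to a reference tissue:
#   scm             mean intensity of the sternocleidomastoid muscle, restricted
#                   to the part inside a 4 cm circular ROI centered at the lumen
#   adjacent_muscle mean intensity of a nearby deep muscle (e.g. scalene) drawn
#                   isointense with normal carotid wall (no ROI intersection --
#                   the polygon is already local)
#   local_median    median intensity over the whole 4 cm ROI; needs no manual
#                   muscle ROI, so it supports fully automatic pipelines
# Invalidity (absent polygon, empty intersection) is a value, not an error:
# such slices are excluded from analyses using that reference, mirroring how
# slices whose SCM lies outside the ROI are dropped.

REFERENCE_KINDS <- c("scm", "adjacent_muscle", "local_median")

#' Construct a reference measurement
#'
#' @param kind one of `"scm"`, `"adjacent_muscle"`, `"local_median"`.
#' @param value mean/median reference intensity (ignored when invalid).
#' @param n_pixels number of pixels the value was computed over.
#' @param valid whether the reference is usable for this slice.
#' @return object of class `reference_measurement`.
#' @export
reference_measurement <- function(kind, value = NA_real_, n_pixels = 0L,
                                  valid = FALSE) {
  kind <- match.arg(kind, REFERENCE_KINDS)
  if (isTRUE(valid) && (!is.finite(value) || value <= 0 || n_pixels < 1L))
    stop("a valid reference needs value > 0 and n_pixels >= 1")
  structure(
    list(kind = kind, value = as.numeric(value),
         n_pixels = as.integer(n_pixels), valid = isTRUE(valid)),
    class = "reference_measurement"
  )
}

#' @export
print.reference_measurement <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<reference> %s = %.4g over %d px\n", x$kind, x$value, x$n_pixels))
  else
    cat(sprintf("<reference> %s: invalid (slice excluded for this reference)\n",
                x$kind))
  invisible(x)
}

.mask_mean_reference <- function(kind, slice, mask) {
  n <- sum(mask)
  if (n == 0L) return(reference_measurement(kind, valid = FALSE))
  reference_measurement(kind, mean(slice$pixels[mask]), n, valid = TRUE)
}

#' SCM mean reference
#'
#' Mean intensity over the intersection of the SCM polygon with the circular
#' ROI (default diameter 40 mm) centered at the lumen. Invalid when the SCM
#' polygon is absent or lies entirely outside the ROI; such slices are
#' excluded from SCM-referenced analyses.
#'
#' @param slice an [image_slice()].
#' @param ann matching [annotation_set()].
#' @param roi_diameter_mm reference ROI diameter, mm (default 40).
#' @return a [reference_measurement()].
#' @export
scm_reference <- function(slice, ann, roi_diameter_mm = 40) {
  validate_image_slice(slice)
  if (is.null(ann$scm)) return(reference_measurement("scm", valid = FALSE))
  mask <- rasterize_polygon(ann$scm, slice) &
    rasterize_circle(ann$lumen_center, roi_diameter_mm, slice)
  .mask_mean_reference("scm", slice, mask)
}

#' Adjacent-muscle mean reference
#'
#' Mean intensity inside the adjacent-muscle polygon (no ROI intersection:
#' the polygon is drawn next to the artery already). Invalid when absent or
#' when the polygon rasterizes to no pixel.
#'
#' @inheritParams scm_reference
#' @return a [reference_measurement()].
#' @export
adjacent_muscle_reference <- function(slice, ann) {
  validate_image_slice(slice)
  if (is.null(ann$adjacent_muscle))
    return(reference_measurement("adjacent_muscle", valid = FALSE))
  mask <- rasterize_polygon(ann$adjacent_muscle, slice)
  .mask_mean_reference("adjacent_muscle", slice, mask)
}

#' Local-median reference
#'
#' Median intensity over all pixels inside the circular ROI centered at the
#' lumen. Even pixel counts use the midpoint of the two central order
#' statistics. Always valid when the ROI touches the image; a lumen center
#' off the image entirely is an error.
#'
#' @inheritParams scm_reference
#' @return a [reference_measurement()].
#' @export
local_median_reference <- function(slice, ann, roi_diameter_mm = 40) {
  validate_image_slice(slice)
  mask <- rasterize_circle(ann$lumen_center, roi_diameter_mm, slice)
  n <- sum(mask)
  if (n == 0L)
    stop("local-median ROI does not intersect the image (lumen center off-image)")
  reference_measurement("local_median", stats::median(slice$pixels[mask]), n,
                        valid = TRUE)
}

#' Compute a reference of a given kind
#'
#' @inheritParams scm_reference
#' @param kind reference kind; see [reference_measurement()].
#' @return a [reference_measurement()].
#' @export
compute_reference <- function(slice, ann, kind, roi_diameter_mm = 40) {
  kind <- match.arg(kind, REFERENCE_KINDS)
  switch(kind,
    scm = scm_reference(slice, ann, roi_diameter_mm),
    adjacent_muscle = adjacent_muscle_reference(slice, ann),
    local_median = local_median_reference(slice, ann, roi_diameter_mm)
  )
}
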