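# IPH segmentation on one slice: pixels inside the reviewer-drawn outer-wall
# contour whose intensity strictly exceeds threshold x reference ("exceeded"
# is a strict inequality; with continuous intensities ties have measure zero).
# No connected-component filtering or morphology is applied -- the method is
# pure thresholding by design.

#' Detect IPH on one slice by normalized-intensity thresholding
#'
#' @param slice an [image_slice()].
#' @param ann matching [annotation_set()]; its `outer_wall` polygon confines
#'   the search region.
#' @param ref a valid [reference_measurement()] for this slice.
#' @param threshold positive normalized-intensity cutoff `t`: a pixel is IPH
#'   when `intensity > t * ref$value`.
#' @param min_area_px presence rule: IPH is called present when the mask has
#'   strictly more than `min_area_px` pixels (default 0: any supra-threshold
#'   pixel counts).
#' @return object of class `iph_detection`: `mask` (logical matrix),
#'   `presence`, `area_mm2` (mask pixels x pixel area), `max_norm_intensity`
#'   (max over outer-wall pixels of intensity / reference), plus the inputs'
#'   identifiers.
#' @export
detect_iph <- function(slice, ann, ref, threshold, min_area_px = 0L) {
  validate_image_slice(slice)
  stopifnot(inherits(ref, "reference_measurement"))
  if (!isTRUE(ref$valid))
    stop("invalid reference for patient ", slice$patient_id, " slice ",
         slice$slice_index, ": filter such slices out before detection")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive number")
  if (is.null(ann$outer_wall)) stop("outer_wall polygon is required")
  wall <- rasterize_polygon(ann$outer_wall, slice)
  mask <- wall & (slice$pixels > threshold * ref$value)
  area <- sum(mask) * slice$spacing_mm[1] * slice$spacing_mm[2]
  maxn <- if (any(wall)) max(slice$pixels[wall]) / ref$value else 0
  structure(
    list(
      patient_id = slice$patient_id,
      slice_index = slice$slice_index,
      threshold = threshold,
      reference = ref,
      mask = mask,
      presence = sum(mask) > min_area_px,
      area_mm2 = area,
      max_norm_intensity = maxn
    ),
    class = "iph_detection"
  )
}

#' @export
print.iph_detection <- function(x, ...) {
  cat(sprintf(
    "<iph_detection> patient %s slice %d | t = %.3g x %s | %s, area %.3f mm^2 (max norm %.3f)\n",
    x$patient_id, x$slice_index, x$threshold, x$reference$kind,
    if (x$presence) "IPH present" else "IPH absent",
    x$area_mm2, x$max_norm_intensity
  ))
  invisible(x)
}

#' Per-slice detection score
#'
#' The maximum normalized intensity over outer-wall pixels. Comparing this
#' scalar to a threshold `t` reproduces the presence call of [detect_iph()]
#' for every `t` simultaneously, which is what the ROC sweep needs.
#'
#' @inheritParams detect_iph
#' @return a single number: `max(intensity inside outer wall) / ref$value`.
#' @export
slice_score <- function(slice, ann, ref) {
  validate_image_slice(slice)
  stopifnot(inherits(ref, "reference_measurement"))
  if (!isTRUE(ref$valid))
    stop("invalid reference for patient ", slice$patient_id, " slice ",
         slice$slice_index)
  if (is.null(ann$outer_wall)) stop("outer_wall polygon is required")
  wall <- rasterize_polygon(ann$outer_wall, slice)
  if (!any(wall)) return(0)
  max(slice$pixels[wall]) / ref$value
}
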