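# One axial grayscale MR slice: the unit of IPH detection.

#' Construct an image slice
#'
#' @param patient_id patient identifier (string).
#' @param slice_index non-negative integer slice index within the patient.
#' @param position_mm signed longitudinal distance from the carotid
#'   bifurcation in mm (distal positive).
#' @param pixels numeric matrix of non-negative intensities (arbitrary units),
#'   at least 2 x 2.
#' @param spacing_mm length-2 positive numeric: (row, column) pixel size, mm.
#' @return an object of class `image_slice`.
#' @export
image_slice <- function(patient_id, slice_index, position_mm, pixels, spacing_mm) {
  obj <- structure(
    list(
      patient_id = as.character(patient_id),
      slice_index = as.integer(slice_index),
      position_mm = as.numeric(position_mm),
      pixels = pixels,
      spacing_mm = as.numeric(spacing_mm)
    ),
    class = "image_slice"
  )
  validate_image_slice(obj)
}

#' @rdname image_slice
#' @param x an `image_slice`.
#' @export
validate_image_slice <- function(x) {
  stopifnot(inherits(x, "image_slice"))
  if (length(x$patient_id) != 1L || is.na(x$patient_id) || !nzchar(x$patient_id))
    stop("patient_id must be a non-empty string")
  if (length(x$slice_index) != 1L || is.na(x$slice_index) || x$slice_index < 0L)
    stop("slice_index must be a non-negative integer")
  if (length(x$position_mm) != 1L || !is.finite(x$position_mm))
    stop("position_mm must be a finite number")
  if (!is.matrix(x$pixels) || !is.numeric(x$pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(x$pixels) < 2L || ncol(x$pixels) < 2L)
    stop("pixels must have at least 2 rows and 2 columns")
  if (!all(is.finite(x$pixels)) || any(x$pixels < 0))
    stop("pixel intensities must be finite and non-negative")
  if (length(x$spacing_mm) != 2L || !all(is.finite(x$spacing_mm)) ||
      any(x$spacing_mm <= 0))
    stop("spacing_mm must be two positive numbers (row, column)")
  x
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf(
    "<image_slice> patient %s, slice %d at %+.2f mm | %d x %d px @ %.3g x %.3g mm\n",
    x$patient_id, x$slice_index, x$position_mm,
    nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2]
  ))
  invisible(x)
}

.sidecar_path <- function(path) {
  sub("\\.(nii\\.gz|nii|tiff?|tif)$", ".json", path, ignore.case = TRUE)
}

#' Write a slice to disk
#'
#' NIfTI (`.nii` / `.nii.gz`, float64, spacing in the header) or 16-bit
#' grayscale TIFF (integer-valued intensities in 0..65535 only). A JSON
#' sidecar carrying `patient_id`, `slice_index`, `position_mm` and
#' `spacing_mm` is always written.
#'
#' @param slice an [image_slice()].
#' @param path output image path; format chosen by extension.
#' @param sidecar sidecar path; default replaces the image extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path, sidecar = .sidecar_path(path)) {
  validate_image_slice(slice)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    im <- RNifti::asNifti(slice$pixels)
    RNifti::pixdim(im) <- slice$spacing_mm
    RNifti::writeNifti(im, path, datatype = "double")
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    px <- slice$pixels
    if (any(px != round(px)) || any(px > 65535))
      stop("TIFF output requires integer intensities in 0..65535; use NIfTI")
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else {
    stop("unsupported image extension (use .nii, .nii.gz, .tif or .tiff): ", path)
  }
  jsonlite::write_json(
    list(
      patient_id = slice$patient_id,
      slice_index = slice$slice_index,
      position_mm = slice$position_mm,
      spacing_mm = slice$spacing_mm
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a slice from disk
#'
#' Intensities are returned exactly as stored, without rescaling. Spacing is
#' taken from the sidecar when present there, else from the NIfTI header;
#' a TIFF with no sidecar spacing is a metadata error.
#'
#' @param path NIfTI or 16-bit grayscale TIFF image path.
#' @param sidecar JSON sidecar path with `patient_id`, `slice_index`,
#'   `position_mm` and (optionally, for NIfTI) `spacing_mm`.
#' @return an [image_slice()].
#' @export
read_slice <- function(path, sidecar = .sidecar_path(path)) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("patient_id", "slice_index", "position_mm")) {
    if (is.null(meta[[f]])) stop("sidecar missing required field '", f, "': ", sidecar)
  }
  spacing <- meta$spacing_mm
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    im <- RNifti::readNifti(path)
    px <- matrix(as.numeric(im), nrow = dim(im)[1], ncol = dim(im)[2])
    if (is.null(spacing)) spacing <- RNifti::pixdim(im)[1:2]
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    storage.mode(px) <- "double"
    if (is.null(spacing))
      stop("pixel spacing absent from sidecar and TIFF carries none: ", sidecar)
  } else {
    stop("unsupported image extension: ", path)
  }
  if (is.null(spacing) || length(spacing) != 2L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("pixel spacing missing or invalid for ", path)
  image_slice(meta$patient_id, meta$slice_index, meta$position_mm, px, spacing)
}
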