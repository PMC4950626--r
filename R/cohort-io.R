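# On-disk cohort layout (the same formats whether the cohort is synthetic or
# real):
#   <dir>/<patient>_slice<idx>.nii.gz (+ .json sidecar)  -- images
#   <dir>/annotations.json                               -- contours
#   <dir>/histology.csv                                  -- ground truth
#   <dir>/truth.csv                                      -- phantom truth (optional)
#   <dir>/manifest.json                                  -- file list + config echo

#' Write a cohort to a directory
#'
#' @param cohort an `iph_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"nifti"` (default) or `"tiff"` for the images; TIFF
#'   requires integer intensities and quantizes by rounding.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "tiff")) {
  stopifnot(inherits(cohort, "iph_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "nifti") ".nii.gz" else ".tif"
  files <- character(0)
  for (key in names(cohort$slices)) {
    s <- cohort$slices[[key]]
    if (format == "tiff") s$pixels <- round(s$pixels)
    fn <- sprintf("%s_slice%03d%s", s$patient_id, s$slice_index, ext)
    write_slice(s, file.path(dir, fn))
    files <- c(files, fn)
  }
  write_annotations(cohort$annotations, file.path(dir, "annotations.json"))
  write_histology(cohort$histology, file.path(dir, "histology.csv"))
  if (!is.null(cohort$truth)) {
    tr <- do.call(rbind, lapply(names(cohort$truth), function(key) {
      t <- cohort$truth[[key]]
      s <- cohort$slices[[key]]
      data.frame(patient_id = s$patient_id, slice_index = s$slice_index,
                 iph_present = as.integer(t$iph_present),
                 iph_area_mm2 = t$iph_area_mm2,
                 calcified_fraction = t$calcified_fraction,
                 contrast_ratio_used = t$contrast_ratio_used,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- list(
    schema = "iph-cohort/1",
    images = files,
    annotations = "annotations.json",
    histology = "histology.csv",
    config = if (!is.null(cohort$config)) unclass(cohort$config) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' @param dir directory written by [write_cohort()] (or laid out the same
#'   way by hand).
#' @return an `iph_cohort` (with `truth = NULL`; truth masks are not stored
#'   on disk, only the histology-style summary travels with the data).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    images <- manifest$images
  } else {
    images <- list.files(dir, pattern = "\\.(nii(\\.gz)?|tiff?)$")
  }
  if (!length(images)) stop("no images found in ", dir)
  slices <- lapply(images, function(fn) read_slice(file.path(dir, fn)))
  names(slices) <- vapply(slices, function(s)
    paste(s$patient_id, s$slice_index, sep = "/"), character(1))
  anns <- read_annotations(file.path(dir, "annotations.json"))
  names(anns) <- vapply(anns, function(a)
    paste(a$patient_id, a$slice_index, sep = "/"), character(1))
  missing <- setdiff(names(slices), names(anns))
  if (length(missing))
    stop("slices without annotations: ", paste(missing, collapse = ", "))
  structure(
    list(slices = slices, annotations = anns[names(slices)],
         histology = read_histology(file.path(dir, "histology.csv")),
         truth = NULL, config = NULL),
    class = "iph_cohort"
  )
}
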