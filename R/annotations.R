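# Per-slice contour annotations: reviewer-drawn outer wall, reference-muscle
# polygons, and the lumen center point that anchors the 4 cm circular ROI.
# On-disk schema ("iph-annotations/1"): a JSON object
#   {"schema": "iph-annotations/1", "slices": [ {record}, ... ]}
# where each record has patient_id, slice_index, lumen_center = [x, y] (mm)
# and polygons (outer_wall required; scm / adjacent_muscle optional) as
# arrays of [x, y] pairs in mm image coordinates.

ANNOTATION_SCHEMA <- "iph-annotations/1"

#' Construct a per-slice annotation set
#'
#' Polygons are closed implicitly (the first vertex follows the last), must be
#' simple and have at least 3 vertices. An absent `scm` polygon models slices
#' where the sternocleidomastoid lies too far from the artery to serve as a
#' reference; an absent `adjacent_muscle` likewise invalidates that reference.
#'
#' @param patient_id,slice_index identify the slice this annotation belongs to.
#' @param lumen_center length-2 numeric `(x, y)` mm: carotid lumen center,
#'   the center of the 4 cm reference ROI. Must lie inside `outer_wall`.
#' @param outer_wall loose polygon enclosing the carotid artery; the IPH
#'   search region.
#' @param scm,adjacent_muscle optional reference-muscle polygons.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(patient_id, slice_index, lumen_center, outer_wall,
                           scm = NULL, adjacent_muscle = NULL) {
  lumen_center <- as.numeric(lumen_center)
  if (length(lumen_center) != 2L || !all(is.finite(lumen_center)))
    stop("lumen_center must be a finite (x, y) pair")
  outer_wall <- .validate_polygon(outer_wall, "outer_wall")
  if (!is.null(scm)) scm <- .validate_polygon(scm, "scm")
  if (!is.null(adjacent_muscle))
    adjacent_muscle <- .validate_polygon(adjacent_muscle, "adjacent_muscle")
  if (!point_in_polygon(lumen_center[1], lumen_center[2], outer_wall))
    stop("lumen_center must lie inside the outer_wall polygon")
  structure(
    list(
      patient_id = as.character(patient_id),
      slice_index = as.integer(slice_index),
      lumen_center = lumen_center,
      outer_wall = outer_wall,
      scm = scm,
      adjacent_muscle = adjacent_muscle
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  opt <- c(
    if (!is.null(x$scm)) "scm",
    if (!is.null(x$adjacent_muscle)) "adjacent_muscle"
  )
  cat(sprintf(
    "<annotation_set> patient %s, slice %d | outer_wall (%d vtx)%s\n",
    x$patient_id, x$slice_index, nrow(x$outer_wall),
    if (length(opt)) paste0(" + ", paste(opt, collapse = ", ")) else ""
  ))
  invisible(x)
}

.poly_to_json <- function(p) {
  if (is.null(p)) NULL else unname(lapply(seq_len(nrow(p)), function(i) p[i, ]))
}

#' Write annotation sets to a JSON document
#'
#' @param annotations a list of [annotation_set()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "annotation_set"))
    r <- list(
      patient_id = a$patient_id,
      slice_index = a$slice_index,
      lumen_center = a$lumen_center,
      outer_wall = .poly_to_json(a$outer_wall)
    )
    if (!is.null(a$scm)) r$scm <- .poly_to_json(a$scm)
    if (!is.null(a$adjacent_muscle))
      r$adjacent_muscle <- .poly_to_json(a$adjacent_muscle)
    r
  })
  jsonlite::write_json(
    list(schema = ANNOTATION_SCHEMA, slices = recs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read annotation sets from a JSON document
#'
#' Every record is validated on read; a malformed polygon raises an error
#' naming the slice and the polygon's role, so no record is silently dropped.
#'
#' @param path JSON path (schema `"iph-annotations/1"`).
#' @return list of [annotation_set()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  recs <- if (!is.null(doc$slices)) doc$slices else doc
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    where <- sprintf("record %d (patient %s, slice %s)",
                     i, r$patient_id %||% "?", r$slice_index %||% "?")
    for (f in c("patient_id", "slice_index", "lumen_center", "outer_wall"))
      if (is.null(r[[f]])) stop(where, ": missing field '", f, "'")
    tryCatch(
      annotation_set(r$patient_id, r$slice_index, unlist(r$lumen_center),
                     r$outer_wall, scm = r$scm,
                     adjacent_muscle = r$adjacent_muscle),
      error = function(e) stop(where, ": ", conditionMessage(e), call. = FALSE)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
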