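# Histology ground truth: per-section IPH presence, area and calcified
# fraction, keyed by patient and signed distance to the carotid bifurcation.
# CSV columns: patient_id, position_mm, iph_present (0/1), iph_area_mm2,
# calcified_fraction. Booleans are encoded 0/1 to stay locale-proof.

.validate_histology <- function(df, path = "<data>") {
  need <- c("patient_id", "position_mm", "iph_present", "iph_area_mm2",
            "calcified_fraction")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("histology table missing column(s): ", paste(missing, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$position_mm <- as.numeric(df$position_mm)
  df$iph_area_mm2 <- as.numeric(df$iph_area_mm2)
  df$calcified_fraction <- as.numeric(df$calcified_fraction)
  pres <- df$iph_present
  if (is.logical(pres)) pres <- as.integer(pres)
  if (!all(pres %in% c(0L, 1L)))
    stop("iph_present must be 0 or 1")
  df$iph_present <- pres == 1L
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    bad <- NULL
    if (!is.finite(r$position_mm)) bad <- "non-finite position_mm"
    else if (!is.finite(r$iph_area_mm2) || r$iph_area_mm2 < 0)
      bad <- "iph_area_mm2 must be >= 0"
    else if (!is.finite(r$calcified_fraction) || r$calcified_fraction < 0 ||
             r$calcified_fraction > 1)
      bad <- "calcified_fraction must be in [0, 1]"
    else if (!r$iph_present && (r$iph_area_mm2 != 0 || r$calcified_fraction != 0))
      bad <- "iph_present = 0 requires iph_area_mm2 = 0 and calcified_fraction = 0"
    else if (r$iph_present && r$iph_area_mm2 == 0)
      bad <- "iph_present = 1 requires iph_area_mm2 > 0"
    if (!is.null(bad))
      stop(sprintf("%s: row %d: %s", path, i, bad))
  }
  df[need]
}

#' Read a histology ground-truth table
#'
#' @param path CSV path (RFC 4180, UTF-8, "." decimal) with columns
#'   `patient_id, position_mm, iph_present, iph_area_mm2, calcified_fraction`.
#' @return a data frame with `iph_present` as logical; every row validated
#'   (an IPH-absent section must have zero area and zero calcified fraction).
#' @export
read_histology <- function(path) {
  if (!file.exists(path)) stop("histology file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_histology(df, path)
}

#' Write a histology ground-truth table
#'
#' @param sections data frame as returned by [read_histology()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histology <- function(sections, path) {
  df <- .validate_histology(sections)
  df$iph_present <- as.integer(df$iph_present)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
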