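# Hand-built miniature cohorts with fully controlled scores and areas.
#
# Layout of a toy slice (10 x 10 px at 1 mm): background 50; an
# adjacent-muscle square (pixel centers 0..2 x 0..2) at exactly 100, so the
# reference is 100; an outer-wall square over centers 5..8 x 5..8 whose
# pixels sit at 80 (normalized 0.8), with `hot_px` pixels raised to
# score x 100. The slice's detection score is therefore exactly `score`
# (or 0.8 when no hot pixel), and the detected area at any threshold in
# (0.8, score) is exactly `hot_px` mm^2.

toy_slice <- function(patient, index, score = NULL, hot_px = 0L,
                      position = index) {
  px <- matrix(50, 10, 10)
  px[1:3, 1:3] <- 100
  px[6:9, 6:9] <- 80
  if (hot_px > 0L) {
    stopifnot(!is.null(score), hot_px <= 16L)
    wall_cells <- as.matrix(expand.grid(i = 6:9, j = 6:9))
    hot <- wall_cells[seq_len(hot_px), , drop = FALSE]
    px[hot] <- score * 100
  }
  slice <- image_slice(patient, index, position, px, c(1, 1))
  ann <- annotation_set(
    patient, index,
    lumen_center = c(6.5, 6.5),
    outer_wall = rbind(c(4.6, 4.6), c(8.4, 4.6), c(8.4, 8.4), c(4.6, 8.4)),
    adjacent_muscle = rbind(c(-0.4, -0.4), c(2.4, -0.4), c(2.4, 2.4),
                            c(-0.4, 2.4))
  )
  list(slice = slice, ann = ann)
}

# cohort of identical patients: each has one negative slice (score 0.8) and
# one positive slice at `score` with `hot_px` detected pixels; histological
# truth area = hot_px mm^2 so detected area matches truth exactly.
toy_cohort <- function(n_patients = 3L, score = 1.8, hot_px = 4L) {
  slices <- list(); anns <- list(); rows <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("T%02d", i)
    neg <- toy_slice(pid, 0L)
    pos <- toy_slice(pid, 1L, score = score, hot_px = hot_px)
    slices[[paste(pid, 0, sep = "/")]] <- neg$slice
    slices[[paste(pid, 1, sep = "/")]] <- pos$slice
    anns[[paste(pid, 0, sep = "/")]] <- neg$ann
    anns[[paste(pid, 1, sep = "/")]] <- pos$ann
    rows[[pid]] <- data.frame(
      patient_id = pid, position_mm = c(0, 1),
      iph_present = c(FALSE, TRUE), iph_area_mm2 = c(0, hot_px),
      calcified_fraction = 0, stringsAsFactors = FALSE)
  }
  structure(
    list(slices = slices, annotations = anns,
         histology = do.call(rbind, rows), truth = NULL, config = NULL),
    class = "iph_cohort"
  )
}

# quiet wrappers: matching/reference messages are part of the interface but
# noise in tests that aren't about them
quiet <- function(expr) suppressMessages(expr)
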