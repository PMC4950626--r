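test_that("NIfTI slice round-trip is bitwise exact and keeps metadata", {
  set.seed(11)
  px <- matrix(runif(32 * 32) * 4096, 32, 32)
  s <- image_slice("P07", 3L, -12.5, px, c(0.31, 0.31))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_slice(s, f)
  r <- read_slice(f)
  expect_identical(r$pixels, px)
  expect_identical(r$patient_id, "P07")
  expect_identical(r$slice_index, 3L)
  expect_identical(r$position_mm, -12.5)
  expect_identical(r$spacing_mm, c(0.31, 0.31))
})

test_that("16-bit TIFF stores integer intensities unscaled", {
  s <- image_slice("P01", 0L, 0, matrix(100, 4, 4), c(0.31, 0.31))
  f <- withr::local_tempfile(fileext = ".tif")
  write_slice(s, f)
  r <- read_slice(f)
  expect_equal(dim(r$pixels), c(4L, 4L))
  expect_true(all(r$pixels == 100))
  expect_identical(r$spacing_mm, c(0.31, 0.31))
})

test_that("missing spacing and missing files are explicit errors", {
  # TIFF with a sidecar that lacks spacing_mm: metadata error
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), f, bits.per.sample = 16L)
  side <- sub("\\.tif$", ".json", f)
  jsonlite::write_json(list(patient_id = "P01", slice_index = 0,
                            position_mm = 0),
                       side, auto_unbox = TRUE)
  expect_error(read_slice(f), "spacing")
  expect_error(read_slice("no/such/file.nii.gz"), "not found")
  expect_error(read_slice(f, "no/such/sidecar.json"), "not found")
})

test_that("image slice invariants are enforced", {
  expect_error(image_slice("P", 0, 0, matrix(-1, 4, 4), c(1, 1)),
               "non-negative")
  expect_error(image_slice("P", 0, 0, matrix(NaN, 4, 4), c(1, 1)), "finite")
  expect_error(image_slice("P", 0, 0, matrix(1, 1, 4), c(1, 1)), "2 rows")
  expect_error(image_slice("P", 0, 0, matrix(1, 4, 4), c(0, 1)), "positive")
})

test_that("annotations round-trip through JSON with optional polygons", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  a1 <- annotation_set("P01", 0L, c(0.5, 0.5), sq)                # no scm
  a2 <- annotation_set("P01", 1L, c(0.5, 0.5), sq, scm = sq + 5,
                       adjacent_muscle = sq + 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(list(a1, a2), f)
  back <- read_annotations(f)
  expect_length(back, 2L)
  expect_null(back[[1]]$scm)
  expect_equal(back[[2]]$scm, a2$scm)
  expect_equal(back[[2]]$adjacent_muscle, a2$adjacent_muscle)
  expect_equal(back[[1]]$outer_wall, a1$outer_wall)
  expect_equal(back[[1]]$lumen_center, c(0.5, 0.5))
})

test_that("malformed polygons are rejected with slice and role named", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(annotation_set("P", 0, c(0.5, 0.5), rbind(c(0, 0), c(1, 1))),
               "at least 3 vertices")
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))   # self-intersecting
  expect_error(annotation_set("P", 0, c(0.5, 0.5), bow), "self-intersecting")
  expect_error(annotation_set("P", 0, c(5, 5), sq), "inside the outer_wall")
  # error from a file names the offending record and role
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "iph-annotations/1", slices = list(list(
    patient_id = "P09", slice_index = 4, lumen_center = c(0.5, 0.5),
    outer_wall = list(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  ))), f, auto_unbox = TRUE, digits = NA)
  expect_error(read_annotations(f), "P09.*outer_wall|outer_wall.*P09")
})

test_that("histology CSV round-trips and invariants are validated by row", {
  df <- data.frame(
    patient_id = c("P01", "P01"), position_mm = c(12, 13),
    iph_present = c(TRUE, FALSE), iph_area_mm2 = c(5.3, 0),
    calcified_fraction = c(0.1, 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_histology(df, f)
  back <- read_histology(f)
  expect_equal(nrow(back), 2L)
  expect_identical(back$iph_present, c(TRUE, FALSE))
  expect_equal(back$iph_area_mm2, c(5.3, 0))

  bad <- df
  bad$iph_area_mm2[2] <- 2.0    # absent IPH with nonzero area
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(transform(bad, iph_present = as.integer(iph_present)),
                   f2, row.names = FALSE)
  expect_error(read_histology(f2), "row 2")

  bad2 <- df
  bad2$calcified_fraction[1] <- 1.5
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(transform(bad2, iph_present = as.integer(iph_present)),
                   f3, row.names = FALSE)
  expect_error(read_histology(f3), "row 1")

  bad3 <- df
  bad3$iph_area_mm2[1] <- 0     # present IPH with zero area
  f4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(transform(bad3, iph_present = as.integer(iph_present)),
                   f4, row.names = FALSE)
  expect_error(read_histology(f4), "row 1")
})
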