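slices_df <- function(patient = "P01", positions = 10)
  data.frame(patient_id = patient, slice_index = seq_along(positions) - 1L,
             position_mm = positions, stringsAsFactors = FALSE)

sec <- function(pos, present, area, frac = 0, patient = "P01")
  data.frame(patient_id = patient, position_mm = pos, iph_present = present,
             iph_area_mm2 = area, calcified_fraction = frac,
             stringsAsFactors = FALSE)

test_that("multiple sections fuse by any-presence and mean area", {
  sections <- rbind(sec(9.7, TRUE, 4.0), sec(10.2, TRUE, 6.0))
  m <- match_sections(slices_df(positions = 10), sections, 0.5)
  expect_equal(nrow(m), 1L)
  expect_true(m$truth_present)
  expect_equal(m$truth_area_mm2, 5.0)
  expect_equal(m$n_sections, 2L)

  sections2 <- rbind(sec(9.7, FALSE, 0), sec(10.2, TRUE, 6.0))
  m2 <- match_sections(slices_df(positions = 10), sections2, 0.5)
  expect_true(m2$truth_present)             # "any" rule
  expect_equal(m2$truth_area_mm2, 3.0)      # mean including the zero
})

test_that("calcified fraction fuses by IPH-area weighting", {
  sections <- rbind(sec(9.8, TRUE, 4.0, frac = 0.5),
                    sec(10.2, TRUE, 1.0, frac = 0.0))
  m <- match_sections(slices_df(positions = 10), sections, 0.5)
  expect_equal(m$truth_calcified_fraction, (4 * 0.5 + 1 * 0) / 5)
  # all-absent sections: fraction defined as 0
  m0 <- match_sections(slices_df(positions = 10),
                       rbind(sec(9.8, FALSE, 0), sec(10.2, FALSE, 0)), 0.5)
  expect_equal(m0$truth_calcified_fraction, 0)
  expect_false(m0$truth_present)
})

test_that("sections outside the window are dropped, counted and reported", {
  sections <- rbind(sec(12.0, TRUE, 3.0), sec(10.1, TRUE, 2.0))
  expect_message(
    m <- match_sections(slices_df(positions = 10), sections, 0.5),
    "1 histology section")
  expect_equal(nrow(m), 1L)
  expect_equal(m$truth_area_mm2, 2.0)
  unm <- attr(m, "unmatched")
  expect_equal(nrow(unm), 1L)
  expect_equal(unm$position_mm, 12.0)
  expect_equal(nrow(m) * m$n_sections + nrow(unm), nrow(sections))
})

test_that("sections never cross patients and duplicates are rejected", {
  slices <- rbind(slices_df("P01", 10), slices_df("P02", 10.05))
  sections <- sec(10.04, TRUE, 3.0, patient = "P02")
  m <- match_sections(slices, sections, 0.5)
  expect_equal(m$patient_id, "P02")
  dup <- rbind(sec(10, TRUE, 1), sec(10, TRUE, 2))
  expect_error(match_sections(slices, dup, 0.5), "duplicate")
})

test_that("subset filtering matches the stated exclusion rules exactly", {
  m <- data.frame(
    patient_id = "P", slice_index = 0:3, position_mm = 0:3,
    truth_present = c(FALSE, TRUE, TRUE, TRUE),
    truth_area_mm2 = c(0, 1.0, 2.0, 5.0),
    truth_calcified_fraction = 0, n_sections = 1L)
  kept <- apply_subset(m, subset_spec(min_iph_area_mm2 = 1.25))
  expect_equal(kept$truth_area_mm2, c(0, 2.0, 5.0))  # absent never removed

  mc <- m
  mc$truth_calcified_fraction <- c(0, 0.6, 0.5, 0.2)
  kept2 <- apply_subset(mc, subset_spec(exclude_heavily_calcified = TRUE))
  expect_equal(kept2$truth_area_mm2, c(0, 2.0, 5.0))  # 0.6 out, 0.5 stays (strict >)

  # identity subset
  expect_equal(apply_subset(m, subset_spec()), m)

  # idempotence and order-independence of the two rules
  sp_both <- subset_spec(1.25, exclude_heavily_calcified = TRUE)
  once <- apply_subset(mc, sp_both)
  expect_equal(apply_subset(once, sp_both), once)
  via_area_first <- apply_subset(apply_subset(mc, subset_spec(1.25)),
                                 subset_spec(exclude_heavily_calcified = TRUE))
  via_ca_first <- apply_subset(apply_subset(mc,
                                            subset_spec(exclude_heavily_calcified = TRUE)),
                               subset_spec(1.25))
  expect_equal(once, via_area_first)
  expect_equal(once, via_ca_first)
  # retained rows are unchanged by filtering
  expect_equal(once, mc[mc$truth_area_mm2 %in% once$truth_area_mm2, ],
               ignore_attr = TRUE)
})

test_that("small-IPH area cutoff follows pi (resolution x)^2", {
  expect_equal(round(area_cutoff(1, 0.63), 2), 1.25)
  # the printed companion value 2.80 agrees to its last printed digit
  expect_lt(abs(area_cutoff(1.5, 0.63) - 2.80), 0.01)
  expect_equal(area_cutoff(1, 1 / sqrt(pi)), 1.0)
  expect_error(area_cutoff(0), "positive")
  expect_error(area_cutoff(1, -0.5), "positive")
})
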