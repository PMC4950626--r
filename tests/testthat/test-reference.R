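make_ann <- function(lumen, outer, scm = NULL, adj = NULL)
  annotation_set("P", 0, lumen, outer, scm = scm, adjacent_muscle = adj)

big_wall <- function(c0 = c(50, 50), r = 45) {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  cbind(c0[1] + r * cos(th), c0[2] + r * sin(th))
}

test_that("SCM reference is the mean over the SCM-within-ROI intersection", {
  s <- blank_slice(101, 101, value = 50)
  sq <- rbind(c(44.5, 44.5), c(48.5, 44.5), c(48.5, 48.5), c(44.5, 48.5))
  ref <- scm_reference(s, make_ann(c(50, 50), big_wall(), scm = sq))
  expect_true(ref$valid)
  expect_equal(ref$value, 50)
  expect_equal(ref$n_pixels, 16L)
})

test_that("SCM entirely outside the 4 cm ROI invalidates the slice", {
  s <- blank_slice(101, 101, value = 50)
  far <- rbind(c(75, 50), c(85, 50), c(85, 60), c(75, 60))  # >20 mm away
  ref <- scm_reference(s, make_ann(c(30, 50), big_wall(c(30, 50), 20),
                                   scm = far))
  expect_false(ref$valid)
  # absent polygon is also an invalid value, not an error
  expect_false(scm_reference(s, make_ann(c(30, 50), big_wall(c(30, 50), 20)))$valid)
})

test_that("SCM half inside the ROI averages only the inside portion", {
  s <- blank_slice(101, 101)
  px <- s$pixels
  px[, 1:60] <- 10; px[, 61:101] <- 30
  s$pixels <- px
  # square straddling the ROI rim at x in [55, 65], lumen at (40, 50), r = 20
  sq <- rbind(c(54.5, 48.5), c(64.5, 48.5), c(64.5, 51.5), c(54.5, 51.5))
  ann <- make_ann(c(40, 50), big_wall(c(40, 50), 10), scm = sq)
  ref <- scm_reference(s, ann)
  inter <- oracle_polygon_mask(sq, s) & oracle_circle_mask(c(40, 50), 40, s)
  expect_equal(ref$value, mean(s$pixels[inter]))
  expect_equal(ref$n_pixels, sum(inter))
  expect_gte(ref$value, min(s$pixels[inter]))
  expect_lte(ref$value, max(s$pixels[inter]))
})

test_that("adjacent-muscle reference is the polygon mean, no ROI clipping", {
  s <- blank_slice(20, 20, value = 80)
  sq <- rbind(c(0.5, 0.5), c(3.5, 0.5), c(3.5, 3.5), c(0.5, 3.5))
  ann <- make_ann(c(10, 10), big_wall(c(10, 10), 8), adj = sq)
  expect_equal(adjacent_muscle_reference(s, ann)$value, 80)

  px <- s$pixels
  px[11, 2:4] <- c(10, 20, 30)   # polygon covering exactly those three pixels
  s2 <- blank_slice(20, 20, value = 80); s2$pixels <- px
  strip <- rbind(c(0.6, 9.6), c(3.4, 9.6), c(3.4, 10.4), c(0.6, 10.4))
  ann2 <- make_ann(c(10, 10), big_wall(c(10, 10), 8), adj = strip)
  ref <- adjacent_muscle_reference(s2, ann2)
  expect_equal(ref$n_pixels, 3L)
  expect_equal(ref$value, 20)
  expect_false(adjacent_muscle_reference(s, make_ann(c(10, 10),
                                                     big_wall(c(10, 10), 8)))$valid)
})

test_that("local median uses midpoint convention and matches sorting oracle", {
  # plus-shaped 5-pixel ROI: diameter 2 at the center pixel
  s <- blank_slice(9, 9, value = 999)
  s$pixels[5, 5] <- 1; s$pixels[4, 5] <- 2; s$pixels[6, 5] <- 3
  s$pixels[5, 4] <- 4; s$pixels[5, 6] <- 5
  ann <- make_ann(c(4, 4), big_wall(c(4, 4), 3))
  ref <- local_median_reference(s, ann, roi_diameter_mm = 2)
  expect_equal(ref$n_pixels, 5L)
  expect_equal(ref$value, 3)

  # even count: 4 pixels symmetric around (0.5, 0.5)
  s2 <- blank_slice(9, 9, value = 999)
  s2$pixels[1:2, 1:2] <- c(1, 3, 2, 4)
  ann2 <- annotation_set("P", 0, c(0.5, 0.5),
                         rbind(c(-1, -1), c(2, -1), c(2, 2), c(-1, 2)))
  ref2 <- local_median_reference(s2, ann2, roi_diameter_mm = 1.6)
  expect_equal(ref2$n_pixels, 4L)
  expect_equal(ref2$value, 2.5)

  # random image: equals the sort-based median over enumerated mask pixels
  set.seed(31)
  s3 <- blank_slice(64, 64)
  s3$pixels <- matrix(runif(64 * 64, 0.01, 10), 64, 64)
  ann3 <- make_ann(c(30, 30), big_wall(c(30, 30), 25))
  ref3 <- local_median_reference(s3, ann3)
  mask <- oracle_circle_mask(c(30, 30), 40, s3)
  v <- sort(s3$pixels[mask])
  n <- length(v)
  med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  expect_equal(ref3$value, med)
  # off-image lumen center is an error for the median reference
  ann_off <- list(lumen_center = c(5000, 5000))
  expect_error(local_median_reference(s3, ann_off), "off-image")
})

test_that("valid references scale linearly with global intensity", {
  set.seed(5)
  s <- blank_slice(64, 64)
  s$pixels <- matrix(runif(64 * 64, 1, 100), 64, 64)
  sq <- rbind(c(20, 20), c(30, 20), c(30, 30), c(20, 30))
  ann <- make_ann(c(32, 32), big_wall(c(32, 32), 28), scm = sq, adj = sq + 3)
  s2 <- s; s2$pixels <- s$pixels * 7
  for (kind in c("scm", "adjacent_muscle", "local_median")) {
    r1 <- compute_reference(s, ann, kind)
    r2 <- compute_reference(s2, ann, kind)
    expect_equal(r2$value, 7 * r1$value)
  }
})
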