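# Synthetic MP-RAGE-like phantom. Each axial slice lays out, in signal units
# relative to a nominal muscle intensity:
#   background 0.2, SCM ellipse near the top edge (superficial) at 1.0,
#   adjacent deep-muscle ellipse beside the vessel at 1.0, a vessel-wall
#   annulus (3-6.5 mm radius) around a dark lumen (0.1), and -- with the
#   configured prevalence -- a hyperintense IPH disk painted inside the
#   annulus at the configured contrast ratio, optionally with a hypointense
#   concentric calcified core. The whole image is multiplied by an
#   exponential coil-sensitivity field decaying with depth from the top edge
#   (the skin surface), then Gaussian (optionally Rician) noise is added and
#   the result clipped at zero. Geometry is circles/ellipses only, so every
#   truth quantity has a closed form and the rasterized truth mask is exact
#   by construction.

# fixed vessel geometry (mm)
.PHANTOM_GEOM <- list(
  lumen_radius = 3, wall_outer_radius = 6.5, outer_wall_contour_radius = 8,
  adjacent_semiaxes = c(4.5, 3.5)
)

#' Phantom cohort configuration
#'
#' Defaults encode the simulated study conditions: 14 patients of 10 slices,
#' IPH at 1.6 x muscle, noise sigma = 5% of muscle, uniform coil field, and
#' roughly half the slices IPH-positive.
#'
#' @param n_patients,slices_per_patient cohort shape.
#' @param image_size_px image rows and columns.
#' @param spacing_mm pixel size (row, column), mm; default the 0.31 mm
#'   reconstructed resolution.
#' @param muscle_signal nominal muscle intensity, arbitrary units.
#' @param wall_signal_ratio normal vessel-wall signal / muscle (default 1).
#' @param iph_contrast_ratio IPH signal / muscle (default 1.6).
#' @param iph_prevalence probability a slice carries IPH.
#' @param iph_radius_range_mm uniform range of IPH disk radius; must fit the
#'   3-6.5 mm wall annulus (radius <= 1.75 mm).
#' @param calcified_probability probability an IPH carries a calcified core.
#' @param calcified_fraction_range uniform range of the calcified area
#'   fraction.
#' @param calcification_signal_ratio calcification signal / muscle; must be
#'   below `iph_contrast_ratio`.
#' @param coil_decay_mm coil-sensitivity decay length: sensitivity =
#'   exp(-depth / decay), depth measured from the image top edge. `Inf`
#'   (default) gives a uniform field.
#' @param noise_sigma_ratio additive noise sigma / muscle signal.
#' @param rician use Rician instead of Gaussian noise.
#' @param seed integer seed; each patient draws from a sub-stream derived
#'   from it, so cohorts are bit-reproducible.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 14L, slices_per_patient = 10L,
                           image_size_px = c(192L, 192L),
                           spacing_mm = c(0.31, 0.31),
                           muscle_signal = 600,
                           wall_signal_ratio = 1.0,
                           iph_contrast_ratio = 1.6,
                           iph_prevalence = 0.5,
                           iph_radius_range_mm = c(0.7, 1.6),
                           calcified_probability = 0.3,
                           calcified_fraction_range = c(0.1, 0.9),
                           calcification_signal_ratio = 0.3,
                           coil_decay_mm = Inf,
                           noise_sigma_ratio = 0.05,
                           rician = FALSE,
                           seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    slices_per_patient = as.integer(slices_per_patient),
    image_size_px = as.integer(image_size_px),
    spacing_mm = as.numeric(spacing_mm),
    muscle_signal = as.numeric(muscle_signal),
    wall_signal_ratio = as.numeric(wall_signal_ratio),
    iph_contrast_ratio = as.numeric(iph_contrast_ratio),
    iph_prevalence = as.numeric(iph_prevalence),
    iph_radius_range_mm = as.numeric(iph_radius_range_mm),
    calcified_probability = as.numeric(calcified_probability),
    calcified_fraction_range = as.numeric(calcified_fraction_range),
    calcification_signal_ratio = as.numeric(calcification_signal_ratio),
    coil_decay_mm = as.numeric(coil_decay_mm),
    noise_sigma_ratio = as.numeric(noise_sigma_ratio),
    rician = isTRUE(rician),
    seed = as.integer(seed)
  )
  g <- .PHANTOM_GEOM
  if (cfg$n_patients < 1L || cfg$slices_per_patient < 1L)
    stop("n_patients and slices_per_patient must be >= 1")
  if (any(cfg$image_size_px < 32L)) stop("image_size_px must be at least 32")
  if (any(cfg$spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (cfg$muscle_signal <= 0) stop("muscle_signal must be positive")
  if (cfg$iph_contrast_ratio <= 0) stop("iph_contrast_ratio must be positive")
  if (cfg$iph_prevalence < 0 || cfg$iph_prevalence > 1)
    stop("iph_prevalence must be in [0, 1]")
  if (length(cfg$iph_radius_range_mm) != 2L ||
      any(cfg$iph_radius_range_mm <= 0) || diff(cfg$iph_radius_range_mm) < 0)
    stop("iph_radius_range_mm must be an increasing positive pair")
  if (cfg$iph_radius_range_mm[2] > (g$wall_outer_radius - g$lumen_radius) / 2)
    stop(sprintf(
      "IPH radius %.2f mm does not fit the %.1f-%.1f mm wall annulus",
      cfg$iph_radius_range_mm[2], g$lumen_radius, g$wall_outer_radius))
  if (cfg$calcified_probability < 0 || cfg$calcified_probability > 1)
    stop("calcified_probability must be in [0, 1]")
  if (any(cfg$calcified_fraction_range < 0) ||
      any(cfg$calcified_fraction_range > 1) ||
      diff(cfg$calcified_fraction_range) < 0)
    stop("calcified_fraction_range must be an increasing pair in [0, 1]")
  if (cfg$calcification_signal_ratio >= cfg$iph_contrast_ratio)
    stop("calcification_signal_ratio must be below iph_contrast_ratio")
  if (cfg$coil_decay_mm <= 0) stop("coil_decay_mm must be positive (or Inf)")
  if (cfg$noise_sigma_ratio < 0) stop("noise_sigma_ratio must be >= 0")
  structure(cfg, class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config> %d patients x %d slices | %dx%d px @ %.3g mm | IPH %.2fx muscle (prev %.2f) | coil decay %s mm | noise %.1f%%\n",
    x$n_patients, x$slices_per_patient, x$image_size_px[1], x$image_size_px[2],
    x$spacing_mm[1], x$iph_contrast_ratio, x$iph_prevalence,
    format(x$coil_decay_mm), 100 * x$noise_sigma_ratio))
  invisible(x)
}

#' Regular polygon approximation of an ellipse
#'
#' @param center `(x, y)` mm; `a,b` semi-axes along x and y, mm;
#'   `n` vertices.
#' @return n x 2 polygon matrix.
#' @export
ellipse_polygon <- function(center, a, b, n = 40L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + a * cos(th), y = center[2] + b * sin(th))
}

# deterministic per-patient sub-seed below 2^31
.patient_seed <- function(seed, i) {
  ((abs(as.numeric(seed)) %% 1e6) * 2099 + i * 7919) %% 2147483647
}

# paint one slice; draws come from the caller's RNG state
.paint_slice <- function(cfg, patient_id, slice_index) {
  g <- .PHANTOM_GEOM
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  sr <- cfg$spacing_mm[1]; sc <- cfg$spacing_mm[2]
  ys <- (seq_len(nr) - 1) * sr
  xs <- (seq_len(nc) - 1) * sc
  xmax <- xs[nc]; ymax <- ys[nr]
  mus <- cfg$muscle_signal

  lumen <- c(0.5 * xmax, 0.55 * ymax)
  scm_c <- c(0.5 * xmax, 0.23 * ymax)
  scm_ab <- c(0.15 * xmax, 0.08 * ymax)
  adj_c <- c(0.28 * xmax, 0.56 * ymax)
  adj_ab <- g$adjacent_semiaxes

  d2 <- outer((ys - lumen[2])^2, (xs - lumen[1])^2, "+")
  img <- matrix(0.2 * mus, nr, nc)
  in_scm <- outer(((ys - scm_c[2]) / scm_ab[2])^2,
                  ((xs - scm_c[1]) / scm_ab[1])^2, "+") <= 1
  in_adj <- outer(((ys - adj_c[2]) / adj_ab[2])^2,
                  ((xs - adj_c[1]) / adj_ab[1])^2, "+") <= 1
  img[in_scm] <- mus
  img[in_adj] <- mus
  ring <- d2 > g$lumen_radius^2 & d2 <= g$wall_outer_radius^2
  img[ring] <- cfg$wall_signal_ratio * mus
  img[d2 <= g$lumen_radius^2] <- 0.1 * mus

  # IPH disk inside the annulus
  present <- stats::runif(1) < cfg$iph_prevalence
  iph_mask <- matrix(FALSE, nr, nc)
  calc_frac <- 0
  if (present) {
    r <- stats::runif(1, cfg$iph_radius_range_mm[1], cfg$iph_radius_range_mm[2])
    th <- stats::runif(1, 0, 2 * pi)
    d <- stats::runif(1, g$lumen_radius + r, g$wall_outer_radius - r)
    bc <- lumen + d * c(cos(th), sin(th))
    b2 <- outer((ys - bc[2])^2, (xs - bc[1])^2, "+")
    iph_mask <- b2 <= r^2
    img[iph_mask] <- cfg$iph_contrast_ratio * mus
    if (stats::runif(1) < cfg$calcified_probability && any(iph_mask)) {
      f <- stats::runif(1, cfg$calcified_fraction_range[1],
                        cfg$calcified_fraction_range[2])
      calc <- b2 <= (r * sqrt(f))^2
      img[calc] <- cfg$calcification_signal_ratio * mus
      calc_frac <- sum(calc & iph_mask) / sum(iph_mask)
    }
    present <- any(iph_mask)
  }

  # coil-sensitivity falloff with depth from the top edge, then noise
  if (is.finite(cfg$coil_decay_mm))
    img <- img * exp(-ys / cfg$coil_decay_mm)
  if (cfg$noise_sigma_ratio > 0) {
    sigma <- cfg$noise_sigma_ratio * mus
    if (cfg$rician) {
      img <- sqrt((img + stats::rnorm(nr * nc, 0, sigma))^2 +
                    stats::rnorm(nr * nc, 0, sigma)^2)
    } else {
      img <- img + stats::rnorm(nr * nc, 0, sigma)
    }
  }
  img[img < 0] <- 0

  pixarea <- sr * sc
  slice <- image_slice(patient_id, slice_index,
                       position_mm = slice_index * 1.0,
                       pixels = img, spacing_mm = cfg$spacing_mm)
  ann <- annotation_set(
    patient_id, slice_index, lumen_center = lumen,
    outer_wall = ellipse_polygon(lumen, g$outer_wall_contour_radius,
                                 g$outer_wall_contour_radius),
    scm = ellipse_polygon(scm_c, scm_ab[1], scm_ab[2]),
    adjacent_muscle = ellipse_polygon(adj_c, adj_ab[1], adj_ab[2])
  )
  truth <- list(
    iph_mask = iph_mask,
    iph_present = present,
    iph_area_mm2 = sum(iph_mask) * pixarea,
    calcified_fraction = calc_frac,
    contrast_ratio_used = cfg$iph_contrast_ratio
  )
  list(slice = slice, annotation = ann, truth = truth)
}

#' Generate a synthetic phantom cohort
#'
#' Produces images, annotations, histology-style truth rows and per-slice
#' truth masks for a whole cohort. All randomness derives from
#' `config$seed` through a per-patient sub-stream, so a given configuration
#' always yields the identical cohort.
#'
#' @param config a [phantom_config()].
#' @return object of class `iph_cohort`: named lists `slices`,
#'   `annotations`, `truth` (keys `"patient/slice"`), a `histology` data
#'   frame in the [read_histology()] layout, and the `config`.
#' @export
generate_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  slices <- list(); anns <- list(); truths <- list(); hist_rows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    set.seed(.patient_seed(config$seed, i))
    for (j in seq_len(config$slices_per_patient) - 1L) {
      out <- .paint_slice(config, pid, j)
      key <- paste(pid, j, sep = "/")
      slices[[key]] <- out$slice
      anns[[key]] <- out$annotation
      truths[[key]] <- out$truth
      hist_rows[[key]] <- data.frame(
        patient_id = pid,
        position_mm = out$slice$position_mm,
        iph_present = out$truth$iph_present,
        iph_area_mm2 = out$truth$iph_area_mm2,
        calcified_fraction = if (out$truth$iph_present)
          out$truth$calcified_fraction else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  hist <- do.call(rbind, hist_rows)
  rownames(hist) <- NULL
  structure(
    list(slices = slices, annotations = anns, histology = hist,
         truth = truths, config = config),
    class = "iph_cohort"
  )
}

#' @export
print.iph_cohort <- function(x, ...) {
  np <- length(unique(vapply(x$slices, function(s) s$patient_id, character(1))))
  cat(sprintf("<iph_cohort> %d slices from %d patients (%d IPH+ by truth)\n",
              length(x$slices), np, sum(x$histology$iph_present)))
  invisible(x)
}

#' Slice position table of a cohort
#'
#' @param cohort an `iph_cohort`.
#' @return data frame `patient_id`, `slice_index`, `position_mm`.
#' @export
slice_table <- function(cohort) {
  stopifnot(inherits(cohort, "iph_cohort"))
  df <- do.call(rbind, lapply(cohort$slices, function(s) data.frame(
    patient_id = s$patient_id, slice_index = s$slice_index,
    position_mm = s$position_mm, stringsAsFactors = FALSE
  )))
  rownames(df) <- NULL
  df
}
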