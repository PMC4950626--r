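# Independent oracles, kept deliberately different in structure from the
# package implementation: the rasterizer sweeps edges over the whole pixel
# grid, so the oracles here work one point at a time; the ROC uses
# trapezoidal integration, so the AUC oracle enumerates pairs.

# even-odd point-in-polygon for ONE point, vectorized over edges
oracle_point_in_polygon <- function(x, y, poly) {
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  spans <- (y1 > y) != (y2 > y)
  keep <- spans & (y2 != y1)
  if (!any(keep)) return(FALSE)
  xint <- x1[keep] + (y - y1[keep]) * (x2[keep] - x1[keep]) / (y2[keep] - y1[keep])
  sum(x < xint) %% 2 == 1
}

# brute-force polygon mask: loop over every pixel center
oracle_polygon_mask <- function(poly, slice) {
  d <- dim(slice$pixels)
  ys <- (seq_len(d[1]) - 1) * slice$spacing_mm[1]
  xs <- (seq_len(d[2]) - 1) * slice$spacing_mm[2]
  m <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      m[i, j] <- oracle_point_in_polygon(xs[j], ys[i], poly)
  m
}

# brute-force circle mask: per-pixel distance check
oracle_circle_mask <- function(center, diameter_mm, slice) {
  d <- dim(slice$pixels)
  ys <- (seq_len(d[1]) - 1) * slice$spacing_mm[1]
  xs <- (seq_len(d[2]) - 1) * slice$spacing_mm[2]
  m <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      m[i, j] <- sqrt((xs[j] - center[1])^2 + (ys[i] - center[2])^2) <=
        diameter_mm / 2
  m
}

# tie-corrected Mann-Whitney concordance: sum(concordant + 0.5 tied) / (n+ n-)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  sum(cmp) / (length(pos) * length(neg))
}

# star-shaped polygon around a center: vertex angles from normalized positive
# increments, so every angular gap stays below pi and the radial polygon is
# simple by construction (needs >= 4 vertices)
random_simple_polygon <- function(n_vertices, center = c(32, 32), rmax = 28) {
  stopifnot(n_vertices >= 4)
  u <- runif(n_vertices, 0.5, 1)
  th <- runif(1, 0, 2 * pi) + 2 * pi * cumsum(u) / sum(u)
  r <- runif(n_vertices, 0.15 * rmax, rmax)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# blank slice for rasterization tests
blank_slice <- function(nr = 64, nc = 64, spacing = c(1, 1), value = 1,
                        patient = "T", index = 0, position = 0) {
  image_slice(patient, index, position, matrix(value, nr, nc), spacing)
}
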