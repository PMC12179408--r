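## Per-particle morphometry in physical units.
##
## Conventions follow the ImageJ particle-analysis definitions: perimeter
## from the sub-pixel outer contour, circularity 4*pi*A/P^2 clipped at 1,
## aspect ratio and roundness from the area-preserving moment-equivalent
## ellipse, solidity against the convex hull of the contour, and cell
## length/width as the maximum/minimum Feret (caliper) diameters.

# Outer contour of a binary mask as a closed sub-pixel polygon (pixel
# units, columns = x, rows = y). The mask is cropped to its bounding box
# before marching squares; the 0.5-level ring passes through pixel-edge
# midpoints. With `upsample` the mask is first replicated 2x so the ring
# hugs the pixel boundary with quarter-pixel corner chamfers - the
# perimeter estimator - and with `simplify_eps > 0` the polygon is
# Douglas-Peucker simplified so digital staircases along straight or
# gently curved edges collapse to straight segments (the raw staircase
# inflates smooth perimeters by 5-10%; true corners deviate beyond the
# tolerance and are preserved). The longest ring is the outer boundary.
particle_contour <- function(mask, simplify_eps = 0, upsample = FALSE) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask: no contour")
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  sub <- mask[r0:r1, c0:c1, drop = FALSE] * 1
  if (upsample)
    sub <- sub[rep(seq_len(nrow(sub)), each = 2),
               rep(seq_len(ncol(sub)), each = 2), drop = FALSE]
  padded <- matrix(0, nrow(sub) + 2, ncol(sub) + 2)
  padded[2:(nrow(sub) + 1), 2:(ncol(sub) + 1)] <- sub
  cl <- grDevices::contourLines(x = 0:(nrow(sub) + 1),
                                y = 0:(ncol(sub) + 1),
                                z = padded, levels = 0.5)
  lens <- vapply(cl, function(p) length(p$x), 0L)
  ring <- cl[[which.max(lens)]]
  # contourLines' x follows rows (our y); swap to (x = col, y = row) and
  # map back into full-mask pixel coordinates
  pts <- if (upsample)
    cbind(x = ring$y / 2 + 0.25 + (c0 - 1),
          y = ring$x / 2 + 0.25 + (r0 - 1))
  else cbind(x = ring$y + (c0 - 1), y = ring$x + (r0 - 1))
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (simplify_eps > 0) pts <- dp_simplify(pts, simplify_eps)
  pts
}

# Iterative Douglas-Peucker polyline simplification (closed polygon:
# endpoints are the first vertex and the farthest vertex from it).
dp_simplify <- function(p, eps) {
  n <- nrow(p)
  if (n <= 3) return(p)
  d0 <- (p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2
  far <- which.max(d0)
  keep <- rep(FALSE, n)
  keep[c(1L, far)] <- TRUE
  segs <- list(c(1L, far), c(far, n + 1L))   # n+1 wraps to vertex 1
  at <- function(i) if (i > n) p[i - n, ] else p[i, ]
  while (length(segs)) {
    seg <- segs[[length(segs)]]
    segs[[length(segs)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- at(i); b <- at(j)
    ab <- b - a
    len <- sqrt(sum(ab^2))
    mid <- (i + 1):(j - 1)
    midw <- ifelse(mid > n, mid - n, mid)
    d <- if (len == 0)
      sqrt((p[midw, 1] - a[1])^2 + (p[midw, 2] - a[2])^2)
    else abs((p[midw, 1] - a[1]) * ab[2] -
               (p[midw, 2] - a[2]) * ab[1]) / len
    k <- which.max(d)
    if (d[k] > eps) {
      m <- mid[k]
      keep[ifelse(m > n, m - n, m)] <- TRUE
      segs <- c(segs, list(c(i, m), c(m, j)))
    }
  }
  p[keep, , drop = FALSE]
}

polygon_perimeter <- function(pts) {
  d <- sqrt(diff(c(pts[, 1], pts[1, 1]))^2 +
            diff(c(pts[, 2], pts[1, 2]))^2)
  sum(d)
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Maximum caliper diameter: attained at a pair of convex-hull vertices.
feret_max <- function(hull) {
  d2 <- as.matrix(stats::dist(hull))^2
  idx <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  list(value = sqrt(max(d2)), from = hull[idx[1], ], to = hull[idx[2], ])
}

# Minimum caliper diameter (min width over directions): for a convex
# polygon it is attained perpendicular to one of its edges.
feret_min <- function(hull) {
  n <- nrow(hull)
  if (n < 3) return(0)
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- (hull[, 1] - hull[i, 1]) * nrm[1] +
            (hull[, 2] - hull[i, 2]) * nrm[2]
    best <- min(best, max(proj) - min(proj))
  }
  best
}

# Exhaustive oracle used in tests: max over all contour-point pairs and
# min projection extent over a fine sweep of directions.
feret_oracle <- function(pts, angle_step_deg = 0.1) {
  d2max <- 0
  n <- nrow(pts)
  for (i in seq_len(n - 1)) {
    d2 <- (pts[(i + 1):n, 1] - pts[i, 1])^2 +
          (pts[(i + 1):n, 2] - pts[i, 2])^2
    d2max <- max(d2max, max(d2))
  }
  angles <- seq(0, 180 - angle_step_deg, by = angle_step_deg) * pi / 180
  wmin <- Inf
  for (a in angles) {
    proj <- pts[, 1] * -sin(a) + pts[, 2] * cos(a)
    wmin <- min(wmin, max(proj) - min(proj))
  }
  list(max = sqrt(d2max), min = wmin)
}

# Area-preserving moment-equivalent ellipse of a pixel set (pixel units).
# Axis directions/ratio come from the second central moments (with the
# 1/12 per-pixel term); axes are then scaled so the ellipse area equals
# the pixel-count area, as ImageJ's "Fit Ellipse" does.
moment_ellipse <- function(xs, ys) {
  n <- length(xs)
  mx <- mean(xs); my <- mean(ys)
  uxx <- sum((xs - mx)^2) / n + 1 / 12
  uyy <- sum((ys - my)^2) / n + 1 / 12
  uxy <- sum((xs - mx) * (ys - my)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  l2 <- max(l2, 1 / 12)                      # 1-px-wide degenerate floor
  ratio <- sqrt(l1 / l2)
  minor <- sqrt(4 * n / (pi * ratio))
  theta <- 0.5 * atan2(2 * uxy, uxx - uyy)
  list(major = minor * ratio, minor = minor, ratio = ratio,
       theta_deg = (theta * 180 / pi) %% 180)
}

#' Measure one particle
#'
#' Computes the full morphometric record of a labeled particle in physical
#' units: area, perimeter, circularity, aspect ratio, roundness, solidity,
#' their product and ratio features, Feret length/width and the fitted
#' ellipse axes.
#'
#' @param particles a [particle_set()].
#' @param particle_id label of the particle to measure.
#' @param pixel_size_um pixel size; defaults to the set's calibration.
#' @return One-row data frame (see [measure_all()] for columns).
#' @export
measure_particle <- function(particles, particle_id,
                             pixel_size_um = particles$pixel_size_um) {
  mask <- particle_mask(particles, particle_id)
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2]; ys <- idx[, 1]               # cols = x, rows = y
  n_px <- nrow(idx)
  area <- n_px * pixel_size_um^2
  perim <- polygon_perimeter(
    particle_contour(mask, simplify_eps = 0.9, upsample = TRUE)) *
    pixel_size_um
  circ <- min(4 * pi * area / perim^2, 1)
  ell <- moment_ellipse(xs, ys)
  major_um <- ell$major * pixel_size_um
  minor_um <- ell$minor * pixel_size_um
  ar <- ell$ratio
  roundness <- min(4 * area / (pi * major_um^2), 1)
  contour <- particle_contour(mask)
  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  hull_area <- polygon_area(hull) * pixel_size_um^2
  solidity <- min(area / hull_area, 1)
  # caliper diameters carry a systematic half-pixel rasterization bias
  # (the mid-crack contour peaks ride outside the true boundary); it is
  # subtracted, with a one-pixel floor for degenerate particles
  fmax <- feret_max(hull)
  length_um <- max(fmax$value - 0.5, 1) * pixel_size_um
  width_um <- max(feret_min(hull) - 0.5, 1) * pixel_size_um
  data.frame(
    particle_id = particle_id,
    area_um2 = area,
    perimeter_um = perim,
    circularity = circ,
    aspect_ratio = ar,
    roundness = roundness,
    solidity = solidity,
    ar_x_solidity = ar * solidity,
    scaled_perimeter_area = perim / sqrt(area),
    length_um = length_um,
    width_um = width_um,
    ellipse_major_um = major_um,
    ellipse_minor_um = minor_um,
    orientation_deg = ell$theta_deg,
    qualified = NA_integer_)
}

#' Measure every particle in a set
#'
#' One [measure_particle()] record per particle, ordered by id. The
#' `qualified` column is `NA` until filled by [classify()].
#'
#' @param particles a [particle_set()].
#' @param pixel_size_um pixel size; defaults to the set's calibration.
#' @return Data frame with columns `particle_id`, `area_um2`,
#'   `perimeter_um`, `circularity`, `aspect_ratio`, `roundness`,
#'   `solidity`, `ar_x_solidity`, `scaled_perimeter_area`, `length_um`,
#'   `width_um`, `ellipse_major_um`, `ellipse_minor_um`,
#'   `orientation_deg`, `qualified`.
#' @examples
#' sp <- cell_spec("intact_rod", 90, 22, 10, NA, center = c(50, 35))
#' sc <- render_scene(c(160, 110), 0.65, list(sp), noise_sd = 0, seed = 1)
#' ps <- segment(sc$image)
#' measure_all(ps)[, c("area_um2", "length_um", "width_um")]
#' @export
measure_all <- function(particles, pixel_size_um = particles$pixel_size_um) {
  if (particles$n_particles == 0) {
    out <- measure_particle_template()
    return(out)
  }
  do.call(rbind, lapply(seq_len(particles$n_particles), function(id)
    measure_particle(particles, id, pixel_size_um)))
}

measure_particle_template <- function() {
  data.frame(particle_id = integer(), area_um2 = numeric(),
             perimeter_um = numeric(), circularity = numeric(),
             aspect_ratio = numeric(), roundness = numeric(),
             solidity = numeric(), ar_x_solidity = numeric(),
             scaled_perimeter_area = numeric(), length_um = numeric(),
             width_um = numeric(), ellipse_major_um = numeric(),
             ellipse_minor_um = numeric(), orientation_deg = numeric(),
             qualified = integer())
}
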