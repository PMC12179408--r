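## Sarcomere striation period from the axial intensity profile.

# bilinear interpolation of image intensities at (x, y) pixel-unit points
# (cols = x, rows = y; pixel centers at integer coordinates)
bilinear <- function(pixels, x, y) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 1L), nc - 1L); x1 <- x0 + 1L
  y0 <- pmin(pmax(y0, 1L), nr - 1L); y1 <- y0 + 1L
  v00 <- pixels[cbind(y0, x0)]; v10 <- pixels[cbind(y0, x1)]
  v01 <- pixels[cbind(y1, x0)]; v11 <- pixels[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) +
    fy * ((1 - fx) * v01 + fx * v11)
}

#' Axial intensity profile of a particle
#'
#' Samples the image along the particle's Feret-length axis at pixel
#' pitch, averaging across a perpendicular band; positions are measured in
#' micrometres from one cell pole. Only sample points inside the particle
#' mask contribute, so the background does not dilute the striation
#' signal.
#'
#' @param image the [calibrated_image()] the particles came from.
#' @param particles a [particle_set()].
#' @param particle_id particle to profile (length must be >= 10 um).
#' @param band_width_um width of the averaging band perpendicular to the
#'   long axis.
#' @param step_px axial sampling step in pixels. The default quarter-pixel
#'   step keeps ~10 samples per sarcomere period even when the period is
#'   only 2-3 pixels, which the peak interpolation in [measure_period()]
#'   needs for sub-percent accuracy.
#' @return data frame `position_um`, `intensity`.
#' @export
axial_profile <- function(image, particles, particle_id,
                          band_width_um = 5, step_px = 0.25) {
  px <- particles$pixel_size_um
  mask <- particle_mask(particles, particle_id)
  contour <- particle_contour(mask)
  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  fmax <- feret_max(hull)
  len_um <- fmax$value * px
  if (len_um < 10)
    stop(sprintf("particle %d is shorter than 10 um (%.1f um)",
                 particle_id, len_um))
  u <- (fmax$to - fmax$from) / fmax$value          # axis unit vector
  nvec <- c(-u[2], u[1])
  s <- seq(0, fmax$value, by = step_px)            # axial, pixel units
  toff <- seq(-band_width_um / 2, band_width_um / 2, by = px) / px
  prof <- vapply(s, function(si) {
    xs <- fmax$from[1] + si * u[1] + toff * nvec[1]
    ys <- fmax$from[2] + si * u[2] + toff * nvec[2]
    xi <- pmin(pmax(round(xs), 1L), ncol(mask))
    yi <- pmin(pmax(round(ys), 1L), nrow(mask))
    keep <- mask[cbind(yi, xi)]
    if (!any(keep)) return(NA_real_)
    mean(bilinear(image$pixels, xs[keep], ys[keep]))
  }, 0)
  ok <- !is.na(prof)
  data.frame(position_um = s[ok] * px, intensity = prof[ok])
}

#' Measure the striation period of an axial profile
#'
#' The profile is detrended by subtracting a moving average (window three
#' times the longest physiological period) and the period estimated from
#' the first prominent maximum of the unbiased autocorrelation, refined by
#' parabolic interpolation; a discrete-spectrum (periodogram) estimate is
#' available as cross-check. Estimates outside the physiological
#' 1.0-3.0 um range, or with too weak a correlation peak, give an invalid
#' record rather than a number.
#'
#' @param profile data frame from [axial_profile()].
#' @param method `"autocorrelation"` (default) or `"spectrum"`.
#' @param period_range admissible period range in micrometres.
#' @param min_confidence minimum normalized autocorrelation height for a
#'   valid record.
#' @param particle_id id copied into the record.
#' @return one-row data frame: `particle_id`, `period_um`,
#'   `n_striations`, `method`, `confidence`, `valid`.
#' @examples
#' pos <- seq(0, 100, by = 0.1625)
#' prof <- data.frame(position_um = pos,
#'                    intensity = 1 + 0.4 * cos(2 * pi * pos / 1.8))
#' measure_period(prof)$period_um
#' @export
measure_period <- function(profile, method = c("autocorrelation",
                                               "spectrum"),
                           period_range = c(1.0, 3.0),
                           min_confidence = 0.25,
                           particle_id = NA_integer_) {
  method <- match.arg(method)
  pos <- profile$position_um
  pitch <- stats::median(diff(pos))
  x <- profile$intensity
  n <- length(x)
  invalid <- function() data.frame(particle_id = particle_id,
                                   period_um = NA_real_,
                                   n_striations = NA_integer_,
                                   method = method,
                                   confidence = 0, valid = FALSE)
  if (n < 5 || diff(range(pos)) < 5 * period_range[1]) return(invalid())

  win <- max(3L, round(3 * period_range[2] / pitch))
  if (win %% 2 == 0) win <- win + 1L
  trend <- stats::filter(x, rep(1 / win, win), sides = 2)
  det <- x - trend
  det <- det[!is.na(det)]
  if (length(det) < 5 || stats::sd(det) == 0) return(invalid())
  det <- det - mean(det)

  lag_lo <- max(2L, floor(period_range[1] / pitch))
  lag_hi <- min(length(det) - 2L, ceiling(period_range[2] / pitch))
  if (lag_hi <= lag_lo) return(invalid())

  if (method == "autocorrelation") {
    m <- length(det)
    r0 <- sum(det^2) / m
    max_lag <- min(m - 2L, ceiling(4 * period_range[2] / pitch))
    r <- vapply(0:max_lag, function(l)
      sum(det[1:(m - l)] * det[(1 + l):m]) / (m - l), 0) / r0
    cand <- (lag_lo:lag_hi) + 1L          # index into r (lag 0 at 1)
    cand <- cand[cand < length(r)]
    is_max <- r[cand] > r[cand - 1L] & r[cand] >= r[cand + 1L]
    if (!any(is_max)) return(invalid())
    peaks <- cand[is_max]
    # first peak at least 80% as high as the strongest one in range:
    # prefers the fundamental over a same-height harmonic
    strongest <- max(r[peaks])
    if (strongest < min_confidence) return(invalid())
    fundamental <- peaks[which(r[peaks] >= 0.8 * strongest)[1]]
    T0 <- fundamental - 1L
    # refine by harmonic regression: locate the autocorrelation maxima
    # near k*T0 for the first few harmonics (each with a 3-point
    # parabola) and take the least-squares slope through the origin;
    # averaging across harmonics cancels the sampling/interpolation
    # ripple a single-peak refinement is sensitive to
    K <- min(5L, max(1L, floor((max_lag - 1L) / T0)))
    ks <- integer(); lag_k <- numeric()
    for (k in seq_len(K)) {
      centre <- k * T0
      wlo <- max(2L, centre - floor(T0 / 3))
      whi <- min(max_lag - 1L, centre + floor(T0 / 3))
      if (whi <= wlo) next
      ii <- (wlo:whi) + 1L
      pk <- ii[which.max(r[ii])]
      y1 <- r[pk - 1L]; y2 <- r[pk]; y3 <- r[pk + 1L]
      den <- y1 - 2 * y2 + y3
      shift <- if (abs(den) > .Machine$double.eps)
        0.5 * (y1 - y3) / den else 0
      ks <- c(ks, k)
      lag_k <- c(lag_k, pk - 1L + shift)
    }
    period <- sum(ks * lag_k) / sum(ks^2) * pitch
    conf <- min(max(r[fundamental], 0), 1)
  } else {
    m <- length(det)
    nfft <- 2^ceiling(log2(m * 8))
    p <- Mod(fft(c(det, rep(0, nfft - m))))^2
    freq <- (0:(nfft - 1)) / (nfft * pitch)
    band <- which(freq > 0 & 1 / freq >= period_range[1] &
                    1 / freq <= period_range[2])
    if (length(band) < 3) return(invalid())
    pk <- band[which.max(p[band])]
    y1 <- p[pk - 1L]; y2 <- p[pk]; y3 <- p[pk + 1L]
    denom <- y1 - 2 * y2 + y3
    shift <- if (abs(denom) > .Machine$double.eps)
      0.5 * (y1 - y3) / denom else 0
    period <- 1 / (freq[pk] + shift / (nfft * pitch))
    conf <- min(y2 / sum(p[band]), 1)
    if (conf < min_confidence / 5) return(invalid())
  }
  if (is.na(period) || period < period_range[1] ||
      period > period_range[2]) return(invalid())
  data.frame(particle_id = particle_id, period_um = period,
             n_striations = as.integer(floor(diff(range(pos)) / period)),
             method = method, confidence = conf, valid = TRUE)
}

#' Measure sarcomere periods for qualified particles
#'
#' Convenience wrapper: axial profile + period estimate per particle.
#'
#' @param image the [calibrated_image()].
#' @param particles a [particle_set()].
#' @param particle_ids particles to measure (default all).
#' @param band_width_um averaging band width.
#' @param ... passed to [measure_period()].
#' @return data frame, one row per particle.
#' @export
measure_sarcomeres <- function(image, particles,
                               particle_ids = seq_len(particles$n_particles),
                               band_width_um = 5, ...) {
  rows <- lapply(particle_ids, function(id) {
    prof <- tryCatch(axial_profile(image, particles, id, band_width_um),
                     error = function(e) NULL)
    if (is.null(prof))
      return(data.frame(particle_id = id, period_um = NA_real_,
                        n_striations = NA_integer_,
                        method = "autocorrelation", confidence = 0,
                        valid = FALSE))
    measure_period(prof, particle_id = id, ...)
  })
  do.call(rbind, rows)
}
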