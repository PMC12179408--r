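#' Labeled particle set
#'
#' Result of [segment()]: an integer label map (0 = background, labels
#' consecutive 1..n over 8-connected components) plus provenance.
#'
#' @param label_map integer matrix.
#' @param pixel_size_um pixel size, micrometres.
#' @param provenance list of segmentation parameters.
#' @return object of class `particle_set`.
#' @export
particle_set <- function(label_map, pixel_size_um, provenance = list()) {
  structure(list(label_map = label_map,
                 n_particles = max(0L, max(label_map)),
                 pixel_size_um = pixel_size_um,
                 provenance = provenance),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particle(s), %d x %d px @ %.3g um/px\n",
              x$n_particles, ncol(x$label_map), nrow(x$label_map),
              x$pixel_size_um))
  invisible(x)
}

#' Segment a calibrated micrograph into particles
#'
#' Threshold (Otsu by default), optionally fill holes, label 8-connected
#' components, then apply the physical size gate and optional border
#' exclusion; surviving particles are renumbered consecutively. This is the
#' analyze-particles stage of the workflow: touching cells are deliberately
#' not split, they are routed to the downstream qualification classifier.
#'
#' @param image a [calibrated_image()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold intensity when `threshold_method`
#'   is `"fixed"`; must lie within the image intensity range.
#' @param min_area_um2,max_area_um2 size gate in square micrometres. The
#'   defaults bracket isolated adult cardiomyocyte surfaces (group means
#'   +/- 3 SD).
#' @param exclude_edges drop components touching the image border.
#' @param fill_holes fill enclosed background holes before labeling, so
#'   solidity reflects the outline (analyze-particles "include holes").
#' @return A [particle_set()].
#' @examples
#' sp <- cell_spec("intact_rod", 100, 24, 0, NA, center = c(55, 30))
#' sc <- render_scene(c(180, 100), 0.65, list(sp), noise_sd = 0.02, seed = 1)
#' segment(sc$image)
#' @export
segment <- function(image, threshold_method = c("otsu", "fixed"),
                    fixed_threshold = NULL,
                    min_area_um2 = 500, max_area_um2 = 15000,
                    exclude_edges = FALSE, fill_holes = TRUE) {
  threshold_method <- match.arg(threshold_method)
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) == 0)
    stop(sprintf("saturated/constant image: cannot threshold (method '%s')",
                 threshold_method))
  thr <- if (threshold_method == "otsu") {
    # EBImage::otsu works on [0,1]-ranged images; rescale and map back
    scaled <- (px - rng[1]) / diff(rng)
    rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
  } else {
    if (is.null(fixed_threshold) || fixed_threshold < rng[1] ||
        fixed_threshold > rng[2])
      stop("fixed_threshold must lie within the image intensity range")
    fixed_threshold
  }
  fg <- px > thr
  if (!any(fg)) {
    warning("no foreground above threshold: empty particle set")
    return(particle_set(matrix(0L, nrow(px), ncol(px)),
                        image$pixel_size_um,
                        list(threshold = thr, method = threshold_method)))
  }
  if (fill_holes) fg <- EBImage::fillHull(fg * 1) > 0
  lab <- .cc_label_2d(fg)
  lab <- filter_particles(lab, image$pixel_size_um, min_area_um2,
                          max_area_um2, exclude_edges)
  particle_set(lab, image$pixel_size_um,
               list(threshold = thr, method = threshold_method,
                    min_area_um2 = min_area_um2,
                    max_area_um2 = max_area_um2,
                    exclude_edges = exclude_edges,
                    fill_holes = fill_holes))
}

# size gate + border exclusion + consecutive renumbering
filter_particles <- function(lab, pixel_size_um, min_area_um2, max_area_um2,
                             exclude_edges) {
  if (max(lab) == 0L) return(lab)
  px_area <- pixel_size_um^2
  counts <- tabulate(lab, nbins = max(lab))
  keep <- counts * px_area >= min_area_um2 &
          counts * px_area <= max_area_um2
  if (exclude_edges) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    keep[border[border > 0]] <- FALSE
  }
  remap <- integer(max(lab))
  remap[keep] <- seq_len(sum(keep))
  out <- lab
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Extract the binary mask of one particle
#'
#' @param particles a [particle_set()].
#' @param particle_id label of the particle.
#' @return logical matrix the size of the label map.
#' @export
particle_mask <- function(particles, particle_id) {
  if (particle_id < 1 || particle_id > particles$n_particles)
    stop(sprintf("particle %d does not exist (set has %d)", particle_id,
                 particles$n_particles))
  particles$label_map == particle_id
}
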