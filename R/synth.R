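#' Synthetic cardiomyocyte specification
#'
#' Describes one object to render: an intact rod-shaped cell (capsule
#' geometry with sinusoidal striation), a touching/overlaying pair of rods,
#' a rounded cell, or a small fragment. Geometry is in micrometres;
#' orientation is the angle of the long axis in degrees, in \[0, 180).
#'
#' @param cell_class one of `"intact_rod"`, `"touching_pair"`, `"rounded"`,
#'   `"fragment"`.
#' @param length_um,width_um capsule length and width (length >= width;
#'   rounded cells have length == width).
#' @param orientation_deg long-axis angle in degrees.
#' @param sarcomere_period_um striation period, or `NA` for unstriated.
#' @param center (x, y) position in micrometres, or `c(NA, NA)` if not yet
#'   placed (see [place_specs()]).
#' @param intensity peak fluorescence intensity in (0, 1].
#' @param volume_um3 target 3D volume for [render_stack()]; `NA` uses the
#'   default depth ratio instead.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(cell_class = c("intact_rod", "touching_pair",
                                     "rounded", "fragment"),
                      length_um, width_um, orientation_deg = 0,
                      sarcomere_period_um = NA_real_,
                      center = c(NA_real_, NA_real_),
                      intensity = 0.8, volume_um3 = NA_real_) {
  cell_class <- match.arg(cell_class)
  if (length_um <= 0 || width_um <= 0)
    stop("length_um and width_um must be positive")
  if (cell_class == "rounded" && abs(length_um - width_um) > 1e-9)
    stop("rounded cells must have length_um == width_um")
  if (cell_class %in% c("intact_rod", "touching_pair") &&
      length_um < width_um)
    stop("length_um must be >= width_um for rod-shaped cells")
  if (intensity <= 0 || intensity > 1)
    stop("intensity must be in (0, 1]")
  structure(
    list(cell_class = cell_class, length_um = length_um,
         width_um = width_um,
         orientation_deg = orientation_deg %% 180,
         sarcomere_period_um = sarcomere_period_um,
         center = as.numeric(center), intensity = intensity,
         volume_um3 = volume_um3),
    class = "cell_spec")
}

#' Reference morphometric parameters per experimental group
#'
#' Mean and standard deviation of cell length, width, sarcomere period and
#' 3D volume for the four study conditions (control, angiotensin-II-treated,
#' isoproterenol-treated, aged), used as the defaults of
#' [sample_population()]. Units: micrometres (lengths), cubic micrometres
#' (volume).
#'
#' @param group `"control"`, `"ang"`, `"iso"` or `"old"`.
#' @return Named list of `c(mean, sd)` pairs.
#' @export
group_reference_params <- function(group = c("control", "ang", "iso", "old")) {
  group <- match.arg(group)
  ref <- list(
    control = list(length_um = c(139.42, 33.06), width_um = c(28.78, 7.93),
                   sarcomere_um = c(1.801, 0.034),
                   volume_um3 = c(35368.88, 19283.40)),
    ang     = list(length_um = c(154.09, 37.52), width_um = c(31.44, 8.29),
                   sarcomere_um = c(1.829, 0.045),
                   volume_um3 = c(56919.39, 28243.97)),
    iso     = list(length_um = c(146.12, 34.29), width_um = c(31.15, 8.96),
                   sarcomere_um = c(1.797, 0.083),
                   volume_um3 = c(48895.67, 21910.03)),
    old     = list(length_um = c(147.24, 36.20), width_um = c(34.48, 10.44),
                   sarcomere_um = c(1.794, 0.031),
                   volume_um3 = c(51928.17, 29308.98)))
  ref[[group]]
}

#' Sample a population of cell specifications
#'
#' Lengths and widths are drawn from truncated normals (width >= 5 um,
#' length >= width); sarcomere periods and target volumes likewise. Class
#' composition is exact: counts are allocated by the largest-remainder rule
#' so a requested 97/3 mix of 100 cells yields exactly 97 and 3. A
#' multinomial mode is available for stochastic composition.
#'
#' @param n_cells number of specifications to draw.
#' @param group_params named list of `c(mean, sd)` as returned by
#'   [group_reference_params()], or a group name.
#' @param class_proportions named fractions over the four classes, summing
#'   to 1. Default reflects the ~97% rod-shaped yield of an optimized
#'   isolation.
#' @param seed RNG seed.
#' @param orientation_range range of long-axis angles to draw from, degrees.
#' @param multinomial draw class counts multinomially instead of exactly.
#' @return list of [cell_spec()] objects (centers unset).
#' @examples
#' specs <- sample_population(10, "control", seed = 1)
#' table(vapply(specs, function(s) s$cell_class, ""))
#' @export
sample_population <- function(n_cells,
                              group_params = "control",
                              class_proportions = c(intact_rod = 0.97,
                                                    rounded = 0.02,
                                                    fragment = 0.01),
                              seed = 1L,
                              orientation_range = c(0, 180),
                              multinomial = FALSE) {
  if (is.character(group_params))
    group_params <- group_reference_params(group_params)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (any(vapply(group_params, function(p) p[1], 0) < 0))
    stop("negative mean in group_params")
  if (any(vapply(group_params, function(p) p[2], 0) < 0))
    stop("negative sd in group_params")
  known <- c("intact_rod", "touching_pair", "rounded", "fragment")
  if (!all(names(class_proportions) %in% known))
    stop("unknown cell class in class_proportions")
  with_seed(seed, {
    counts <- if (multinomial) {
      stats::setNames(as.integer(
        stats::rmultinom(1, n_cells, class_proportions)),
        names(class_proportions))
    } else largest_remainder(n_cells, class_proportions)
    classes <- rep(names(counts), counts)
    lp <- group_params$length_um
    wp <- group_params$width_um
    sp <- group_params$sarcomere_um %||% c(1.801, 0.034)
    vp <- group_params$volume_um3
    specs <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      cls <- classes[i]
      ori <- runif(1, orientation_range[1], orientation_range[2]) %% 180
      inten <- min(max(rnorm(1, 0.8, 0.05), 0.5), 1)
      if (cls %in% c("intact_rod", "touching_pair")) {
        W <- rnorm_trunc(1, wp[1], wp[2], lower = 5)
        L <- rnorm_trunc(1, lp[1], lp[2], lower = W)
        s <- rnorm_trunc(1, sp[1], sp[2], lower = 1.0, upper = 3.0)
        # symmetric truncation keeps the group mean volume unbiased while
        # excluding the non-physical lower tail of a wide normal
        V <- if (!is.null(vp))
          rnorm_trunc(1, vp[1], vp[2], lower = vp[1] - 1.8 * vp[2],
                      upper = vp[1] + 1.8 * vp[2])
        else NA_real_
        specs[[i]] <- cell_spec(cls, L, W, ori, s, intensity = inten,
                                volume_um3 = V)
      } else if (cls == "rounded") {
        # rounded (dedifferentiated/damaged) cells: disc of diameter drawn
        # from an inflated width distribution
        D <- rnorm_trunc(1, 1.6 * wp[1], 1.6 * wp[2], lower = 15)
        specs[[i]] <- cell_spec("rounded", D, D, ori, NA_real_,
                                intensity = inten)
      } else {
        # fragments: small debris, area well below one cell
        W <- runif(1, 5, 12)
        L <- W + runif(1, 2, 18)
        specs[[i]] <- cell_spec("fragment", L, W, ori, NA_real_,
                                intensity = inten)
      }
    }
    specs
  })
}

# rotated extents of a spec's bounding box, micrometres
spec_extent <- function(spec) {
  th <- spec$orientation_deg * pi / 180
  L <- spec$length_um; W <- spec$width_um
  pad <- if (spec$cell_class == "touching_pair") 1.6 else 1.0
  c(x = pad * (abs(L * cos(th)) + abs(W * sin(th))),
    y = pad * (abs(L * sin(th)) + abs(W * cos(th))))
}

#' Place specifications in a field without overlap
#'
#' Greedy shelf packing: cells are laid out row by row in order, each
#' taking its rotated bounding box plus a margin, with a small seeded
#' jitter. Errors if the requested cells cannot fit.
#'
#' @param specs list of [cell_spec()].
#' @param field_size_px field dimensions `c(nx, ny)` in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @param margin_um clearance between bounding boxes and to the border.
#' @param seed RNG seed for placement jitter.
#' @return `specs` with centers assigned.
#' @export
place_specs <- function(specs, field_size_px, pixel_size_um,
                        margin_um = 8, seed = 1L) {
  fx <- field_size_px[1] * pixel_size_um
  fy <- field_size_px[2] * pixel_size_um
  with_seed(seed, {
    x <- margin_um; y <- margin_um; row_h <- 0
    for (i in seq_along(specs)) {
      ext <- spec_extent(specs[[i]])
      if (x + ext["x"] + margin_um > fx) {   # new shelf
        x <- margin_um
        y <- y + row_h + margin_um
        row_h <- 0
      }
      if (y + ext["y"] + margin_um > fy)
        stop("field too small to place all cells without overlap")
      jx <- runif(1, 0, margin_um / 2); jy <- runif(1, 0, margin_um / 2)
      specs[[i]]$center <- c(x + ext["x"] / 2 + jx, y + ext["y"] / 2 + jy)
      x <- x + ext["x"] + margin_um
      row_h <- max(row_h, ext["y"])
    }
    specs
  })
}

# point-in-capsule test on micrometre coordinate grids (vectorized)
capsule_dist2 <- function(xs, ys, cx, cy, L, W, theta_deg) {
  th <- theta_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  h <- max((L - W) / 2, 0)
  dx <- xs - cx; dy <- ys - cy
  t <- dx * ux + dy * uy
  tc <- pmin(pmax(t, -h), h)
  px <- dx - tc * ux; py <- dy - tc * uy
  list(d2 = px^2 + py^2, axial = t)
}

# Decompose a spec into drawable capsule components. Touching pairs become
# two overlapping capsules sharing one label; the second capsule's pose is
# drawn from the current RNG stream (seeded by the caller).
spec_components <- function(spec, pixel_size_um) {
  base <- list(cx = spec$center[1], cy = spec$center[2],
               L = spec$length_um, W = spec$width_um,
               theta = spec$orientation_deg,
               striated = spec$cell_class %in% c("intact_rod",
                                                 "touching_pair") &&
                          !is.na(spec$sarcomere_period_um),
               period = spec$sarcomere_period_um)
  if (spec$cell_class != "touching_pair") return(list(base))
  # companion rod, overlapping the first by 2-8 px
  overlap_um <- runif(1, 2, 8) * pixel_size_um
  dtheta <- sample(c(-1, 1), 1) * runif(1, 8, 30)
  L2 <- 0.85 * spec$length_um; W2 <- 0.9 * spec$width_um
  th <- spec$orientation_deg * pi / 180
  nx <- -sin(th); ny <- cos(th)                      # unit normal
  off <- spec$width_um / 2 + W2 / 2 - overlap_um
  ax <- runif(1, -0.15, 0.15) * spec$length_um       # axial slide
  comp2 <- list(cx = spec$center[1] + off * nx + ax * cos(th),
                cy = spec$center[2] + off * ny + ax * sin(th),
                L = L2, W = W2, theta = (spec$orientation_deg + dtheta) %% 180,
                striated = base$striated, period = base$period)
  list(base, comp2)
}

#' Render a synthetic micrograph with ground truth
#'
#' Draws each specification into a calibrated field: intact rods as
#' capsules (stadium shapes) with multiplicative sinusoidal striation of
#' the given sarcomere period along the long axis, touching pairs as two
#' overlapping capsules under one label, rounded cells as discs and
#' fragments as small capsules. Additive Gaussian noise is applied last.
#' Where objects overlap, the pixel is owned by the lower spec index.
#' Rendering is bit-reproducible for a fixed (specs, seed).
#'
#' @param field_size_px `c(nx, ny)` field size in pixels (>= 64 each).
#' @param pixel_size_um pixel size, micrometres.
#' @param specs list of placed [cell_spec()] (see [place_specs()]); specs
#'   reaching beyond the field are clipped and flagged.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed.
#' @param striation_amplitude relative amplitude of the striation
#'   modulation `(1 + a cos(2 pi u / s)) / (1 + a)`.
#' @return An object of class `synthetic_scene`: list with `image`
#'   ([calibrated_image()]), `label_map` (integer matrix, 0 = background),
#'   `truth` (data frame, one row per spec) and `seed`.
#' @examples
#' sp <- cell_spec("intact_rod", 120, 25, 15, 1.8, center = c(60, 45))
#' sc <- render_scene(c(160, 140), 0.65, list(sp), noise_sd = 0.03, seed = 1)
#' max(sc$label_map)
#' @export
render_scene <- function(field_size_px, pixel_size_um, specs,
                         noise_sd = 0.05, seed = 1L,
                         striation_amplitude = 0.4) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (any(field_size_px < 64)) stop("field must be at least 64 x 64 px")
  nx <- as.integer(field_size_px[1]); ny <- as.integer(field_size_px[2])
  img <- matrix(0, nrow = ny, ncol = nx)   # rows = y, cols = x
  lab <- matrix(0L, nrow = ny, ncol = nx)
  truth <- truth_frame(specs)
  with_seed(seed, {
    for (k in seq_along(specs)) {
      comps <- spec_components(specs[[k]], pixel_size_um)
      clipped <- FALSE
      for (cp in comps) {
        half <- cp$L / 2 + pixel_size_um
        j0 <- floor((cp$cx - half) / pixel_size_um) + 1L
        j1 <- ceiling((cp$cx + half) / pixel_size_um)
        i0 <- floor((cp$cy - half) / pixel_size_um) + 1L
        i1 <- ceiling((cp$cy + half) / pixel_size_um)
        if (j0 < 1 || i0 < 1 || j1 > nx || i1 > ny) clipped <- TRUE
        j0 <- max(j0, 1L); i0 <- max(i0, 1L)
        j1 <- min(j1, nx); i1 <- min(i1, ny)
        if (j0 > j1 || i0 > i1) next
        jj <- j0:j1; ii <- i0:i1
        xs <- matrix((jj - 0.5) * pixel_size_um, nrow = length(ii),
                     ncol = length(jj), byrow = TRUE)
        ys <- matrix((ii - 0.5) * pixel_size_um, nrow = length(ii),
                     ncol = length(jj))
        g <- capsule_dist2(xs, ys, cp$cx, cp$cy, cp$L, cp$W, cp$theta)
        inside <- g$d2 <= (cp$W / 2)^2
        if (!any(inside)) next
        val <- specs[[k]]$intensity
        vals <- if (cp$striated) {
          a <- striation_amplitude
          val * (1 + a * cos(2 * pi * (g$axial + cp$L / 2) / cp$period)) /
            (1 + a)
        } else matrix(val, nrow = length(ii), ncol = length(jj))
        sub_img <- img[ii, jj, drop = FALSE]
        sub_lab <- lab[ii, jj, drop = FALSE]
        put <- inside & (sub_lab == 0L | sub_lab == k)
        sub_img[put] <- pmax(sub_img[put], vals[put])
        sub_lab[inside & sub_lab == 0L] <- k
        img[ii, jj] <- sub_img
        lab[ii, jj] <- sub_lab
      }
      truth$clipped[k] <- clipped
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                          nrow = ny)
  })
  structure(
    list(image = calibrated_image(img, pixel_size_um),
         label_map = lab, truth = truth, seed = as.integer(seed)),
    class = "synthetic_scene")
}

truth_frame <- function(specs) {
  if (length(specs) == 0)
    return(data.frame(index = integer(), cell_class = character(),
                      length_um = numeric(), width_um = numeric(),
                      orientation_deg = numeric(),
                      sarcomere_period_um = numeric(),
                      center_x_um = numeric(), center_y_um = numeric(),
                      intensity = numeric(), volume_um3 = numeric(),
                      clipped = logical()))
  data.frame(
    index = seq_along(specs),
    cell_class = vapply(specs, function(s) s$cell_class, ""),
    length_um = vapply(specs, function(s) s$length_um, 0),
    width_um = vapply(specs, function(s) s$width_um, 0),
    orientation_deg = vapply(specs, function(s) s$orientation_deg, 0),
    sarcomere_period_um = vapply(specs,
                                 function(s) s$sarcomere_period_um, 0),
    center_x_um = vapply(specs, function(s) s$center[1], 0),
    center_y_um = vapply(specs, function(s) s$center[2], 0),
    intensity = vapply(specs, function(s) s$intensity, 0),
    volume_um3 = vapply(specs, function(s) s$volume_um3, 0),
    clipped = FALSE)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px @ %.3g um/px, %d object(s), seed %d\n",
              ncol(x$image$pixels), nrow(x$image$pixels),
              x$image$pixel_size_um, nrow(x$truth), x$seed))
  invisible(x)
}

#' Analytic area of a capsule (stadium) outline
#'
#' `W * (L - W) + pi * W^2 / 4`: the closed form used as rasterization
#' oracle for rendered rods.
#'
#' @param length_um,width_um capsule dimensions, micrometres.
#' @return area in square micrometres.
#' @export
capsule_area <- function(length_um, width_um)
  width_um * (length_um - width_um) + pi * width_um^2 / 4

#' Render a single cell as a 3D z-stack
#'
#' The cell body is an elliptic-cylinder solid along the long axis:
#' cross-section an ellipse with horizontal axis `width_um` and vertical
#' (z) axis the cell depth. Depth is `width_um * depth_ratio` unless the
#' spec carries a target `volume_um3`, in which case depth is solved so
#' the analytic volume `pi/4 * W * D * L` equals the target. The truth
#' records the analytic volume.
#'
#' @param spec a [cell_spec()] (center ignored; the cell is centred).
#' @param voxel_um voxel dimensions `c(x, y, z)`, micrometres.
#' @param depth_slices number of z slices (>= 3); `NULL` sizes the stack to
#'   the cell depth plus one empty slice each side.
#' @param seed RNG seed (used for the additive noise).
#' @param depth_ratio cell depth as a fraction of width when no target
#'   volume is given.
#' @param noise_sd additive Gaussian noise sd.
#' @return A list with `stack` (3D array), `voxel_um`, `truth` (one-row
#'   data frame incl. `volume_um3`), `seed`.
#' @export
render_stack <- function(spec, voxel_um = c(0.5, 0.5, 1.0),
                         depth_slices = NULL, seed = 1L,
                         depth_ratio = 0.5, noise_sd = 0) {
  if (any(voxel_um <= 0)) stop("voxel dimensions must be positive")
  L <- spec$length_um; W <- spec$width_um
  D <- if (!is.na(spec$volume_um3)) {
    4 * spec$volume_um3 / (pi * W * L)
  } else W * depth_ratio
  vol_true <- pi / 4 * W * D * L
  nxv <- ceiling((L + 4) / voxel_um[1])
  nyv <- ceiling((W + 4) / voxel_um[2])
  nzv <- if (is.null(depth_slices)) ceiling(D / voxel_um[3]) + 2L
         else as.integer(depth_slices)
  if (nzv < 3) stop("depth_slices must be >= 3")
  cx <- nxv * voxel_um[1] / 2; cy <- nyv * voxel_um[2] / 2
  cz <- nzv * voxel_um[3] / 2
  xs <- (seq_len(nxv) - 0.5) * voxel_um[1]
  ys <- (seq_len(nyv) - 0.5) * voxel_um[2]
  zs <- (seq_len(nzv) - 0.5) * voxel_um[3]
  ax <- abs(xs - cx) <= L / 2                       # axial extent gate
  yy <- ((ys - cy) / (W / 2))^2
  stack <- array(0, c(nyv, nxv, nzv))
  for (z in seq_len(nzv)) {
    zz <- ((zs[z] - cz) / (D / 2))^2
    if (zz > 1) next
    sl <- outer(yy, as.numeric(ax), function(a, b) (a + zz <= 1) * b)
    stack[, , z] <- sl * spec$intensity
  }
  with_seed(seed, {
    if (noise_sd > 0)
      stack <- stack + array(rnorm(length(stack), 0, noise_sd), dim(stack))
  })
  truth <- truth_frame(list(spec))
  truth$volume_um3 <- vol_true
  truth$depth_um <- D
  list(stack = stack, voxel_um = as.numeric(voxel_um), truth = truth,
       seed = as.integer(seed))
}

#' Cuboid debug stack
#'
#' A solid axis-aligned cuboid of known voxel dimensions, whose analytic
#' volume is exactly `prod(dims_vox) * prod(voxel_um)`; used to verify the
#' voxel-count volume identity.
#'
#' @param dims_vox cuboid size in voxels `c(nx, ny, nz)`.
#' @param voxel_um voxel dimensions, micrometres.
#' @param pad empty voxels added on every side.
#' @return same shape of list as [render_stack()].
#' @export
cuboid_stack <- function(dims_vox = c(20, 10, 5),
                         voxel_um = c(0.5, 0.5, 1.0), pad = 2L) {
  stack <- array(0, c(dims_vox[2] + 2 * pad, dims_vox[1] + 2 * pad,
                      dims_vox[3] + 2 * pad))
  stack[pad + seq_len(dims_vox[2]), pad + seq_len(dims_vox[1]),
        pad + seq_len(dims_vox[3])] <- 1
  truth <- data.frame(index = 1L, cell_class = "cuboid",
                      volume_um3 = prod(dims_vox) * prod(voxel_um))
  list(stack = stack, voxel_um = as.numeric(voxel_um), truth = truth,
       seed = NA_integer_)
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered image as 16-bit TIFF (calibration in a sidecar
#' JSON), the label map as TIFF, the ground-truth table as CSV and the
#' scene parameters as JSON.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_tiff(scene$image, file.path(dir, paste0(stem, ".tif")))
  tiff::writeTIFF(scene$label_map / max(1L, max(scene$label_map)),
                  file.path(dir, paste0(stem, "_labels.tif")),
                  bits.per.sample = 16L)
  write.csv(scene$truth, file.path(dir, paste0(stem, "_truth.csv")),
            row.names = FALSE)
  jsonlite::write_json(list(seed = scene$seed,
                            pixel_size_um = scene$image$pixel_size_um,
                            n_objects = nrow(scene$truth)),
                       file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
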