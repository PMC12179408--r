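#' Calibrated intensity image
#'
#' A 2D intensity raster with its physical pixel size, the unit in which all
#' downstream measurements are expressed. Pixels are stored as a numeric
#' matrix (rows = y, columns = x), intensities typically in \[0, 1\].
#'
#' @param pixels numeric matrix of intensities.
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @param channel_name free-text channel label (e.g. "actin").
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(matrix(runif(64), 8, 8), pixel_size_um = 0.65)
#' img
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel_name = "morphology") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0)
    stop("pixels must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_name = channel_name),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px @ %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$channel_name))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Sidecar JSON next to a TIFF records the physical calibration, since
# baseline TIFF resolution tags do not carry micrometre units portably.
sidecar_path <- function(path) paste0(path, ".json")

#' Write a calibrated image (or z-stack) to TIFF
#'
#' 2D images are written as single-page TIFF, 3D arrays as multi-page
#' (one page per z-slice). The physical calibration is stored in a sidecar
#' JSON file `<path>.json` so it survives round-tripping.
#'
#' @param x a `calibrated_image`, or a 3D numeric array for stacks.
#' @param path output TIFF path.
#' @param voxel_um for stacks: numeric length-3 voxel dimensions
#'   (x, y, z) in micrometres.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, voxel_um = NULL) {
  if (inherits(x, "calibrated_image")) {
    px <- pmin(pmax(x$pixels, 0), 1)
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
    jsonlite::write_json(
      list(pixel_size_um = x$pixel_size_um, channel_name = x$channel_name),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else if (is.array(x) && length(dim(x)) == 3) {
    if (is.null(voxel_um) || length(voxel_um) != 3 || any(voxel_um <= 0))
      stop("stacks require positive voxel_um = c(x, y, z)")
    pages <- lapply(seq_len(dim(x)[3]),
                    function(z) pmin(pmax(x[, , z], 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(list(voxel_um = voxel_um), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  } else stop("x must be a calibrated_image or a 3D array")
  invisible(path)
}

#' Read a TIFF written by this package (or any calibrated TIFF)
#'
#' Single-page files return a `calibrated_image`; multi-page files return a
#' list with the 3D array and voxel dimensions. Calibration is taken from
#' the sidecar JSON when present, otherwise from the explicit arguments.
#'
#' @param path TIFF path.
#' @param pixel_size_um fallback pixel size if no sidecar file exists.
#' @param voxel_um fallback voxel dimensions for stacks.
#' @return `calibrated_image` or `list(stack, voxel_um)`.
#' @export
read_image_tiff <- function(path, pixel_size_um = NULL, voxel_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else list()
  if (length(pages) == 1) {
    ps <- meta$pixel_size_um %||% pixel_size_um
    if (is.null(ps)) stop("no pixel size: supply pixel_size_um")
    calibrated_image(pages[[1]], ps, meta$channel_name %||% "morphology")
  } else {
    vx <- meta$voxel_um %||% voxel_um
    if (is.null(vx)) stop("no voxel size: supply voxel_um")
    stack <- array(0, c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) stack[, , z] <- pages[[z]]
    list(stack = stack, voxel_um = as.numeric(vx))
  }
}
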