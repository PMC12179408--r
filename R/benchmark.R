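#' Synthetic labeled benchmark table
#'
#' Builds a labeled feature table for training and benchmarking the
#' qualification classifier. Each drawn specification is rendered into its
#' own calibrated tile, segmented and measured, and labeled from ground
#' truth: intact rods are qualified (1), touching pairs, rounded cells and
#' fragments are not (0). This stands in for a visually verified training
#' set; the label source is the generator's truth, not expert annotation.
#'
#' @param n_cells number of cells in the table.
#' @param class_proportions class mix; the default is the 70/30
#'   qualified/disqualified benchmark composition.
#' @param seed RNG seed.
#' @param group_params morphometric group parameters (see
#'   [sample_population()]).
#' @param pixel_size_um pixel size of the rendered tiles.
#' @param noise_sd additive noise of the rendered tiles.
#' @return Data frame: eight feature columns, `length_um`, `width_um`,
#'   `cell_class`, `label`.
#' @examples
#' b <- synth_benchmark(n_cells = 60, seed = 7)
#' table(b$cell_class, b$label)
#' @export
synth_benchmark <- function(n_cells = 1000,
                            class_proportions = c(intact_rod = 0.70,
                                                  touching_pair = 0.15,
                                                  rounded = 0.10,
                                                  fragment = 0.05),
                            seed = 7L,
                            group_params = "control",
                            pixel_size_um = 0.65,
                            noise_sd = 0.05) {
  specs <- sample_population(n_cells, group_params, class_proportions,
                             seed = seed, orientation_range = c(-20, 20))
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    m <- measure_single_spec(specs[[i]], pixel_size_um, noise_sd,
                             seed = seed + i)
    if (is.null(m)) next
    m$cell_class <- specs[[i]]$cell_class
    m$label <- as.integer(specs[[i]]$cell_class == "intact_rod")
    rows[[i]] <- m
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

# Render one spec centred in a tile sized to its rotated extent, segment
# with a permissive size gate (fragments must survive to be learned as
# disqualified), and return the largest particle's measurements.
measure_single_spec <- function(spec, pixel_size_um, noise_sd, seed) {
  ext <- spec_extent(spec)
  margin <- 8
  nx <- max(64L, ceiling((ext["x"] + 2 * margin) / pixel_size_um))
  ny <- max(64L, ceiling((ext["y"] + 2 * margin) / pixel_size_um))
  spec$center <- c(nx, ny) * pixel_size_um / 2
  scene <- render_scene(c(nx, ny), pixel_size_um, list(spec),
                        noise_sd = noise_sd, seed = seed)
  ps <- segment(scene$image, min_area_um2 = 30, max_area_um2 = Inf,
                fill_holes = TRUE)
  if (ps$n_particles == 0) return(NULL)
  areas <- tabulate(ps$label_map[ps$label_map > 0], ps$n_particles)
  measure_particle(ps, which.max(areas))
}
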