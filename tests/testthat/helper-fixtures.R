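# Small deterministic fixtures shared across tests; everything is built
# in code at test time.

disc_mask <- function(r = 35, pad = 6) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

square_mask <- function(side = 40, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

mask_particles <- function(mask, pixel_size_um = 1) {
  particle_set(cardiomorph:::.cc_label_2d(mask), pixel_size_um)
}

# one rod rendered alone in a tight field
rod_scene <- function(length_um = 137.81, width_um = 28.53,
                      orientation_deg = 0, period_um = NA,
                      pixel_size_um = 0.65, noise_sd = 0, seed = 1) {
  half <- length_um / 2 + 10
  spec <- cell_spec("intact_rod", length_um, width_um, orientation_deg,
                    period_um, center = c(half, half))
  render_scene(c(ceiling(2 * half / pixel_size_um),
                 ceiling(2 * half / pixel_size_um)),
               pixel_size_um, list(spec), noise_sd = noise_sd, seed = seed)
}

# cleanly separable labeled feature table (rods vs rounded), built from
# closed-form geometry rather than rendering, for fast classifier tests
separable_table <- function(n = 200, seed = 1) {
  stopifnot(n %% 2 == 0)
  cardiomorph:::with_seed(seed, {
    half <- n / 2
    rod_L <- rnorm(half, 140, 10); rod_W <- rnorm(half, 28, 2)
    rnd_D <- rnorm(half, 45, 4)
    area <- c(rod_W * (rod_L - rod_W) + pi * rod_W^2 / 4,
              pi * rnd_D^2 / 4)
    perim <- c(2 * (rod_L - rod_W) + pi * rod_W, pi * rnd_D)
    ar <- c(rnorm(half, 5, 0.3), rnorm(half, 1.1, 0.05))
    sol <- c(rnorm(half, 0.98, 0.005), rnorm(half, 0.99, 0.004))
    data.frame(
      area_um2 = area, perimeter_um = perim,
      circularity = pmin(4 * pi * area / perim^2, 1),
      aspect_ratio = ar,
      roundness = pmin(1 / ar, 1),
      solidity = pmin(sol, 1),
      ar_x_solidity = ar * pmin(sol, 1),
      scaled_perimeter_area = perim / sqrt(area),
      label = rep(c(1L, 0L), each = half))
  })
}
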