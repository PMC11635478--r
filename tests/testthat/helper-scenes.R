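# Shared fixtures: modest scenes reused across test files. All randomness is
# seeded through the generator itself.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# render an isolated-Gaussian-spot image directly from the closed form
# (pnorm differences), independent of the scene generator's rendering path
render_spots_oracle <- function(xy, intensities, dims, sigma = 1) {
  img <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(xy))) {
    cols <- 0:(dims[2] - 1); rows <- 0:(dims[1] - 1)
    px <- pnorm((cols + 0.5 - xy[i, 1]) / sigma) -
      pnorm((cols - 0.5 - xy[i, 1]) / sigma)
    py <- pnorm((rows + 0.5 - xy[i, 2]) / sigma) -
      pnorm((rows - 0.5 - xy[i, 2]) / sigma)
    img <- img + intensities[i] * outer(py, px)
  }
  img
}

# standard mid-size three-channel scene shared by colocalization tests
std_scene <- quiet(generate_scene(
  scene_params(field_size_px = c(200L, 200L),
               particle_density_per_um2 = 0.03, seed = 101)))
std_pre <- quiet(preprocess_field(std_scene$field))
std_particles <- quiet(composite_detect(std_pre))

# single-channel detection fixture helper
detect_one_channel <- function(img, params = detection_params(),
                               segment = TRUE) {
  f <- band_filter(img, params$kernel_size_px)
  sp <- detect_spots(f, img, params)
  if (segment) sp <- segment_strings(sp, f, img, params)
  sp
}
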