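# Synthetic TIRF scene generation --------------------------------------------
#
# Ground-truthed stand-ins for surface-anchored sEVP arrays: fields of
# diffraction-limited spots whose per-channel intensities follow a
# seven-subpopulation mixture, with copy-number-resolved antibody emission in
# the CD63 channel, multiplicative illumination inhomogeneity and an
# EM-CCD-like Poisson + Gaussian read-noise model.

#' The seven sEVP subpopulation labels
#'
#' Particles carrying the membrane probe COE are vesicular small extracellular
#' vesicles (sEV); COE-negative particles are non-vesicular nanoparticles
#' (NP). Within each branch the luminal marker CFSE and the surface marker
#' CD63 split the particles further; the all-negative combination is not a
#' detectable particle, leaving seven classes.
#'
#' @return Character vector of the seven labels, in canonical order
#'   (vesicular classes first).
#' @export
subpop_labels <- function() {
  c("sEV CFSE+CD63+", "sEV CFSE+CD63-", "sEV CFSE-CD63+", "sEV CFSE-CD63-",
    "NP CFSE+CD63+", "NP CFSE+CD63-", "NP CFSE-CD63+")
}

# Marker positivity for each of the seven labels (rows in subpop_labels order).
subpop_positivity <- function() {
  m <- rbind(
    c(TRUE,  TRUE,  TRUE),
    c(TRUE,  TRUE,  FALSE),
    c(TRUE,  FALSE, TRUE),
    c(TRUE,  FALSE, FALSE),
    c(FALSE, TRUE,  TRUE),
    c(FALSE, TRUE,  FALSE),
    c(FALSE, FALSE, TRUE))
  dimnames(m) <- list(subpop_labels(), c("COE", "CFSE", "CD63"))
  m
}

#' Parameters for the synthetic scene generator
#'
#' @param field_size_px Integer pair, image size as c(rows, cols).
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param particle_density_per_um2 Expected particles per square micrometre.
#' @param category_probs Seven non-negative mixture probabilities over
#'   [subpop_labels()], summing to 1.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels; the default
#'   1 px gives a diffraction-limited spot about 2 px across.
#' @param marker_intensity_model Per-channel log-normal parameters for the
#'   membrane (COE) and luminal (CFSE) markers: a list with elements `COE`
#'   and `CFSE`, each `list(median_adu=, gsd=)` (geometric SD > 1).
#' @param cd63_copy_model CD63 antibody copy-number model for CD63-positive
#'   particles: `list(type = "poisson", lambda =)` (zero-truncated), or
#'   `list(type = "weights", weights =)` over copy numbers 1..length(weights).
#' @param unit_intensity_mu_sigma Length-2 numeric, mean and SD (ADU) of the
#'   integrated intensity of one fluorophore-labelled antibody; emission per
#'   copy is drawn from this normal truncated at zero.
#' @param marker_correlation Latent Gaussian-copula correlations, a list with
#'   `coe_cfse`, `coe_cd63`, `cfse_cd63` in (-1, 1). Correlations act on the
#'   latent normal scale; CD63 enters through its copy number.
#' @param illumination_gradient Length-2 numeric `c(min_gain, max_gain)`,
#'   multiplicative gain ramping linearly left to right across the field.
#' @param background_offset_adu Uniform diffuse background level (ADU,
#'   pre-gain), subject to shot noise.
#' @param read_noise_sd_adu Additive Gaussian read noise SD (ADU).
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return A validated `scene_params` list.
#' @export
scene_params <- function(field_size_px = c(400L, 400L),
                         pixel_size_um = 0.25,
                         particle_density_per_um2 = 0.05,
                         category_probs = c(0.20, 0.15, 0.10, 0.15,
                                            0.15, 0.15, 0.10),
                         psf_sigma_px = 1.0,
                         marker_intensity_model = list(
                           COE  = list(median_adu = 9000, gsd = 1.8),
                           CFSE = list(median_adu = 8000, gsd = 1.8)),
                         cd63_copy_model = list(type = "poisson", lambda = 10),
                         unit_intensity_mu_sigma = c(1000, 150),
                         marker_correlation = list(coe_cfse = 0.8,
                                                   coe_cd63 = 0,
                                                   cfse_cd63 = 0),
                         illumination_gradient = c(1, 1),
                         background_offset_adu = 100,
                         read_noise_sd_adu = 3,
                         seed = 1L) {
  p <- list(field_size_px = as.integer(field_size_px),
            pixel_size_um = pixel_size_um,
            particle_density_per_um2 = particle_density_per_um2,
            category_probs = category_probs,
            psf_sigma_px = psf_sigma_px,
            marker_intensity_model = marker_intensity_model,
            cd63_copy_model = cd63_copy_model,
            unit_intensity_mu_sigma = unit_intensity_mu_sigma,
            marker_correlation = marker_correlation,
            illumination_gradient = illumination_gradient,
            background_offset_adu = background_offset_adu,
            read_noise_sd_adu = read_noise_sd_adu,
            seed = as.integer(seed))
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  stopifnot(length(p$field_size_px) == 2L, all(p$field_size_px >= 8L),
            p$pixel_size_um > 0,
            p$particle_density_per_um2 >= 0,
            length(p$category_probs) == 7L, all(p$category_probs >= 0),
            p$psf_sigma_px > 0,
            length(p$unit_intensity_mu_sigma) == 2L,
            p$unit_intensity_mu_sigma[1] > 0,
            p$unit_intensity_mu_sigma[2] >= 0,
            length(p$illumination_gradient) == 2L,
            all(p$illumination_gradient > 0))
  if (abs(sum(p$category_probs) - 1) > 1e-9)
    stop("category_probs must sum to 1 (within 1e-9)")
  if (p$background_offset_adu < 0 || p$read_noise_sd_adu < 0)
    stop("noise parameters must be non-negative")
  for (m in c("COE", "CFSE")) {
    mm <- p$marker_intensity_model[[m]]
    stopifnot(mm$median_adu > 0, mm$gsd >= 1)
  }
  cm <- p$cd63_copy_model
  if (cm$type == "poisson") stopifnot(cm$lambda > 0)
  else if (cm$type == "weights") stopifnot(all(cm$weights >= 0),
                                           sum(cm$weights) > 0)
  else stop("unknown cd63_copy_model type: ", cm$type)
  invisible(p)
}

#' Construct a multi-channel field of view
#'
#' @param channels Named list of numeric matrices (identical dimensions),
#'   one per fluorescence channel, values in ADU.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param field_id Identifier for the field of view.
#' @return A `field_image` object.
#' @export
field_image <- function(channels, pixel_size_um, field_id = "field") {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), pixel_size_um > 0)
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all channels must share identical dimensions")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("channel intensities must be non-negative")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 field_id = field_id),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image '%s'> %d x %d px (%.3g x %.3g um), channels: %s\n",
              x$field_id, d[1], d[2], d[1] * x$pixel_size_um,
              d[2] * x$pixel_size_um, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Linear left-to-right gain ramp as a matrix.
gain_field <- function(field_size_px, gradient) {
  nr <- field_size_px[1]; nc <- field_size_px[2]
  matrix(seq(gradient[1], gradient[2], length.out = nc),
         nr, nc, byrow = TRUE)
}

# Draw per-particle marker intensities and CD63 copy numbers through a latent
# Gaussian copula, zeroing channels the category declares absent.
draw_particle_content <- function(n, cat_idx, params) {
  pos <- subpop_positivity()[cat_idx, , drop = FALSE]
  rho <- params$marker_correlation
  R <- matrix(c(1, rho$coe_cfse, rho$coe_cd63,
                rho$coe_cfse, 1, rho$cfse_cd63,
                rho$coe_cd63, rho$cfse_cd63, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) stop("marker_correlation matrix is not positive definite")
  z <- matrix(rnorm(3L * n), n, 3L) %*% chol(R)
  u <- pnorm(z)

  mm <- params$marker_intensity_model
  coe <- ifelse(pos[, "COE"],
                qlnorm(u[, 1], log(mm$COE$median_adu), log(mm$COE$gsd)), 0)
  cfse <- ifelse(pos[, "CFSE"],
                 qlnorm(u[, 2], log(mm$CFSE$median_adu), log(mm$CFSE$gsd)), 0)

  copies <- integer(n)
  cpos <- pos[, "CD63"]
  if (any(cpos)) {
    cm <- params$cd63_copy_model
    if (cm$type == "poisson") {
      # zero-truncated Poisson via the copula quantile
      p0 <- ppois(0, cm$lambda)
      copies[cpos] <- qpois(p0 + u[cpos, 3] * (1 - p0), cm$lambda)
    } else {
      w <- cm$weights / sum(cm$weights)
      cw <- cumsum(w)
      copies[cpos] <- findInterval(u[cpos, 3], cw, left.open = TRUE) + 1L
    }
  }
  mu1 <- params$unit_intensity_mu_sigma[1]
  s1 <- params$unit_intensity_mu_sigma[2]
  cd63 <- numeric(n)
  tot <- sum(copies)
  if (tot > 0) {
    draws <- rtruncnorm0(tot, mu1, s1)
    idx <- rep.int(seq_len(n), copies)
    sums <- rowsum(draws, idx)          # one row per particle with copies > 0
    cd63[as.integer(rownames(sums))] <- as.numeric(sums)
  }
  data.frame(intensity_COE = coe, intensity_CFSE = cfse,
             intensity_CD63 = cd63, cd63_copies = copies)
}

# Render noiseless per-channel signal, then apply gain, shot noise and read
# noise: ADU = gain * Poisson(signal + offset) + N(0, read_sd^2), clamped >= 0.
render_channels <- function(truth, params, channel_names) {
  nr <- params$field_size_px[1]; nc <- params$field_size_px[2]
  g <- gain_field(params$field_size_px, params$illumination_gradient)
  out <- list()
  for (ch in channel_names) {
    sig <- matrix(0, nr, nc)
    ints <- truth[[paste0("intensity_", ch)]]
    keep <- which(ints > 0)
    for (i in keep) {
      p <- gaussian_patch(truth$x_px[i], truth$y_px[i], params$psf_sigma_px,
                          ints[i], nr, nc)
      sig <- add_patch(sig, p)
    }
    photons <- matrix(rpois(nr * nc, sig + params$background_offset_adu),
                      nr, nc)
    adu <- g * photons
    if (params$read_noise_sd_adu > 0)
      adu <- adu + matrix(rnorm(nr * nc, 0, params$read_noise_sd_adu), nr, nc)
    out[[ch]] <- pmax(adu, 0)
  }
  out
}

#' Generate a ground-truthed synthetic three-channel TIRF field
#'
#' Particle count is Poisson in the field area; sub-pixel positions are
#' uniform; each particle is assigned one of the seven subpopulations and
#' rendered in each of its positive channels as a 2-D Gaussian whose integral
#' equals the particle's true intensity. The CD63 channel intensity is the sum
#' of per-antibody emissions (truncated-normal draws), so molecule-counting
#' stages can be validated against exact copy numbers.
#'
#' @param params A [scene_params()] object.
#' @param field_id Identifier stored in the returned field.
#' @return List with `field` (a [field_image()]) and `truth` (data.frame with
#'   one row per particle: position, category, true per-channel intensities,
#'   CD63 copy count, and an `edge` flag for particles within one PSF sigma
#'   of the border).
#' @export
generate_scene <- function(params, field_id = "scene") {
  validate_scene_params(params)
  nr <- params$field_size_px[1]; nc <- params$field_size_px[2]
  rho_px <- params$particle_density_per_um2 * params$pixel_size_um^2
  if (rho_px > 0 && 0.5 / sqrt(rho_px) < 2 * params$psf_sigma_px)
    warning("particle density so high that expected spacing < 2 PSF sigma; ",
            "spots will overlap heavily")

  with_seed(params$seed, {
    area_um2 <- nr * nc * params$pixel_size_um^2
    n <- rpois(1L, params$particle_density_per_um2 * area_um2)
    if (n > 0) {
      x <- runif(n, 0, nc - 1)
      y <- runif(n, 0, nr - 1)
      cat_idx <- sample.int(7L, n, replace = TRUE,
                            prob = params$category_probs)
      content <- draw_particle_content(n, cat_idx, params)
      s <- params$psf_sigma_px
      truth <- data.frame(
        x_px = x, y_px = y,
        category = subpop_labels()[cat_idx],
        content,
        edge = x < s | x > nc - 1 - s | y < s | y > nr - 1 - s,
        stringsAsFactors = FALSE)
    } else {
      truth <- data.frame(x_px = numeric(0), y_px = numeric(0),
                          category = character(0),
                          intensity_COE = numeric(0),
                          intensity_CFSE = numeric(0),
                          intensity_CD63 = numeric(0),
                          cd63_copies = integer(0), edge = logical(0))
    }
    channels <- render_channels(truth, params, c("COE", "CFSE", "CD63"))
    field <- field_image(channels, params$pixel_size_um, field_id)
    attr(truth, "params") <- params
    list(field = field, truth = truth)
  })
}

#' Generate a single-antibody calibration field
#'
#' Emulates imaging surface-immobilized fluorophore-labelled antibodies in the
#' absence of particles: one channel of isolated spots whose true integrated
#' intensities are single draws from the unit-fluorophore distribution
#' N(mu1, sigma1^2) truncated at zero.
#'
#' @param unit_mu_adu,unit_sigma_adu Unit-fluorophore intensity mean and SD.
#' @param density_per_um2 Spot density; must be sparse enough that spots are
#'   isolated (expected nearest-neighbour distance > 6 PSF sigma).
#' @param field_size_px,pixel_size_um,psf_sigma_px,background_offset_adu,read_noise_sd_adu,illumination_gradient
#'   As in [scene_params()].
#' @param seed Integer seed.
#' @return List with `field` (single channel `"CAL"`) and `truth`.
#' @export
generate_calibration_field <- function(unit_mu_adu, unit_sigma_adu,
                                       density_per_um2 = 0.01,
                                       field_size_px = c(400L, 400L),
                                       pixel_size_um = 0.25,
                                       psf_sigma_px = 1.0,
                                       background_offset_adu = 100,
                                       read_noise_sd_adu = 3,
                                       illumination_gradient = c(1, 1),
                                       seed = 1L) {
  stopifnot(unit_mu_adu > 0, unit_sigma_adu >= 0, density_per_um2 >= 0,
            background_offset_adu >= 0, read_noise_sd_adu >= 0)
  rho_px <- density_per_um2 * pixel_size_um^2
  if (rho_px > 0 && 0.5 / sqrt(rho_px) <= 6 * psf_sigma_px)
    stop("calibration density too high: expected nearest-neighbour distance ",
         "must exceed 6 PSF sigma")
  params <- list(field_size_px = as.integer(field_size_px),
                 pixel_size_um = pixel_size_um,
                 psf_sigma_px = psf_sigma_px,
                 background_offset_adu = background_offset_adu,
                 read_noise_sd_adu = read_noise_sd_adu,
                 illumination_gradient = illumination_gradient,
                 unit_intensity_mu_sigma = c(unit_mu_adu, unit_sigma_adu),
                 seed = as.integer(seed))
  nr <- params$field_size_px[1]; nc <- params$field_size_px[2]
  with_seed(seed, {
    area_um2 <- nr * nc * pixel_size_um^2
    n <- rpois(1L, density_per_um2 * area_um2)
    x <- runif(n, 0, nc - 1)
    y <- runif(n, 0, nr - 1)
    ints <- rtruncnorm0(n, unit_mu_adu, unit_sigma_adu)
    s <- psf_sigma_px
    truth <- data.frame(x_px = x, y_px = y, intensity_CAL = ints,
                        edge = x < s | x > nc - 1 - s | y < s | y > nr - 1 - s)
    p2 <- params
    p2$field_size_px <- c(nr, nc)
    channels <- render_channels(
      data.frame(x_px = x, y_px = y, intensity_CAL = ints),
      p2, "CAL")
    field <- field_image(channels, pixel_size_um, "calibration")
    attr(truth, "params") <- params
    list(field = field, truth = truth)
  })
}

#' Convert scene ground truth into a particle table
#'
#' Bypasses imaging entirely: builds the particle records the colocalization
#' stage would produce under perfect detection, using the generator's true
#' categories and intensities. Used to validate population statistics
#' (e.g. Venn fractions) against pure sampling variability.
#'
#' @param truth Truth data.frame from [generate_scene()].
#' @param field_id Field/ROI identifier to attach.
#' @return A particle data.frame compatible with [venn_fractions()].
#' @export
particles_from_truth <- function(truth, field_id = "truth") {
  pos <- subpop_positivity()[match(truth$category, subpop_labels()), ,
                             drop = FALSE]
  data.frame(field_id = field_id,
             x_px = truth$x_px, y_px = truth$y_px,
             pos_COE = pos[, "COE"], pos_CFSE = pos[, "CFSE"],
             pos_CD63 = pos[, "CD63"],
             intensity_COE = truth$intensity_COE,
             intensity_CFSE = truth$intensity_CFSE,
             intensity_CD63 = truth$intensity_CD63,
             label = truth$category,
             flag_edge = truth$edge,
             flag_aggregate = FALSE,
             flag_string = FALSE,
             stringsAsFactors = FALSE)
}
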