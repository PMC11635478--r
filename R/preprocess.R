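# Illumination flattening and diffuse-background removal ---------------------

#' Preprocessing parameters
#'
#' Defaults follow the standard single-particle TIRF workflow at a 0.25 um/px
#' scale: a 30 px (7.5 um) Gaussian blur for the flat-field gain estimate and
#' a 50 px (12.5 um) rolling-ball radius for diffuse background.
#'
#' @param blur_radius_px Gaussian blur radius (sigma, px) used to estimate the
#'   illumination profile.
#' @param ball_radius_px Rolling-ball radius (px) for background subtraction.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(blur_radius_px = 30, ball_radius_px = 50) {
  stopifnot(blur_radius_px >= 1, ball_radius_px >= 1)
  structure(list(blur_radius_px = blur_radius_px,
                 ball_radius_px = ball_radius_px),
            class = "preprocess_params")
}

#' Flat-field (illumination) correction
#'
#' Estimates the smooth multiplicative illumination profile as a wide Gaussian
#' blur of the image and divides it out, normalized so the overall image mean
#' is preserved: `out = image / (blur(image) / mean(blur(image)))`. Division
#' (rather than subtraction) is used because uneven excitation acts
#' multiplicatively on emitted intensity, and spot intensities must remain
#' comparable across the field for downstream molecule counting.
#'
#' @param image Numeric matrix, non-negative ADU.
#' @param blur_radius_px Gaussian sigma of the illumination estimate (px).
#' @return Corrected matrix of the same dimensions, non-negative.
#' @export
flat_field_correct <- function(image, blur_radius_px = 30) {
  stopifnot(is.matrix(image), length(image) > 0, blur_radius_px >= 1)
  # suppress diffraction-limited spots before estimating the gain profile,
  # so bright particles do not dent the illumination estimate; a small
  # grey-scale opening removes features a few pixels across
  base <- if (min(dim(image)) > 9) flat_opening(image, 3L) else image
  ks <- 2L * ceiling(2 * blur_radius_px) + 1L
  ks <- min(ks, min(dim(image)) - 1L + min(dim(image)) %% 2L)
  if (ks %% 2L == 0L) ks <- ks - 1L
  g <- seq_len(ks) - (ks + 1L) / 2
  k1 <- exp(-g^2 / (2 * blur_radius_px^2))
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  blurred <- as.matrix(EBImage::filter2(EBImage::Image(base), k2,
                                        boundary = "replicate"))
  m <- mean(blurred)
  gain <- blurred / m
  bad <- gain <= 1e-6
  if (any(bad)) {
    warning(sum(bad), " pixels with near-zero illumination estimate clamped")
    gain[bad] <- 1e-6
  }
  pmax(image / gain, 0)
}

# Flat-disc grey-scale opening on raw intensity values (EBImage's grey-scale
# morphology assumes the [0, 1] range, so this works directly on ADU).
flat_opening <- function(m, radius = 3L) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  pad_run <- function(x, dilate) {
    acc <- x
    for (i in seq_len(nrow(offs))) {
      cand <- shift_matrix(x, offs$dr[i], offs$dc[i],
                           if (dilate) -Inf else Inf)
      acc <- if (dilate) pmax(acc, cand) else pmin(acc, cand)
    }
    acc
  }
  pad_run(pad_run(m, dilate = FALSE), dilate = TRUE)
}

# Paraboloid grey-scale erosion/dilation by separable sliding-parabola
# inf/sup-convolution, truncated at lateral radius r. The structuring element
# height drop at lateral offset u is u^2/(2r) (intensity and pixel units
# identified), i.e. the apex curvature of a ball of radius r.
paraboloid_transform <- function(image, radius, dilate = FALSE) {
  r <- as.integer(ceiling(radius))
  fill <- if (dilate) -Inf else Inf
  # sliding-parabola envelope along matrix rows, with replicated edges so the
  # envelope does not undercut rising backgrounds at the border
  pass <- function(m) {
    nc0 <- ncol(m)
    mp <- cbind(matrix(m[, 1], nrow(m), r), m,
                matrix(m[, nc0], nrow(m), r))
    acc <- mp
    for (k in seq_len(r)) {
      pen <- k^2 / (2 * radius)
      for (s in c(-k, k)) {
        cand <- shift_matrix(mp, 0L, s, fill)
        acc <- if (dilate) pmax(acc, cand - pen) else pmin(acc, cand + pen)
      }
    }
    acc[, (r + 1):(r + nc0), drop = FALSE]
  }
  out <- pass(image)       # horizontal pass
  t(pass(t(out)))          # vertical pass
}

#' Rolling-ball background subtraction
#'
#' Estimates the diffuse background as a grey-scale morphological opening of
#' the intensity surface by a paraboloid of the given radius (the classic
#' rolling-ball formulation; the paraboloid matches the apex curvature of a
#' ball of radius `ball_radius_px` and is computed exactly by separable
#' sliding-parabola envelopes). Features narrower than the ball — the
#' diffraction-limited spots — are left intact while smooth background is
#' removed. Output is clamped at zero.
#'
#' @param image Numeric matrix, non-negative.
#' @param ball_radius_px Ball radius in pixels; must be smaller than the
#'   smallest image dimension.
#' @return Background-subtracted matrix, same dimensions, non-negative.
#' @export
rolling_ball_subtract <- function(image, ball_radius_px = 50) {
  stopifnot(is.matrix(image), all(image >= 0))
  if (ball_radius_px >= min(dim(image)))
    stop("ball radius must be smaller than the image")
  er <- paraboloid_transform(image, ball_radius_px, dilate = FALSE)
  bg <- paraboloid_transform(er, ball_radius_px, dilate = TRUE)
  pmax(image - bg, 0)
}

#' Preprocess every channel of a field
#'
#' Applies flat-field correction then rolling-ball background subtraction to
#' each channel independently (no cross-channel normalization). This order
#' matters: the gain profile must be divided out while the diffuse background
#' still carries it, otherwise spot intensities near the dim edge of the
#' field are biased.
#'
#' @param field A [field_image()].
#' @param params A [preprocess_params()].
#' @return A new `field_image` with corrected channels.
#' @export
preprocess_field <- function(field, params = preprocess_params()) {
  stopifnot(inherits(field, "field_image"))
  chans <- lapply(field$channels, function(ch) {
    rolling_ball_subtract(flat_field_correct(ch, params$blur_radius_px),
                          params$ball_radius_px)
  })
  field_image(chans, field$pixel_size_um, field$field_id)
}
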