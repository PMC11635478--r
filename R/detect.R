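# Diffraction-limited spot detection -----------------------------------------

#' Spot-detection parameters
#'
#' @param kernel_size_px Band-pass kernel size (px); a diffraction-limited
#'   spot at the default pixel scale is about 2 px across.
#' @param k_sd Threshold multiplier applied to the SD of the band-filtered
#'   image; conventional operating range 3--4.
#' @param min_area_px Minimum connected above-threshold area for a candidate.
#' @param edge_margin_px Spots whose centroid falls within this margin of the
#'   border are flagged `edge` and excluded from statistics.
#' @param aggregate_area_px,aggregate_circularity,aggregate_intensity_quantile
#'   Joint criteria for flagging large, bright, circular aggregates.
#' @param robust_sd Use a robust (MAD-based) SD of the filtered image as the
#'   threshold scale (default). The filtered image of a field carrying bright
#'   particles has a plain SD inflated far above the noise floor, which would
#'   silently discard the dim end of the particle population; the MAD tracks
#'   the noise. Set to `FALSE` for the plain standard deviation.
#' @return A `detection_params` list.
#' @export
detection_params <- function(kernel_size_px = 2, k_sd = 3.5, min_area_px = 3L,
                             edge_margin_px = 4L, aggregate_area_px = 50L,
                             aggregate_circularity = 0.8,
                             aggregate_intensity_quantile = 0.999,
                             robust_sd = TRUE) {
  stopifnot(kernel_size_px >= 1, min_area_px >= 1, edge_margin_px >= 0)
  if (k_sd < 3 || k_sd > 4)
    warning("k_sd = ", k_sd, " is outside the conventional 3-4 range")
  structure(list(kernel_size_px = kernel_size_px, k_sd = k_sd,
                 min_area_px = as.integer(min_area_px),
                 edge_margin_px = as.integer(edge_margin_px),
                 aggregate_area_px = as.integer(aggregate_area_px),
                 aggregate_circularity = aggregate_circularity,
                 aggregate_intensity_quantile = aggregate_intensity_quantile,
                 robust_sd = robust_sd),
            class = "detection_params")
}

# Laplacian-of-Gaussian (Mexican-hat) kernel, negated so bright spots give
# positive maxima, and adjusted to sum exactly to zero.
log_kernel <- function(sigma) {
  h <- max(3L, ceiling(4 * sigma))
  g <- seq(-h, h)
  xx <- outer(rep(1, length(g)), g)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)
  k / sum(k[k > 0])
}

#' Band-pass filter an image for spot detection
#'
#' Convolves with a Gaussian-smoothed Mexican-hat (Laplacian-of-Gaussian)
#' kernel of scale `kernel_size_px / 2`, producing a zero-mean response in
#' which an isolated diffraction-limited spot appears as a positive local
#' maximum at its centre.
#'
#' @param image Numeric matrix (preprocessed channel).
#' @param kernel_size_px Kernel size in pixels (default 2; the LoG sigma is
#'   half this).
#' @return Filtered matrix, same dimensions.
#' @export
band_filter <- function(image, kernel_size_px = 2) {
  stopifnot(is.matrix(image), kernel_size_px >= 1)
  sigma <- kernel_size_px / 2
  k <- log_kernel(sigma)
  if (any(dim(k) > dim(image))) stop("kernel larger than image")
  as.matrix(EBImage::filter2(EBImage::Image(image), k,
                             boundary = "replicate"))
}

filtered_sd <- function(filtered, robust = FALSE) {
  if (robust) mad(filtered) else sd(as.numeric(filtered))
}

# Normalized autocorrelation of the band-pass kernel.
kernel_autocorr <- function(sigma) {
  k <- log_kernel(sigma)
  n <- nrow(k)
  C <- matrix(0, 2 * n - 1, 2 * n - 1)
  for (dr in -(n - 1):(n - 1)) for (dc in -(n - 1):(n - 1)) {
    r1 <- max(1, 1 - dr):min(n, n - dr)
    c1 <- max(1, 1 - dc):min(n, n - dc)
    C[dr + n, dc + n] <- sum(k[r1, c1] * k[r1 + dr, c1 + dc])
  }
  C / C[n, n]
}

.noise_factor_cache <- new.env(parent = emptyenv())

# Variance multiplier S(A) such that the sum of band-filtered noise over a
# roughly disc-shaped footprint of A pixels has variance sigma_f^2 * S(A).
# Band-pass filtering correlates neighbouring pixels, so S(A) != A; it is
# computed exactly from the kernel autocorrelation on discs and
# interpolated in area.
footprint_noise_var_mult <- function(area, sigma) {
  key <- sprintf("s%g", sigma)
  tab <- .noise_factor_cache[[key]]
  if (is.null(tab)) {
    rho <- kernel_autocorr(sigma)
    n <- (nrow(rho) + 1) / 2
    areas <- integer(0); S <- numeric(0)
    for (r in seq(0.5, 10, by = 0.25)) {
      w <- ceiling(r)
      g <- seq(-w, w)
      D <- outer(g, g, function(a, b) a^2 + b^2 <= r^2)
      A <- sum(D)
      if (A %in% areas) next
      idx <- which(D, arr.ind = TRUE)
      dr <- outer(idx[, 1], idx[, 1], "-")
      dc <- outer(idx[, 2], idx[, 2], "-")
      keep <- abs(dr) < n & abs(dc) < n
      areas <- c(areas, A)
      S <- c(S, sum(rho[cbind(dr[keep] + n, dc[keep] + n)]))
    }
    tab <- list(areas = areas, S = pmax(S, 1))
    .noise_factor_cache[[key]] <- tab
  }
  out <- approx(tab$areas, tab$S, xout = pmin(area, max(tab$areas)),
                rule = 2)$y
  # beyond the tabulated discs, scale proportionally with area
  big <- area > max(tab$areas)
  if (any(big))
    out[big] <- tab$S[length(tab$S)] * area[big] / max(tab$areas)
  pmax(out, 1)
}

# Measure all labelled spots on the raw (preprocessed) image.
#
# Photometry uses a measurement aperture: the above-threshold footprint
# dilated by 2 px (capturing PSF tails the threshold cuts off), partitioned
# between nearby spots by intensity-guided propagation so overlapping
# apertures never double-count. The local background is the median of a
# 2-px-wide ring starting 2 px outside the footprint, likewise partitioned.
measure_spots <- function(lab, raw, filtered, params, channel = "composite",
                          field_id = "field") {
  nr <- nrow(raw); nc <- ncol(raw)
  nlab <- max(lab)
  empty <- spot_table(0)
  if (nlab == 0) return(structure(empty, labels = lab))

  mask <- lab > 0L
  inner <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1),
                                     EBImage::makeBrush(5L, "disc"))) > 0
  outer_m <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1),
                                       EBImage::makeBrush(9L, "disc"))) > 0
  # nearest-spot partition of the dilated neighbourhood
  palab <- as.matrix(EBImage::imageData(EBImage::propagate(
    EBImage::Image(raw), EBImage::Image(lab), mask = EBImage::Image(outer_m * 1),
    lambda = 1e10)))
  storage.mode(palab) <- "integer"

  g <- lab[mask]
  idx <- which(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  w <- raw[mask]
  area <- as.integer(tabulate(g, nlab))
  wsum <- sum_by(w, g, nlab)
  # intensity-weighted centroid, 0-based (x = col - 1, y = row - 1)
  cx <- sum_by(w * (cols - 1), g, nlab) / wsum
  cy <- sum_by(w * (rows - 1), g, nlab) / wsum
  # fall back to unweighted centroid if weights degenerate
  bad <- !is.finite(cx) | !is.finite(cy)
  if (any(bad)) {
    ux <- sum_by(cols - 1, g, nlab) / area
    uy <- sum_by(rows - 1, g, nlab) / area
    cx[bad] <- ux[bad]; cy[bad] <- uy[bad]
  }

  ap_mask <- inner & palab > 0L
  ga <- palab[ap_mask]
  ap_area <- as.integer(tabulate(ga, nlab))
  ap_sum <- sum_by(raw[ap_mask], ga, nlab)

  ring_mask <- outer_m & !inner & palab > 0L
  bg <- numeric(nlab)
  if (any(ring_mask)) {
    fr <- palab[ring_mask]
    bg_list <- split(raw[ring_mask], factor(fr, levels = seq_len(nlab)))
    bg <- vapply(bg_list, function(v) if (length(v)) median(v) else 0,
                 numeric(1))
  }
  intensity <- pmax(ap_sum - bg * ap_area, 0)

  shp <- EBImage::computeFeatures.shape(EBImage::Image(lab))
  circ <- rep(NA_real_, nlab)
  if (!is.null(shp) && nrow(shp) == nlab) {
    per <- pmax(shp[, "s.perimeter"], 1)
    circ <- pmin(4 * pi * shp[, "s.area"] / per^2, 1)
  }

  m <- params$edge_margin_px
  spots <- data.frame(
    field_id = field_id, channel = channel,
    spot_id = seq_len(nlab),
    x_px = cx, y_px = cy, area_px = area,
    intensity_adu = intensity, background_adu = bg,
    circularity = circ,
    flag_edge = cx < m | cx > nc - 1 - m | cy < m | cy > nr - 1 - m,
    flag_string = FALSE, flag_aggregate = FALSE,
    stringsAsFactors = FALSE)
  structure(spots, labels = lab)
}

spot_table <- function(n) {
  data.frame(field_id = character(n), channel = character(n),
             spot_id = integer(n), x_px = numeric(n), y_px = numeric(n),
             area_px = integer(n), intensity_adu = numeric(n),
             background_adu = numeric(n), circularity = numeric(n),
             flag_edge = logical(n), flag_string = logical(n),
             flag_aggregate = logical(n), stringsAsFactors = FALSE)
}

#' Detect diffraction-limited spots
#'
#' Thresholds the band-filtered image at `k_sd` times its standard deviation;
#' connected above-threshold regions of at least `min_area_px` pixels become
#' spots. Centroids are intensity-weighted on the raw (preprocessed) image;
#' integrated intensities are local-background-corrected aperture sums (see
#' Details in [measure_spots] internals). Spots near the border are flagged
#' `edge`.
#'
#' @param filtered Band-filtered image from [band_filter()].
#' @param raw The preprocessed (but unfiltered) image used for photometry.
#' @param params A [detection_params()].
#' @param channel,field_id Labels stored in the output table.
#' @return A spot data.frame with the label matrix attached as attribute
#'   `"labels"` and the detection threshold as attribute `"threshold"`.
#' @export
detect_spots <- function(filtered, raw, params = detection_params(),
                         channel = "composite", field_id = "field") {
  stopifnot(all(dim(filtered) == dim(raw)))
  if (length(filtered) == 0) stop("empty image")
  sdf <- filtered_sd(filtered, params$robust_sd)
  if (sdf == 0) {
    message("constant filtered image (SD = 0): no spots detected")
    return(structure(spot_table(0),
                     labels = matrix(0L, nrow(raw), ncol(raw)),
                     threshold = Inf))
  }
  thr <- params$k_sd * sdf
  mask <- filtered > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  # drop small regions, relabel densely
  if (max(lab) > 0) {
    area <- tabulate(lab[lab > 0L], max(lab))
    keep <- which(area >= params$min_area_px)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  spots <- measure_spots(lab, raw, filtered, params, channel, field_id)
  attr(spots, "threshold") <- thr
  attr(spots, "filtered_sd") <- sdf
  spots
}

# Local maxima of `filtered` above `thr` inside `mask`, as (row, col) pairs.
local_maxima <- function(filtered, mask, thr) {
  nr <- nrow(filtered); nc <- ncol(filtered)
  is_max <- mask & filtered > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & filtered >= shift_matrix(filtered, dr, dc, -Inf)
  }
  which(is_max, arr.ind = TRUE)
}

#' Split strings of merged particles
#'
#' Above-threshold regions occasionally cover a short string of adjacent
#' particles. Regions containing two or more local maxima of the filtered
#' image (each above the detection threshold, pairwise at least 2 px apart)
#' are split along intensity watershed lines between the maxima; the children
#' are flagged `string_segmented`. Regions with a single maximum pass through
#' untouched, and the total integrated intensity is conserved across a split.
#'
#' @param spots Output of [detect_spots()] (label matrix attached).
#' @param filtered,raw The images used for detection and photometry.
#' @param params A [detection_params()].
#' @return Updated spot table with attribute `"labels"` rebuilt.
#' @export
segment_strings <- function(spots, filtered, raw, params = detection_params()) {
  lab <- attr(spots, "labels")
  thr <- attr(spots, "threshold")
  if (is.null(lab) || nrow(spots) == 0) return(spots)
  nlab <- max(lab)
  maxima <- local_maxima(filtered, lab > 0L, thr)
  if (nrow(maxima) == 0) return(spots)
  mlab <- lab[maxima]
  seeds_by_region <- split(seq_len(nrow(maxima)), mlab)

  seed_mat <- matrix(0L, nrow(lab), ncol(lab))
  next_id <- 1L
  split_parents <- integer(0)
  for (rg in names(seeds_by_region)) {
    ids <- seeds_by_region[[rg]]
    pts <- maxima[ids, , drop = FALSE]
    o <- order(filtered[pts], decreasing = TRUE)
    pts <- pts[o, , drop = FALSE]
    # enforce >= 2 px separation between retained maxima
    kept <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      if (nrow(kept) == 0 ||
          min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= 4)
        kept <- rbind(kept, p)
    }
    if (nrow(kept) >= 2) split_parents <- c(split_parents, as.integer(rg))
    for (i in seq_len(nrow(kept))) {
      seed_mat[kept[i, 1], kept[i, 2]] <- next_id
      next_id <- next_id + 1L
    }
  }
  if (length(split_parents) == 0) return(spots)

  # rebuild labels: unsplit regions keep one label; split regions are
  # partitioned among their seeds by intensity-guided growth
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  keep_mask <- lab > 0L & !(lab %in% split_parents)
  new_lab[keep_mask] <- lab[keep_mask]
  split_mask <- lab > 0L & (lab %in% split_parents)
  seed_img <- seed_mat
  seed_img[!split_mask] <- 0L
  grown <- as.matrix(EBImage::imageData(EBImage::propagate(
    EBImage::Image(filtered - min(filtered)), EBImage::Image(seed_img),
    mask = EBImage::Image(split_mask * 1))))
  storage.mode(grown) <- "integer"
  offset <- max(lab)
  new_lab[split_mask] <- grown[split_mask] + offset
  # densify labels
  u <- sort(unique(new_lab[new_lab > 0L]))
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  child_ids <- remap[offset + sort(unique(grown[split_mask]))]
  new_lab[new_lab > 0L] <- remap[new_lab[new_lab > 0L]]

  out <- measure_spots(new_lab, raw, filtered, params,
                       channel = spots$channel[1],
                       field_id = spots$field_id[1])
  out$flag_string[out$spot_id %in% child_ids] <- TRUE
  attr(out, "threshold") <- thr
  attr(out, "filtered_sd") <- attr(spots, "filtered_sd")
  out
}

#' Flag large bright spherical aggregates
#'
#' Occasional large, bright and circular particle aggregates are excluded
#' from population statistics. A spot is flagged when its area exceeds
#' `aggregate_area_px`, its circularity (4 pi A / P^2) exceeds
#' `aggregate_circularity`, and its integrated intensity exceeds the
#' `aggregate_intensity_quantile` of the ordinary (non-large) spot
#' population. The flagged fraction is attached as attribute
#' `"aggregate_fraction"` so it can be compared with the few-percent level
#' typical of real sEVP preparations.
#'
#' @param spots Spot table from [detect_spots()] / [segment_strings()].
#' @param params A [detection_params()].
#' @return Spot table with `flag_aggregate` set.
#' @export
flag_aggregates <- function(spots, params = detection_params()) {
  if (nrow(spots) == 0) {
    attr(spots, "aggregate_fraction") <- 0
    return(spots)
  }
  normal <- spots$area_px <= params$aggregate_area_px
  ref <- if (any(normal)) spots$intensity_adu[normal] else spots$intensity_adu
  iq <- quantile(ref, params$aggregate_intensity_quantile, names = FALSE)
  flag <- spots$area_px > params$aggregate_area_px &
    !is.na(spots$circularity) &
    spots$circularity > params$aggregate_circularity &
    spots$intensity_adu > iq
  spots$flag_aggregate <- flag
  attr(spots, "aggregate_fraction") <- mean(flag)
  spots
}

#' Evaluate detections against synthetic ground truth
#'
#' Greedy one-to-one matching of detections to true particle positions in
#' ascending distance order, within `match_dist_px`. Edge-flagged and
#' aggregate-flagged detections are excluded, as are true particles within
#' `edge_margin_px` of the border (the detector deliberately ignores the
#' margin).
#'
#' @param spots Detected spot (or particle) table with `x_px`, `y_px`.
#' @param truth Truth table from [generate_scene()].
#' @param dims Image dimensions c(rows, cols).
#' @param match_dist_px Maximum centroid distance for a match.
#' @param edge_margin_px Border margin excluded on both sides of the match.
#' @return List with precision, recall, localization RMSE (px), and the
#'   matched index pairs.
#' @export
detection_metrics <- function(spots, truth, dims, match_dist_px = 2,
                              edge_margin_px = 4) {
  m <- edge_margin_px
  nr <- dims[1]; nc <- dims[2]
  det_keep <- which(!spots$flag_edge & !spots$flag_aggregate)
  tr_keep <- which(truth$x_px >= m & truth$x_px <= nc - 1 - m &
                   truth$y_px >= m & truth$y_px <= nr - 1 - m)
  dx <- outer(spots$x_px[det_keep], truth$x_px[tr_keep], "-")
  dy <- outer(spots$y_px[det_keep], truth$y_px[tr_keep], "-")
  d <- sqrt(dx^2 + dy^2)
  pairs <- which(d <= match_dist_px, arr.ind = TRUE)
  if (length(pairs)) {
    ord <- order(d[pairs])
    pairs <- pairs[ord, , drop = FALSE]
    used_d <- logical(length(det_keep)); used_t <- logical(length(tr_keep))
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (!used_d[a] && !used_t[b]) {
        used_d[a] <- TRUE; used_t[b] <- TRUE; keep[i] <- TRUE
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  n_match <- nrow(pairs)
  rmse <- if (n_match) sqrt(mean(d[pairs]^2)) else NA_real_
  list(precision = if (length(det_keep)) n_match / length(det_keep) else NA,
       recall = if (length(tr_keep)) n_match / length(tr_keep) else NA,
       rmse_px = rmse,
       matches = data.frame(spot = det_keep[pairs[, 1]],
                            truth = tr_keep[pairs[, 2]],
                            dist_px = d[pairs]))
}
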