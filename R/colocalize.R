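# Multi-channel colocalization and subpopulation assignment ------------------

#' Assign a subpopulation label from marker positivity
#'
#' The vesicular/non-vesicular split is decided solely by the membrane probe:
#' COE-positive particles are vesicular sEVs, COE-negative ones are
#' non-vesicular NPs. CFSE and CD63 positivity select the sub-label. The
#' all-negative combination is not a particle and is rejected.
#'
#' @param coe,cfse,cd63 Logical positivity (vectorized).
#' @return Character vector of labels from [subpop_labels()].
#' @export
categorize <- function(coe, cfse, cd63) {
  n <- max(length(coe), length(cfse), length(cd63))
  coe <- rep_len(coe, n); cfse <- rep_len(cfse, n); cd63 <- rep_len(cd63, n)
  if (any(!coe & !cfse & !cd63))
    stop("all-negative particle: at least one marker must be positive")
  branch <- ifelse(coe, "sEV", "NP")
  paste0(branch, " CFSE", ifelse(cfse, "+", "-"),
         "CD63", ifelse(cd63, "+", "-"))
}

particle_table <- function(n) {
  data.frame(field_id = character(n), x_px = numeric(n), y_px = numeric(n),
             pos_COE = logical(n), pos_CFSE = logical(n),
             pos_CD63 = logical(n),
             intensity_COE = numeric(n), intensity_CFSE = numeric(n),
             intensity_CD63 = numeric(n),
             label = character(n), flag_edge = logical(n),
             flag_aggregate = logical(n), flag_string = logical(n),
             stringsAsFactors = FALSE)
}

#' Composite-image particle detection and colocalization
#'
#' The default colocalization mode: channels are merged into a composite
#' (pixel-wise maximum after scaling each channel by the SD of its own
#' band-filtered image), detection runs once on the composite, and each
#' detected footprint is then interrogated per channel. Channel c is called
#' positive when the band-filtered channel-c response summed over the
#' footprint strictly exceeds `k_sd * SD_c * sqrt(area)` (the noise scaling
#' of a sum over `area` pixels); a channel exactly at threshold is negative.
#' Per-channel intensities are aperture photometry on the preprocessed
#' channel images, zeroed for negative channels.
#'
#' @param field Preprocessed [field_image()] with channels named among
#'   COE, CFSE, CD63 (any subset, any order).
#' @param params A [detection_params()].
#' @param segment Split merged particle strings before measuring.
#' @return Particle data.frame; spot-level table and label matrix attached as
#'   attributes `"spots"` and `"labels"`.
#' @export
composite_detect <- function(field, params = detection_params(),
                             segment = TRUE) {
  stopifnot(inherits(field, "field_image"))
  chans <- field$channels
  labels <- names(chans)
  filt <- lapply(chans, band_filter, kernel_size_px = params$kernel_size_px)
  sds <- vapply(filt, filtered_sd, numeric(1), robust = params$robust_sd)
  if (any(sds == 0)) {
    message("channel(s) with zero filtered SD: ",
            paste(labels[sds == 0], collapse = ", "))
    sds[sds == 0] <- Inf
  }
  scaled <- Map(function(ch, s) ch / s, chans, sds)
  composite <- Reduce(pmax, scaled)
  raw_sum <- Reduce(`+`, chans)

  cfilt <- band_filter(composite, params$kernel_size_px)
  spots <- detect_spots(cfilt, raw_sum, params, channel = "composite",
                        field_id = field$field_id)
  if (segment) spots <- segment_strings(spots, cfilt, raw_sum, params)
  spots <- flag_aggregates(spots, params)
  lab <- attr(spots, "labels")
  n <- nrow(spots)
  if (n == 0) {
    out <- particle_table(0)
    attr(out, "spots") <- spots
    attr(out, "labels") <- lab
    return(out)
  }

  # per-channel positivity: filtered response integrated over the footprint
  gl <- lab[lab > 0L]
  pos <- matrix(FALSE, n, length(labels), dimnames = list(NULL, labels))
  ints <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  svar <- footprint_noise_var_mult(spots$area_px, params$kernel_size_px / 2)
  for (ch in labels) {
    fsum <- sum_by(filt[[ch]][lab > 0L], gl, n)
    thr_ch <- params$k_sd * sds[ch] * sqrt(svar)
    pos[, ch] <- fsum > thr_ch
    m <- measure_spots(lab, chans[[ch]], filt[[ch]], params,
                       channel = ch, field_id = field$field_id)
    ints[, ch] <- m$intensity_adu
  }
  ints[!pos] <- 0

  # particles with no positive channel are composite-threshold artefacts
  keep <- rowSums(pos) > 0
  spots_kept <- spots[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  ints <- ints[keep, , drop = FALSE]

  getcol <- function(m, ch, default) {
    if (ch %in% colnames(m)) m[, ch] else rep(default, nrow(m))
  }
  pc <- getcol(pos, "COE", FALSE); pf <- getcol(pos, "CFSE", FALSE)
  pd <- getcol(pos, "CD63", FALSE)
  lab_str <- if (all(c("COE", "CFSE", "CD63") %in% labels)) {
    categorize(pc, pf, pd)
  } else {
    # reduced-channel mode: label by the positive markers present
    apply(pos, 1, function(p) paste0(colnames(pos), ifelse(p, "+", "-"),
                                     collapse = " "))
  }
  out <- data.frame(
    field_id = field$field_id,
    x_px = spots_kept$x_px, y_px = spots_kept$y_px,
    pos_COE = pc, pos_CFSE = pf, pos_CD63 = pd,
    intensity_COE = getcol(ints, "COE", 0),
    intensity_CFSE = getcol(ints, "CFSE", 0),
    intensity_CD63 = getcol(ints, "CD63", 0),
    label = lab_str,
    flag_edge = spots_kept$flag_edge,
    flag_aggregate = spots_kept$flag_aggregate,
    flag_string = spots_kept$flag_string,
    stringsAsFactors = FALSE)
  attr(out, "spots") <- spots
  attr(out, "labels") <- lab
  attr(out, "aggregate_fraction") <- attr(spots, "aggregate_fraction")
  out
}

#' Match independently detected per-channel spots into particles
#'
#' Secondary colocalization mode mirroring classic two-channel spot matching:
#' spots detected separately in each channel are merged by greedy
#' nearest-neighbour matching (all candidate pairs considered in ascending
#' centre-distance order, each spot used at most once, distance at most
#' `max_dist_px`). Unmatched spots become single-channel particles.
#'
#' @param spots_by_channel Named list of spot tables from [detect_spots()],
#'   one per channel.
#' @param max_dist_px Maximum centre distance for two spots to be the same
#'   particle.
#' @param field_id Field identifier for the output.
#' @return Particle data.frame as in [composite_detect()].
#' @export
match_spots <- function(spots_by_channel, max_dist_px = 2,
                        field_id = "field") {
  labels <- names(spots_by_channel)
  stopifnot(!is.null(labels), all(nzchar(labels)))
  # one group per growing particle; start from the first channel
  parts <- list()
  for (ci in seq_along(labels)) {
    ch <- labels[ci]
    sp <- spots_by_channel[[ch]]
    if (nrow(sp) == 0) next
    if (length(parts) == 0) {
      parts <- lapply(seq_len(nrow(sp)), function(i) {
        p <- list(x = sp$x_px[i], y = sp$y_px[i],
                  flag_edge = sp$flag_edge[i],
                  flag_aggregate = sp$flag_aggregate[i],
                  flag_string = sp$flag_string[i],
                  intensity = setNames(numeric(length(labels)), labels),
                  pos = setNames(logical(length(labels)), labels))
        p$intensity[ch] <- sp$intensity_adu[i]
        p$pos[ch] <- TRUE
        p
      })
      next
    }
    px <- vapply(parts, `[[`, numeric(1), "x")
    py <- vapply(parts, `[[`, numeric(1), "y")
    d <- sqrt(outer(px, sp$x_px, "-")^2 + outer(py, sp$y_px, "-")^2)
    cand <- which(d <= max_dist_px, arr.ind = TRUE)
    used_p <- logical(length(parts)); used_s <- logical(nrow(sp))
    if (length(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        a <- cand[i, 1]; b <- cand[i, 2]
        if (used_p[a] || used_s[b]) next
        used_p[a] <- TRUE; used_s[b] <- TRUE
        parts[[a]]$intensity[ch] <- sp$intensity_adu[b]
        parts[[a]]$pos[ch] <- TRUE
        parts[[a]]$flag_edge <- parts[[a]]$flag_edge || sp$flag_edge[b]
        parts[[a]]$flag_aggregate <-
          parts[[a]]$flag_aggregate || sp$flag_aggregate[b]
        parts[[a]]$flag_string <- parts[[a]]$flag_string || sp$flag_string[b]
      }
    }
    for (b in which(!used_s)) {
      p <- list(x = sp$x_px[b], y = sp$y_px[b],
                flag_edge = sp$flag_edge[b],
                flag_aggregate = sp$flag_aggregate[b],
                flag_string = sp$flag_string[b],
                intensity = setNames(numeric(length(labels)), labels),
                pos = setNames(logical(length(labels)), labels))
      p$intensity[ch] <- sp$intensity_adu[b]
      p$pos[ch] <- TRUE
      parts[[length(parts) + 1L]] <- p
    }
  }
  if (length(parts) == 0) return(particle_table(0))
  np <- length(parts)
  posm <- vapply(c("COE", "CFSE", "CD63"), function(ch) {
    if (ch %in% labels) vapply(parts, function(p) p$pos[[ch]], logical(1))
    else rep(FALSE, np)
  }, logical(np))
  intm <- vapply(c("COE", "CFSE", "CD63"), function(ch) {
    if (ch %in% labels) vapply(parts, function(p) p$intensity[[ch]],
                               numeric(1))
    else rep(0, np)
  }, numeric(np))
  posm <- matrix(posm, nrow = np,
                 dimnames = list(NULL, c("COE", "CFSE", "CD63")))
  intm <- matrix(intm, nrow = np,
                 dimnames = list(NULL, c("COE", "CFSE", "CD63")))
  lab_str <- if (all(c("COE", "CFSE", "CD63") %in% labels)) {
    categorize(posm[, "COE"], posm[, "CFSE"], posm[, "CD63"])
  } else {
    apply(posm[, labels, drop = FALSE], 1, function(p)
      paste0(labels, ifelse(p, "+", "-"), collapse = " "))
  }
  data.frame(
    field_id = field_id,
    x_px = vapply(parts, `[[`, numeric(1), "x"),
    y_px = vapply(parts, `[[`, numeric(1), "y"),
    pos_COE = posm[, "COE"], pos_CFSE = posm[, "CFSE"],
    pos_CD63 = posm[, "CD63"],
    intensity_COE = intm[, "COE"], intensity_CFSE = intm[, "CFSE"],
    intensity_CD63 = intm[, "CD63"],
    label = lab_str,
    flag_edge = vapply(parts, `[[`, logical(1), "flag_edge"),
    flag_aggregate = vapply(parts, `[[`, logical(1), "flag_aggregate"),
    flag_string = vapply(parts, `[[`, logical(1), "flag_string"),
    stringsAsFactors = FALSE)
}

#' Subpopulation (Venn) fractions across regions of interest
#'
#' Pools particles over ROIs (fields) for the point estimates and reports the
#' between-ROI spread as the standard error: fraction_l = count_l / total
#' over all ROIs; SE_l = SD of the per-ROI fractions / sqrt(#ROIs).
#' Edge- and aggregate-flagged particles are excluded.
#'
#' @param particles Particle table with `field_id` and `label` columns.
#' @param labels Label universe; defaults to [subpop_labels()] when the
#'   particles carry three-channel labels, otherwise the observed labels.
#' @return data.frame with label, count, fraction, se.
#' @export
venn_fractions <- function(particles, labels = NULL) {
  keep <- !particles$flag_edge & !particles$flag_aggregate
  particles <- particles[keep, , drop = FALSE]
  if (nrow(particles) == 0) stop("no particles after flag exclusion")
  if (is.null(labels)) {
    labels <- if (all(particles$label %in% subpop_labels())) subpop_labels()
              else sort(unique(particles$label))
  }
  rois <- unique(particles$field_id)
  tab <- table(factor(particles$label, levels = labels))
  frac <- as.numeric(tab) / sum(tab)
  per_roi <- vapply(rois, function(r) {
    sub <- particles$label[particles$field_id == r]
    as.numeric(table(factor(sub, levels = labels))) / length(sub)
  }, numeric(length(labels)))
  per_roi <- matrix(per_roi, nrow = length(labels))
  se <- if (length(rois) > 1)
    apply(per_roi, 1, sd) / sqrt(length(rois)) else rep(NA_real_,
                                                        length(labels))
  out <- data.frame(label = labels, count = as.integer(tab),
                    fraction = frac, se = se, stringsAsFactors = FALSE)
  attr(out, "per_roi") <- per_roi
  attr(out, "n_roi") <- length(rois)
  out
}
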