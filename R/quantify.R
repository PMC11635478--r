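# Molecule counting and heterogeneity statistics -----------------------------

fd_breaks <- function(x) {
  bw <- 2 * IQR(x) / length(x)^(1 / 3)   # Freedman-Diaconis
  if (bw <= 0) bw <- diff(range(x)) / 30
  if (bw <= 0) return(NULL)
  seq(min(x) - bw / 2, max(x) + bw, by = bw)
}

#' Fit the single-fluorophore intensity distribution
#'
#' Builds an intensity histogram of isolated single-antibody spots
#' (Freedman-Diaconis bin width) and fits a Gaussian to the dominant mode;
#' the fitted peak position is the average single-fluorophore ("single-CD63")
#' signal used to convert particle intensities into molecule counts. The fit
#' window is restricted to 0.5-1.5 times the modal bin centre so that dimer
#' or aggregate contamination at twice the unit intensity does not bias the
#' peak.
#'
#' @param intensities Numeric vector of calibration spot intensities (ADU),
#'   at least 100.
#' @return A `calibration_model` list with `unit_mu_adu`, `unit_sigma_adu`,
#'   `n_calibration_spots` and `fit_quality` (R^2 of the histogram fit).
#' @export
fit_single_fluorophore <- function(intensities) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 100)
    stop("need at least 100 calibration spot intensities")
  if (diff(range(intensities)) == 0) {
    # degenerate: a delta distribution
    return(structure(list(unit_mu_adu = intensities[1], unit_sigma_adu = 0,
                          n_calibration_spots = length(intensities),
                          fit_quality = 1), class = "calibration_model"))
  }
  br <- fd_breaks(intensities)
  h <- hist(intensities, breaks = br, plot = FALSE)
  centers <- h$mids; counts <- h$counts
  peak <- centers[which.max(counts)]
  win <- centers >= 0.5 * peak & centers <= 1.5 * peak
  xc <- centers[win]; yc <- counts[win]
  if (length(xc) < 4) {
    # too few bins for a curve fit: fall back to windowed moments
    sel <- intensities >= 0.5 * peak & intensities <= 1.5 * peak
    mu <- mean(intensities[sel]); sg <- sd(intensities[sel])
    fit_q <- NA_real_
  } else {
    start <- list(A = max(yc), mu = peak,
                  sg = max(sd(intensities[intensities >= 0.5 * peak &
                                          intensities <= 1.5 * peak]),
                           diff(br)[1]))
    fit <- tryCatch(
      minpack.lm::nlsLM(yc ~ A * exp(-(xc - mu)^2 / (2 * sg^2)),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) stop("Gaussian fit did not converge")
    cf <- coef(fit)
    mu <- unname(cf["mu"]); sg <- abs(unname(cf["sg"]))
    resid <- yc - predict(fit)
    fit_q <- 1 - sum(resid^2) / sum((yc - mean(yc))^2)
  }
  if (!is.finite(mu) || mu <= 0) stop("fitted peak position is not positive")
  if (mu <= 2 * sg)
    stop("unreliable calibration: fitted peak (", round(mu, 1),
         ") not distinguishable from zero at 2 sigma (", round(sg, 1), ")")
  structure(list(unit_mu_adu = mu, unit_sigma_adu = sg,
                 n_calibration_spots = length(intensities),
                 fit_quality = fit_q),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model> unit intensity %.1f +/- %.1f ADU ",
                     "(n = %d spots, fit R^2 = %.3f)\n"),
              x$unit_mu_adu, x$unit_sigma_adu, x$n_calibration_spots,
              if (is.na(x$fit_quality)) NA else x$fit_quality))
  invisible(x)
}

#' Convert particle intensities to molecule counts by unit-intensity ratio
#'
#' Divides each particle's integrated marker intensity by the calibrated
#' single-fluorophore peak intensity. Counts are kept real-valued: the
#' count histogram is the intensity histogram with a rescaled abscissa, and
#' rounding would discard information.
#'
#' @param intensities Per-particle integrated intensities (ADU).
#' @param calibration A `calibration_model` from [fit_single_fluorophore()],
#'   or a positive scalar unit intensity.
#' @return List with `counts` (per particle), `mean_count`, and a `histogram`
#'   data.frame of (bin_mid, count) on the copy-number axis.
#' @export
counts_by_ratio <- function(intensities, calibration) {
  mu <- if (inherits(calibration, "calibration_model"))
    calibration$unit_mu_adu else calibration
  if (!is.finite(mu) || mu <= 0) stop("unit intensity must be positive")
  counts <- intensities / mu
  hg <- if (length(counts) > 1 && diff(range(counts)) > 0) {
    h <- hist(counts, breaks = "FD", plot = FALSE)
    data.frame(bin_mid = h$mids, count = h$counts)
  } else data.frame(bin_mid = numeric(0), count = integer(0))
  list(counts = counts, mean_count = mean(counts), histogram = hg)
}

#' Estimate the copy-number distribution by intensity-histogram deconvolution
#'
#' Models the measured intensity density as a mixture of n-fold convolutions
#' of the single-fluorophore Gaussian, sum_n w_n N(n mu1, n sigma1^2), and
#' estimates the weights by non-negative least squares on the binned
#' histogram with the sum-to-one constraint enforced (plus a small ridge
#' penalty for conditioning). Complements [counts_by_ratio()]: it resolves
#' the integer copy-number composition rather than only rescaling the axis.
#'
#' @param intensities At least 500 per-particle intensities (ADU).
#' @param calibration A `calibration_model` or list with `unit_mu_adu`,
#'   `unit_sigma_adu`.
#' @param n_max Largest copy number modelled.
#' @param bin_width Histogram bin width (ADU); default `unit_mu_adu / 4`.
#' @param ridge Ridge penalty on the weights.
#' @return A `copy_number_distribution` list: `weights` (over 1..n_max,
#'   summing to 1), `mean_count`, `n_max`.
#' @export
counts_by_deconvolution <- function(intensities, calibration, n_max = 100L,
                                    bin_width = NULL, ridge = 1e-6) {
  mu1 <- calibration$unit_mu_adu
  s1 <- calibration$unit_sigma_adu
  stopifnot(mu1 > 0, s1 >= 0)
  if (length(intensities) < 500)
    stop("need at least 500 intensities for deconvolution")
  if (s1 > mu1)
    warning("unit sigma exceeds unit mu: deconvolution is ill-conditioned ",
            "and results are unreliable")
  if (s1 == 0) s1 <- mu1 * 1e-3   # delta units: use narrow Gaussians
  if (is.null(bin_width)) bin_width <- mu1 / 4
  lo <- 0
  hi <- max(intensities) + 3 * s1 * sqrt(n_max)
  edges <- seq(lo, hi + bin_width, by = bin_width)
  counts <- hist(pmin(pmax(intensities, lo), hi), breaks = edges,
                 plot = FALSE)$counts
  dens <- counts / sum(counts)

  nn <- seq_len(n_max)
  A <- vapply(nn, function(n) {
    diff(pnorm(edges, mean = n * mu1, sd = sqrt(n) * s1))
  }, numeric(length(dens)))

  # sum-to-one as a heavily weighted extra row; ridge rows for conditioning
  gamma <- 10 * max(abs(A))
  Aaug <- rbind(A, rep(gamma, n_max), sqrt(ridge) * diag(n_max))
  baug <- c(dens, gamma, rep(0, n_max))
  w <- pracma::lsqnonneg(Aaug, baug)$x
  if (sum(w) <= 0) stop("deconvolution failed: all weights zero")
  w <- w / sum(w)
  structure(list(weights = w, mean_count = sum(nn * w), n_max = n_max,
                 bin_width = bin_width),
            class = "copy_number_distribution")
}

#' @export
print.copy_number_distribution <- function(x, ...) {
  top <- order(x$weights, decreasing = TRUE)[1:min(5, x$n_max)]
  cat(sprintf("<copy_number_distribution> mean count %.2f (n_max %d)\n",
              x$mean_count, x$n_max))
  cat("  top weights:",
      paste(sprintf("w[%d]=%.3f", top, x$weights[top]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pairwise marker-intensity correlation within a subpopulation
#'
#' Pearson correlation of two markers' integrated intensities over the
#' particles of one subpopulation that carry both markers, with the paired
#' table returned for scatter plotting. With `log = TRUE` the correlation is
#' computed on log intensities, which for the generator's log-normal
#' intensity model estimates the latent copula correlation directly.
#'
#' @param particles Particle table.
#' @param label Subpopulation label to restrict to (NULL for all).
#' @param markers Character pair from c("COE", "CFSE", "CD63").
#' @param log Correlate log intensities.
#' @param min_n Minimum number of double-positive particles required.
#' @return List with `r`, `n`, and the paired intensity data.frame `pairs`.
#' @export
pairwise_correlation <- function(particles, label = NULL,
                                 markers = c("CFSE", "COE"),
                                 log = FALSE, min_n = 30L) {
  stopifnot(length(markers) == 2L,
            all(markers %in% c("COE", "CFSE", "CD63")))
  keep <- !particles$flag_edge & !particles$flag_aggregate
  if (!is.null(label)) keep <- keep & particles$label == label
  keep <- keep & particles[[paste0("pos_", markers[1])]] &
    particles[[paste0("pos_", markers[2])]]
  x <- particles[[paste0("intensity_", markers[1])]][keep]
  y <- particles[[paste0("intensity_", markers[2])]][keep]
  if (length(x) < min_n)
    stop("only ", length(x), " double-positive particles; need >= ", min_n)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, n = length(x),
                pairs = data.frame(x = x, y = y),
                note = "constant intensities: correlation undefined"))
  if (log) { x <- base::log(x); y <- base::log(y) }
  pr <- data.frame(x = x, y = y)
  names(pr) <- markers
  list(r = cor(x, y), n = length(x), pairs = pr)
}

#' Relative size proxy from membrane-probe intensity
#'
#' The membrane probe's integrated intensity scales with membrane surface
#' area, i.e. with diameter squared, so the square root of the intensity is
#' a relative diameter.
#'
#' @param coe_intensity Non-negative COE integrated intensities.
#' @return sqrt(intensity), a relative-diameter value.
#' @export
size_proxy <- function(coe_intensity) {
  if (any(coe_intensity < 0)) stop("negative intensity")
  sqrt(coe_intensity)
}

#' Between-subpopulation dispersion of a marker's mean intensity
#'
#' Normalizes each subpopulation's mean intensity by the grand mean across
#' subpopulations and returns the population variance of the normalized
#' values. Larger values mean the marker's per-particle signal differs more
#' strongly between subpopulations; the statistic is invariant to global
#' intensity rescaling by construction.
#'
#' @param label_means Per-subpopulation mean intensities (>= 2 values).
#' @param normalize `"grand_mean"` (default) or `"max"`.
#' @return The normalized-intensity variance, a non-negative scalar.
#' @export
normalized_variance <- function(label_means,
                                normalize = c("grand_mean", "max")) {
  normalize <- match.arg(normalize)
  label_means <- label_means[is.finite(label_means)]
  if (length(label_means) < 2)
    stop("need mean intensities from at least 2 subpopulations")
  ref <- if (normalize == "grand_mean") mean(label_means) else
    max(label_means)
  if (ref == 0) stop("grand mean is zero")
  z <- label_means / ref
  mean((z - mean(z))^2)   # population variance
}

#' Fraction of bulk particles captured on the imaging surface
#'
#' f = (surface density x chip area) / (bulk concentration x incubated
#' volume), with micrometre/millimetre/millilitre conversions handled
#' internally. Values above 1 violate mass balance and trigger a warning.
#'
#' @param surface_density_per_um2 Measured particles per square micrometre.
#' @param chip_area_mm2 Imaging chip area (mm^2).
#' @param bulk_concentration_per_ml Bulk particle concentration (1/mL).
#' @param incubated_volume_ml Incubated sample volume (mL).
#' @return The captured fraction.
#' @export
captured_fraction <- function(surface_density_per_um2, chip_area_mm2,
                              bulk_concentration_per_ml,
                              incubated_volume_ml) {
  stopifnot(surface_density_per_um2 >= 0, chip_area_mm2 > 0,
            incubated_volume_ml > 0)
  if (bulk_concentration_per_ml <= 0) stop("bulk concentration must be > 0")
  n_surface <- surface_density_per_um2 * chip_area_mm2 * 1e6  # mm^2 -> um^2
  n_bulk <- bulk_concentration_per_ml * incubated_volume_ml
  f <- n_surface / n_bulk
  if (f > 1)
    warning("captured fraction ", signif(f, 4),
            " exceeds 1: surface count exceeds supplied particles ",
            "(mass-balance violation)")
  f
}

#' Compare a summary statistic between two groups of trials
#'
#' Two-sided Welch two-sample t-test on trial-level summary values, with the
#' conventional significance stars.
#'
#' @param group1,group2 Numeric vectors of per-trial summaries (>= 2, ideally
#'   >= 3 trials each).
#' @return List with `p_value`, `t`, `stars` ("ns", "*", "**", "***").
#' @export
compare_groups <- function(group1, group2) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("need at least 2 trials per group")
  if (length(group1) < 3 || length(group2) < 3)
    warning("fewer than 3 trials in a group: the test is underpowered")
  if (sd(group1) == 0 && sd(group2) == 0 &&
      mean(group1) == mean(group2))
    return(list(p_value = 1, t = 0, stars = "ns"))
  ht <- t.test(group1, group2, var.equal = FALSE)
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(p_value = p, t = unname(ht$statistic), stars = stars)
}

#' Convert a pixel count to physical length
#'
#' @param pixels Number of pixels.
#' @param pixel_size_um Pixel pitch (um/px).
#' @return Length in micrometres.
#' @export
physical_length <- function(pixels, pixel_size_um = 0.25) {
  stopifnot(pixel_size_um > 0)
  pixels * pixel_size_um
}

#' Number of fields needed to tile an imaging chip
#'
#' @param chip_area_mm2 Chip area (mm^2).
#' @param fov_um Field of view as c(width, height) in micrometres.
#' @return Integer field count, `ceiling(chip area / field area)`.
#' @export
plan_acquisition <- function(chip_area_mm2, fov_um = c(100, 100)) {
  stopifnot(chip_area_mm2 > 0, all(fov_um > 0), length(fov_um) == 2L)
  field_mm2 <- prod(fov_um) / 1e6
  as.integer(ceiling(chip_area_mm2 / field_mm2))
}

#' Per-subpopulation content summary
#'
#' Mean integrated intensity per marker and particle count for each
#' subpopulation (flag-excluded), the between-subpopulation
#' normalized-intensity variance per marker, and optionally mean CD63 copy
#' numbers when a calibration model is supplied. Standard errors are across
#' ROIs when several are present.
#'
#' @param particles Particle table.
#' @param calibration Optional `calibration_model` for CD63 counting.
#' @return List with `table` (per-label data.frame), `variance` (named per
#'   marker), and `n_total`.
#' @export
subpopulation_summary <- function(particles, calibration = NULL) {
  keep <- !particles$flag_edge & !particles$flag_aggregate
  p <- particles[keep, , drop = FALSE]
  if (nrow(p) == 0) stop("no particles after flag exclusion")
  labels <- if (all(p$label %in% subpop_labels())) subpop_labels() else
    sort(unique(p$label))
  rows <- lapply(labels, function(l) {
    sub <- p[p$label == l, , drop = FALSE]
    mean_pos <- function(marker) {
      v <- sub[[paste0("intensity_", marker)]][sub[[paste0("pos_", marker)]]]
      if (length(v)) mean(v) else NA_real_
    }
    data.frame(label = l, n = nrow(sub),
               mean_COE = mean_pos("COE"),
               mean_CFSE = mean_pos("CFSE"),
               mean_CD63 = mean_pos("CD63"),
               mean_cd63_count = if (!is.null(calibration)) {
                 v <- sub$intensity_CD63[sub$pos_CD63]
                 if (length(v)) mean(v) / calibration$unit_mu_adu else
                   NA_real_
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  vfun <- function(marker) {
    mm <- tab[[paste0("mean_", marker)]]
    mm <- mm[!is.na(mm)]
    if (length(mm) >= 2) normalized_variance(mm) else NA_real_
  }
  list(table = tab,
       variance = c(COE = vfun("COE"), CFSE = vfun("CFSE"),
                    CD63 = vfun("CD63")),
       n_total = nrow(p))
}

#' @importFrom stats IQR predict
#' @importFrom graphics hist
NULL
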