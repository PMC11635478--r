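# End-to-end pipeline orchestration ------------------------------------------

#' Build a pipeline configuration
#'
#' @param fields List of field specs, each a list with `id` and `paths`
#'   (named channel -> TIFF path), or in-memory `field_image` objects.
#' @param pixel_size_um Pixel pitch.
#' @param preprocess A [preprocess_params()].
#' @param detection A [detection_params()].
#' @param coloc_mode "composite" (detect once on the merged image) or
#'   "match" (detect per channel, then nearest-neighbour match).
#' @param max_dist_px Matching radius for `coloc_mode = "match"`.
#' @param channel_shift_px Optional named list of per-channel `c(dx, dy)`
#'   chromatic shifts applied before colocalization.
#' @param calibration Optional: a numeric vector of calibration spot
#'   intensities, a path to a one-column CSV of them, or NULL.
#' @param capture Optional [list()] with `chip_area_mm2`,
#'   `bulk_concentration_per_ml`, `incubated_volume_ml` for the captured
#'   fraction.
#' @param out_dir Output directory (NULL for no file output).
#' @param seed Integer seed recorded in the run log.
#' @param plots Write diagnostic PNG plots.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fields, pixel_size_um = 0.25,
                            preprocess = preprocess_params(),
                            detection = detection_params(),
                            coloc_mode = c("composite", "match"),
                            max_dist_px = 2,
                            channel_shift_px = NULL,
                            calibration = NULL,
                            capture = NULL,
                            out_dir = NULL,
                            seed = 1L,
                            plots = FALSE) {
  coloc_mode <- match.arg(coloc_mode)
  structure(list(fields = fields, pixel_size_um = pixel_size_um,
                 preprocess = preprocess, detection = detection,
                 coloc_mode = coloc_mode, max_dist_px = max_dist_px,
                 channel_shift_px = channel_shift_px,
                 calibration = calibration, capture = capture,
                 out_dir = out_dir, seed = as.integer(seed), plots = plots),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # hash the canonical YAML text of the analysis-relevant configuration
  # (the output location and plotting switch do not affect results)
  cfg <- config
  cfg$out_dir <- NULL
  cfg$plots <- NULL
  cfg$fields <- lapply(cfg$fields, function(f) {
    if (inherits(f, "field_image"))
      list(id = f$field_id, channels = names(f$channels),
           dims = dim(f$channels[[1]]))
    else f
  })
  cfg$calibration <- if (is.numeric(cfg$calibration))
    list(n = length(cfg$calibration), sum = sum(cfg$calibration)) else
      cfg$calibration
  txt <- yaml::as.yaml(rapply(unclass(cfg), unclass, how = "replace"))
  tf <- tempfile()
  writeLines(txt, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

shift_channel <- function(m, dx, dy) {
  # constant integer chromatic shift; sub-pixel parts are ignored
  shift_matrix(m, as.integer(round(dy)), as.integer(round(dx)), 0)
}

load_config_field <- function(f, pixel_size_um) {
  if (inherits(f, "field_image")) return(f)
  read_field_tiff(unlist(f$paths), pixel_size_um,
                  field_id = if (!is.null(f$id)) f$id else "field")
}

#' Run the full analysis pipeline
#'
#' For every field: preprocess (flat-field then rolling ball), detect and
#' colocalize (composite or per-channel matching), categorize into the seven
#' subpopulations, then pool particles across fields for Venn fractions and
#' per-subpopulation content statistics. With a calibration source the CD63
#' intensities are converted to molecule counts. Outputs (particle table,
#' Venn JSON, summary CSV, run log) are written under `out_dir` when set;
#' identical configuration and inputs give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with `particles`, `venn`, `summary`, `calibration`,
#'   `cd63_counts`, `captured_fraction`, `config_hash`, `log` (character
#'   vector of log lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  log_lines <- c(
    sprintf("sevpimage %s", as.character(utils::packageVersion("sevpimage"))),
    sprintf("config_hash %s", hash),
    sprintf("seed %d", config$seed),
    sprintf("coloc_mode %s", config$coloc_mode),
    sprintf("blur_radius_px %s ball_radius_px %s",
            fmt_num(config$preprocess$blur_radius_px),
            fmt_num(config$preprocess$ball_radius_px)),
    sprintf("kernel_size_px %s k_sd %s min_area_px %d",
            fmt_num(config$detection$kernel_size_px),
            fmt_num(config$detection$k_sd), config$detection$min_area_px))
  logi <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  all_particles <- list()
  agg_fracs <- numeric(0)
  for (f in config$fields) {
    field <- load_config_field(f, config$pixel_size_um)
    if (!is.null(config$channel_shift_px)) {
      for (ch in intersect(names(config$channel_shift_px),
                           names(field$channels))) {
        s <- config$channel_shift_px[[ch]]
        field$channels[[ch]] <- shift_channel(field$channels[[ch]],
                                              s[1], s[2])
      }
    }
    pre <- preprocess_field(field, config$preprocess)
    particles <- if (config$coloc_mode == "composite") {
      composite_detect(pre, config$detection)
    } else {
      spots_by <- lapply(names(pre$channels), function(ch) {
        filt <- band_filter(pre$channels[[ch]],
                            config$detection$kernel_size_px)
        sp <- detect_spots(filt, pre$channels[[ch]], config$detection,
                           channel = ch, field_id = pre$field_id)
        sp <- segment_strings(sp, filt, pre$channels[[ch]],
                              config$detection)
        flag_aggregates(sp, config$detection)
      })
      names(spots_by) <- names(pre$channels)
      match_spots(spots_by, config$max_dist_px, field_id = pre$field_id)
    }
    af <- attr(particles, "aggregate_fraction")
    if (!is.null(af) && is.finite(af)) {
      agg_fracs <- c(agg_fracs, af)
      if (af > 0) logi("WARN field %s: aggregate fraction %.3f excluded",
                      pre$field_id, af)
    }
    if (nrow(particles) == 0)
      logi("WARN field %s: no particles detected", pre$field_id)
    logi("field %s: %d particles", pre$field_id, nrow(particles))
    all_particles[[length(all_particles) + 1L]] <- particles
  }
  particles <- do.call(rbind, lapply(all_particles, as.data.frame))
  rownames(particles) <- NULL

  venn <- if (nrow(particles) > 0 &&
              any(!particles$flag_edge & !particles$flag_aggregate))
    venn_fractions(particles) else NULL

  calibration <- NULL
  if (!is.null(config$calibration)) {
    ints <- config$calibration
    if (is.character(ints)) ints <- read_table_csv(ints)[[1]]
    calibration <- fit_single_fluorophore(ints)
    logi("calibration: unit %.1f +/- %.1f ADU (R^2 %.3f)",
         calibration$unit_mu_adu, calibration$unit_sigma_adu,
         calibration$fit_quality)
  }
  summary <- if (!is.null(venn)) subpopulation_summary(particles,
                                                       calibration) else NULL

  cd63_counts <- NULL
  if (!is.null(calibration) && !is.null(venn)) {
    keep <- particles$pos_CD63 & !particles$flag_edge &
      !particles$flag_aggregate
    if (sum(keep) > 0)
      cd63_counts <- counts_by_ratio(particles$intensity_CD63[keep],
                                     calibration)
  }

  capfrac <- NULL
  if (!is.null(config$capture) && nrow(particles) > 0) {
    area_px <- prod(dim(load_config_field(config$fields[[1]],
                                          config$pixel_size_um)$channels[[1]]))
    total_area_um2 <- length(config$fields) * area_px *
      config$pixel_size_um^2
    dens <- sum(!particles$flag_edge & !particles$flag_aggregate) /
      total_area_um2
    capfrac <- captured_fraction(dens, config$capture$chip_area_mm2,
                                 config$capture$bulk_concentration_per_ml,
                                 config$capture$incubated_volume_ml)
    logi("surface density %.4f /um^2, captured fraction %.3f", dens, capfrac)
    if (capfrac > 1) logi("WARN captured fraction > 1 (mass balance)")
  }

  res <- list(particles = particles, venn = venn, summary = summary,
              calibration = calibration, cd63_counts = cd63_counts,
              captured_fraction = capfrac,
              aggregate_fraction = if (length(agg_fracs))
                mean(agg_fracs) else 0,
              config_hash = hash, log = log_lines)

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  write_table_csv(res$particles, file.path(od, "particles.csv"),
                  res$config_hash)
  if (!is.null(res$venn)) {
    venn_list <- as.list(setNames(res$venn$fraction, res$venn$label))
    jsonlite::write_json(
      list(config_hash = res$config_hash, fractions = venn_list,
           se = as.list(setNames(res$venn$se, res$venn$label)),
           n = sum(res$venn$count)),
      file.path(od, "venn.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$summary))
    write_table_csv(res$summary$table, file.path(od, "summary.csv"),
                    res$config_hash)
  if (!is.null(res$cd63_counts))
    write_table_csv(res$cd63_counts$histogram,
                    file.path(od, "cd63_count_histogram.csv"),
                    res$config_hash)
  writeLines(res$log, file.path(od, "run.log"))
  if (isTRUE(config$plots)) write_diagnostic_plots(res, od)
  invisible(od)
}

write_diagnostic_plots <- function(res, od) {
  p <- res$particles
  keep <- !p$flag_edge & !p$flag_aggregate
  grDevices::png(file.path(od, "intensity_scatter.png"), 600, 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  both <- keep & p$pos_COE & p$pos_CFSE
  if (sum(both) >= 2) {
    graphics::plot(p$intensity_COE[both], p$intensity_CFSE[both],
                   log = "xy", pch = 20, cex = 0.5,
                   xlab = "COE intensity (ADU)",
                   ylab = "CFSE intensity (ADU)",
                   main = "Per-particle marker intensities")
  } else graphics::plot.new()
  invisible(NULL)
}

#' Simulate a scene and write it to disk
#'
#' Convenience wrapper pairing [generate_scene()] with [write_scene()]:
#' produces the per-channel TIFFs, truth CSV and parameter YAML that
#' [run_pipeline()] consumes.
#'
#' @param params A [scene_params()].
#' @param dir Output directory.
#' @param scene_name Basename prefix.
#' @return Invisibly, the written paths.
#' @export
simulate_scene_files <- function(params, dir, scene_name = "scene") {
  scene <- generate_scene(params, field_id = scene_name)
  write_scene(scene, dir, scene_name)
}
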