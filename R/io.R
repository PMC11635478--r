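# TIFF, CSV and config I/O ----------------------------------------------------

#' Write a field of view as per-channel 16-bit TIFF files
#'
#' One single-plane grayscale TIFF per channel, named
#' `<scene>_<channel>.tif`. Values are stored as 16-bit unsigned integers;
#' ADU above 65535 are clipped with a warning.
#'
#' @param field A [field_image()].
#' @param dir Output directory (created if needed).
#' @param scene Basename prefix.
#' @return Invisibly, the written file paths (named by channel).
#' @export
write_field_tiff <- function(field, dir, scene = field$field_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(field$channels)) {
    m <- field$channels[[ch]]
    if (any(m > 65535)) {
      warning("channel ", ch, ": values above 65535 clipped for 16-bit TIFF")
      m <- pmin(m, 65535)
    }
    path <- file.path(dir, paste0(scene, "_", ch, ".tif"))
    tiff::writeTIFF(round(m) / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    paths[ch] <- path
  }
  invisible(paths)
}

#' Read per-channel TIFF files into a field of view
#'
#' Accepts single-plane grayscale TIFFs (one file per channel); 16-bit files
#' are rescaled back to ADU. A multi-page TIFF given as a single path is
#' interpreted as one channel per page, in the declared channel order.
#'
#' @param paths Named character vector of file paths (names = channel
#'   labels), or one multi-page TIFF path with `channels` giving the labels.
#' @param pixel_size_um Pixel pitch.
#' @param field_id Field identifier.
#' @param channels Channel labels for the multi-page case.
#' @return A [field_image()].
#' @export
read_field_tiff <- function(paths, pixel_size_um, field_id = "field",
                            channels = NULL) {
  to_adu <- function(x) {
    if (is.list(x)) return(lapply(x, to_adu))
    m <- x
    if (length(dim(m)) == 3L) m <- m[, , 1]   # drop extra samples per pixel
    m * 65535
  }
  if (length(paths) == 1L && !is.null(channels)) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (length(pages) != length(channels))
      stop("multi-page TIFF has ", length(pages), " pages but ",
           length(channels), " channel labels were declared")
    chans <- setNames(lapply(pages, function(p) to_adu(p)), channels)
  } else {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
      stop("per-channel paths must be named by channel label")
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("missing channel file(s): ",
                              paste(missing, collapse = ", "))
    chans <- lapply(paths, function(p) to_adu(tiff::readTIFF(p)))
  }
  field_image(chans, pixel_size_um, field_id)
}

#' Write a scene and its ground truth to disk
#'
#' Writes per-channel TIFFs, the truth table as CSV, and the generator
#' parameters as a YAML config, so a simulated data set can be consumed by
#' the pipeline exactly like real acquisitions.
#'
#' @param scene List from [generate_scene()].
#' @param dir Output directory.
#' @param scene_name Basename prefix.
#' @return Invisibly, a list of written paths.
#' @export
write_scene <- function(scene, dir, scene_name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiffs <- write_field_tiff(scene$field, dir, scene_name)
  truth_path <- file.path(dir, paste0(scene_name, "_truth.csv"))
  write.csv(scene$truth, truth_path, row.names = FALSE)
  params <- attr(scene$truth, "params")
  cfg_path <- file.path(dir, paste0(scene_name, "_params.yaml"))
  yaml::write_yaml(unclass(params), cfg_path)
  invisible(list(tiffs = tiffs, truth = truth_path, params = cfg_path))
}

#' Write a spot or particle table as CSV
#'
#' Fixed column order; a `# config_hash:` comment line records the
#' configuration that produced the table when one is supplied.
#'
#' @param x Spot or particle data.frame.
#' @param path Output CSV path.
#' @param config_hash Optional hash string written into the header comment.
#' @export
write_table_csv <- function(x, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
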