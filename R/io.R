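# File I/O: multi-page 16-bit TIFF movies, masks, tables, config.

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit samples; values are clamped to
#' [0, 65535].
#'
#' @param stack an \code{\link{ImageStack}} or 3D array.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStackTiff <- function(stack, path) {
  a <- if (is(stack, "ImageStack")) frames(stack) else stack
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  pages <- lapply(seq_len(dim(a)[3L]), function(t)
    pmin(pmax(a[, , t], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file written by \code{\link{writeStackTiff}}.
#' @param pixelSize,frameInterval calibration to attach.
#' @return an \code{\link{ImageStack}} in counts.
#' @export
readStackTiff <- function(path, pixelSize = 0.1, frameInterval = 0.034) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) a[, , t] <- pages[[t]] * 65535
  ImageStack(a, pixelSize, frameInterval)
}

#' Write a binary mask as a single-page TIFF
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMaskTiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write ground truth as JSON plus a CSV positions table
#'
#' @param truth a \code{\link{GroundTruth}}.
#' @param prefix path prefix; writes \code{<prefix>.json} (counts, pairs)
#'   and \code{<prefix>_positions.csv}.
#' @return the JSON path, invisibly.
#' @export
writeGroundTruth <- function(truth, prefix) {
  jsonPath <- paste0(prefix, ".json")
  jsonlite::write_json(list(counts = truth@counts,
                            pairs = truth@pairs),
                       jsonPath, digits = NA)
  utils::write.csv(truth@positions, paste0(prefix, "_positions.csv"),
                   row.names = FALSE)
  invisible(jsonPath)
}

#' Write a correlation time course as a CSV matrix
#'
#' Rows are time points, columns are lags (column names carry the lag in
#' um).
#'
#' @param tc a \code{\link{CorrelationTimecourse}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTimecourseCsv <- function(tc, path) {
  m <- tc@values
  colnames(m) <- sprintf("lag_%+.2f", tc@lags)
  utils::write.csv(data.frame(time = tc@times, m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Contour plot of a correlation time course
#'
#' Filled contours of correlation versus distance lag (x) and time (y),
#' low-to-high correlation colored blue to red.
#'
#' @param tc a \code{\link{CorrelationTimecourse}}.
#' @param main plot title.
#' @return invisibly, NULL; draws on the active device.
#' @export
plotTimecourse <- function(tc, main = "short-axis autocorrelation") {
  pal <- grDevices::colorRampPalette(c("#2c7bb6", "#ffffbf", "#d7191c"))
  graphics::filled.contour(
    x = tc@lags, y = tc@times, z = t(tc@values), color.palette = pal,
    xlab = "distance lag (um)", ylab = "time (min)", main = main)
  invisible(NULL)
}

#' Load a run configuration
#'
#' Reads a YAML config file and fills in package defaults for missing
#' keys, warning once per defaulted key. The returned list carries a
#' provenance block (config hash, seed, package version) that analysis
#' outputs embed.
#'
#' @param path YAML file, or NULL for an all-defaults config.
#' @param defaults named list of defaults
#'   (\code{\link{defaultRunConfig}}).
#' @return a named list with attribute \code{provenance}.
#' @export
readRunConfig <- function(path = NULL, defaults = defaultRunConfig()) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  missing <- setdiff(names(defaults), names(user))
  if (length(missing) && !is.null(path))
    warning("config keys defaulted: ", paste(missing, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  hash <- sum(utf8ToInt(paste(names(cfg), unlist(cfg), collapse = ";"))) %%
    .Machine$integer.max
  attr(cfg, "provenance") <- list(
    configHash = hash,
    seed = cfg$seed,
    package = as.character(utils::packageVersion("memloc")))
  cfg
}

#' Default run configuration
#'
#' All tunable pipeline parameters with their package defaults.
#'
#' @return a named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    pixel_size_um = 0.1,
    psf_sigma_um = 0.10,
    depth_of_field_um = 0.10,
    frame_interval_s = 0.034,
    n_frames = 296L,
    cell_width_um = 0.6,
    cell_length_um = 4.5,
    bleach_tau_s = 5.0,
    photon_rate = 5000,
    em_gain = 30,
    read_noise = 20,
    camera_offset = 100,
    background_rate = 50,
    autofluor_rate = 30,
    illumination_corner_ratio = 0.70,
    blur_radius_px = 10,
    discoidal_r_inner = 1,
    discoidal_r_outer = 3,
    max_lag_um = 1.0,
    bin_height_um = 20,
    peak_exclusion_um = 0.25,
    static_min_duration_s = 0.300,
    coloc_radius_nm = 100,
    tail_frames = 50L,
    timelapse_interval_min = 5)
}
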