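#' Read a single-plane grayscale TIFF as an intensity grid
#'
#' Accepts 8- or 16-bit single-plane grayscale TIFFs and returns raw integer
#' intensities. The physical pixel size comes from the caller's
#' configuration; a resolution tag embedded in the file never overrides it
#' (a notice is emitted when the two disagree).
#'
#' @param path TIFF file.
#' @param pixel_size um/px to attach.
#' @return a [pixel_grid()] of integer intensities.
#' @export
read_image <- function(path, pixel_size = 1) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(planes) != 1)
    stop("multi-plane TIFF not supported (", length(planes),
         " planes): supply single-plane grayscale images")
  img <- planes[[1]]
  if (length(dim(img)) != 2)
    stop("RGB/multi-channel TIFF not supported: supply grayscale images")
  xres <- attr(img, "x.resolution")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    tag_um <- 1e4 / xres  # TIFF resolution is typically px per cm
    if (abs(tag_um - pixel_size) / pixel_size > 0.01)
      message("TIFF resolution tag (", signif(tag_um, 3),
              " um/px) differs from configured pixel_size (", pixel_size,
              "); configuration wins")
  }
  pixel_grid(matrix(as.numeric(img), nrow(img), ncol(img)), pixel_size)
}

#' Write an intensity grid as a 16-bit grayscale TIFF
#'
#' Intensities are rounded and clipped to the `[0, 2^bits - 1]` range;
#' integer-valued grids round-trip bit-exactly through [read_image()].
#'
#' @param img numeric matrix.
#' @param path output file.
#' @param bits 8 or 16.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path, bits = 16) {
  stopifnot(bits %in% c(8, 16))
  maxv <- 2^bits - 1
  m <- pmin(pmax(round(as_plain(img)), 0), maxv)
  tiff::writeTIFF(m / maxv, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' Per-channel 16-bit grayscale TIFFs (`<name>.tif`), the ground-truth label
#' map (`labels.tif`, 16-bit) and the per-colonoid truth table
#' (`truth.csv`: label, true_angle_deg, true_slope, true_edu_offset,
#' true_edu_angle, area_um2).
#'
#' @param scene a [make_scene()] result.
#' @param dir output directory (created if needed).
#' @param clean write the noise-free channels instead of the degraded ones?
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir, clean = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set <- if (clean) scene$clean else scene$channels
  for (nm in names(set))
    write_image(set[[nm]], file.path(dir, paste0(nm, ".tif")))
  write_image(scene$truth$label_map, file.path(dir, "labels.tif"))
  write.csv(scene$truth$table, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Pipeline configuration
#'
#' @param channels named list of TIFF paths (`dsred`, `brightfield`, and
#'   optionally `egfp`, `hoechst`, `edu`, `muc2`); alternatively a named list
#'   of in-memory matrices.
#' @param pixel_size um/px.
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest (the measurement path is
#'   deterministic; the seed governs any simulation step).
#' @param segmentation a [segment_config()].
#' @param measurement a [measure_config()].
#' @param condition optional condition name attached to every record.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(channels, pixel_size = 1, outdir = "colonpol_out",
                            seed = 1L, segmentation = segment_config(),
                            measurement = measure_config(),
                            condition = NA_character_) {
  stopifnot(is.list(channels), "dsred" %in% names(channels) ||
              "hoechst" %in% names(channels))
  structure(list(channels = channels, pixel_size = pixel_size,
                 outdir = outdir, seed = as.integer(seed),
                 segmentation = segmentation, measurement = measurement,
                 condition = condition),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(segment_config, y$segmentation %||% list())
  mea <- do.call(measure_config, y$measurement %||% list())
  pipeline_config(channels = y$channels,
                  pixel_size = y$pixel_size %||% 1,
                  outdir = y$outdir %||% "colonpol_out",
                  seed = y$seed %||% 1L, segmentation = seg,
                  measurement = mea,
                  condition = y$condition %||% NA_character_)
}

#' Run the segment-measure-report pipeline
#'
#' Reads (or takes in memory) the channel images, segments colonoids from
#' DsRed (or Hoechst) with brightfield debris removal, measures every
#' colonoid, and writes `colonoids.csv` (one row per colonoid),
#' `vectors.csv` (compass-plot data: label, angle_deg, magnitude, metric),
#' `summary.csv`, the label map as `labels.tif`, and `manifest.json`
#' (configuration hash, package version, seed). Identical configuration and
#' seed give byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()] or path to its YAML.
#' @return the output directory, invisibly; the measurement table is attached
#'   as attribute `"records"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  chans <- lapply(config$channels, function(ch) {
    if (is.character(ch)) read_image(ch, config$pixel_size)
    else pixel_grid(as_plain(ch), config$pixel_size)
  })
  fluor <- chans$dsred %||% chans$hoechst
  labels <- segment_colonoids(fluor, chans$brightfield,
                              config$segmentation, config$pixel_size)
  records <- measure_colonoids(chans, labels, config$measurement,
                               config$pixel_size)
  records$condition <- config$condition
  write_image(labels, file.path(config$outdir, "labels.tif"))
  write.csv(records, file.path(config$outdir, "colonoids.csv"),
            row.names = FALSE)
  vec <- rbind(
    data.frame(label = records$label, angle_deg = records$sox9_angle_deg,
               magnitude = records$sox9_magnitude, metric = "sox9_slope"),
    data.frame(label = records$label, angle_deg = records$edu_angle_deg,
               magnitude = records$edu_magnitude, metric = "edu_centroid"))
  write.csv(vec, file.path(config$outdir, "vectors.csv"), row.names = FALSE)
  if (nrow(records)) {
    smry <- condition_summary(records)
    write.csv(smry, file.path(config$outdir, "summary.csv"),
              row.names = FALSE)
  }
  cfg_path <- file.path(config$outdir, "config.yaml")
  cfg_flat <- config
  cfg_flat$channels <- lapply(config$channels, function(ch)
    if (is.character(ch)) ch else "<in-memory matrix>")
  yaml::write_yaml(unclass(cfg_flat), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("colonpol")),
    seed = config$seed,
    n_colonoids = nrow(records))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(config$outdir, records = records))
}
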