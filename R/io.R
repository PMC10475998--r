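#' Construct and validate a localization table
#'
#' @param rows data.frame with columns `frame`, `x_nm`, `y_nm`, `photons`,
#'   `signal`, `precision_nm` (extra columns are kept).
#' @param pixel_size_nm camera pixel size in nm.
#' @param n_frames number of frames in the acquisition.
#' @return `localization_table` (a data.frame with attributes).
#' @export
localization_table <- function(rows, pixel_size_nm = 107, n_frames = NULL) {
  need <- c("frame", "x_nm", "y_nm", "photons", "signal", "precision_nm")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0)
    stop("localization table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(n_frames)) n_frames <- if (nrow(rows)) max(rows$frame) else 0L
  if (nrow(rows) > 0) {
    if (any(rows$frame < 1 | rows$frame > n_frames))
      stop("frames must lie in [1, n_frames]", call. = FALSE)
    if (any(rows$photons <= 0) || any(rows$precision_nm <= 0))
      stop("photons and precision_nm must be positive", call. = FALSE)
  }
  structure(as.data.frame(rows), pixel_size_nm = pixel_size_nm,
            n_frames = as.integer(n_frames),
            class = c("localization_table", "data.frame"))
}

#' Read / write localization CSV files
#'
#' Dialect: header `frame,x_nm,y_nm,photons,signal,precision_nm`; the
#' reader tolerates extra columns.
#'
#' @param path CSV path.
#' @param pixel_size_nm,n_frames metadata attached on read.
#' @return [read_localizations()] returns a `localization_table`.
#' @export
read_localizations <- function(path, pixel_size_nm = 107, n_frames = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  localization_table(df, pixel_size_nm = pixel_size_nm, n_frames = n_frames)
}

#' @rdname read_localizations
#' @param table a `localization_table` or compatible data.frame.
#' @export
write_localizations <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a rendered image as TIFF with a JSON sidecar
#'
#' Pixel values are scaled into `[0, 1]` for storage; the scale factor,
#' pixel size and channel identity travel in `<path>.json`.
#'
#' @param image a `rendered_image`.
#' @param path output TIFF path.
#' @export
write_image_tiff <- function(image, path) {
  px <- as_pixel_matrix(image)
  scale <- max(px, 1)
  # TIFF rows are y; transpose so x maps to columns on disk
  tiff::writeTIFF(t(px) / scale, path, bits.per.sample = 16L)
  meta <- list(channel = if (inherits(image, "rendered_image")) image$channel else NA,
               modality = if (inherits(image, "rendered_image")) image$modality else NA,
               pixel_size_nm = image_pixel_size(image),
               scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- t(tiff::readTIFF(path)) * meta$scale
  structure(list(pixels = px, channel = meta$channel,
                 pixel_size_nm = c(x = meta$pixel_size_nm,
                                   y = meta$pixel_size_nm),
                 psf_fwhm_nm = NA_real_, modality = meta$modality,
                 background = NA_real_,
                 field_nm = nrow(px) * meta$pixel_size_nm),
            class = "rendered_image")
}

#' Write a complete synthetic fixture set to disk
#'
#' Generates a scene, renders it under the requested modalities, simulates
#' a localization stream, and writes TIFF images, localization CSVs and
#' ground-truth CSVs plus a JSON manifest recording every seed, so a run
#' can be reproduced bit-exactly.
#'
#' @param out_dir writable output directory (created if absent).
#' @param params a [scene_params()] object.
#' @param modalities modalities to render.
#' @param channels channels to render per modality.
#' @param n_frames,events_rate,precision_nm forwarded to
#'   [simulate_localization_events()].
#' @param noise render with shot noise.
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
write_fixture_set <- function(out_dir, params = scene_params(),
                              modalities = c("confocal", "airyscan", "gsted"),
                              channels = SCENE_CHANNELS,
                              n_frames = 400, events_rate = 0.01,
                              precision_nm = 20, noise = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  scene <- generate_scene(params)
  gt_syn <- file.path(out_dir, "ground_truth_synapses.csv")
  gt_cl <- file.path(out_dir, "ground_truth_clusters.csv")
  write.csv(scene$synapses, gt_syn, row.names = FALSE, quote = FALSE)
  cl <- scene$clusters
  gt <- data.frame(id = cl$id,
                   subtype = scene$synapses$subtype[
                     match(cl$parent_synapse, scene$synapses$id)],
                   compartment = cl$compartment, x_nm = cl$x_nm,
                   y_nm = cl$y_nm, z_nm = cl$z_nm,
                   diameter_nm = cl$diameter_nm)
  write.csv(gt, gt_cl, row.names = FALSE, quote = FALSE)

  images <- list()
  for (m in modalities) for (ch in channels) {
    f <- file.path(out_dir, sprintf("%s_%s.tif", m, ch))
    img <- render_channel_image(scene, m, ch, noise = noise,
                                seed = params$seed + 1000L)
    write_image_tiff(img, f)
    images[[length(images) + 1L]] <-
      list(path = basename(f), modality = m, channel = ch,
           pixel_size_nm = unname(img$pixel_size_nm[["x"]]))
  }
  stream <- simulate_localization_events(scene, n_frames = n_frames,
                                         mean_events_per_cluster_per_frame = events_rate,
                                         precision_nm = precision_nm,
                                         seed = params$seed + 2000L)
  locs <- events_to_localizations(stream)
  loc_path <- file.path(out_dir, "localizations.csv")
  write_localizations(locs, loc_path)

  manifest <- list(seed = params$seed,
                   field_size_um = params$field_size_um,
                   n_synapses = nrow(scene$synapses),
                   n_clusters = nrow(scene$clusters),
                   modalities = as.list(modalities),
                   images = images,
                   localizations = list(path = basename(loc_path),
                                        n_frames = n_frames,
                                        precision_nm = precision_nm,
                                        seed = params$seed + 2000L),
                   ground_truth = list(synapses = basename(gt_syn),
                                       clusters = basename(gt_cl)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
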