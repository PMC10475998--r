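#' Imaging modality presets
#'
#' Pixel sizes follow the acquisition settings of each instrument class
#' (Airyscan 35 nm, g-STED 20 nm, SMLM camera 107 nm = 16 um EMCCD pixel /
#' (60x objective x 2.5 beam expander)); PSF widths are configurable
#' defaults chosen so that rendering identical ground truth reproduces the
#' empirical confocal > Airyscan > g-STED ordering of measured spot sizes.
#'
#' @param modality one of `"confocal"`, `"airyscan"`, `"gsted"`, `"tirf"`.
#' @return list with `pixel_size_nm` and `psf_fwhm_nm`.
#' @export
modality_config <- function(modality = c("confocal", "airyscan", "gsted",
                                         "tirf")) {
  modality <- match.arg(modality)
  switch(modality,
         confocal = list(pixel_size_nm = 85, psf_fwhm_nm = 300),
         airyscan = list(pixel_size_nm = 35, psf_fwhm_nm = 180),
         gsted    = list(pixel_size_nm = 20, psf_fwhm_nm = 90),
         tirf     = list(pixel_size_nm = 107, psf_fwhm_nm = 300))
}

SCENE_CHANNELS <- c("PSD95", "VGLUT1", "VGLUT2", "pTDP43")

# rasterize additive ellipse interiors at pixel centers into `img`
add_ellipses <- function(img, ps, cx, cy, a, b, theta, amp) {
  nx <- nrow(img); ny <- ncol(img)
  for (i in seq_along(cx)) {
    r <- max(a[i], b[i])
    i0 <- max(1L, floor((cx[i] - r) / ps)); i1 <- min(nx, ceiling((cx[i] + r) / ps))
    j0 <- max(1L, floor((cy[i] - r) / ps)); j1 <- min(ny, ceiling((cy[i] + r) / ps))
    if (i0 > i1 || j0 > j1) next
    xs <- px_center_nm(i0:i1, ps); ys <- px_center_nm(j0:j1, ps)
    g <- expand.grid(x = xs, y = ys)
    ins <- inside_ellipse(g$x, g$y, cx[i], cy[i], a[i], b[i], theta[i])
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] +
      matrix(ins * amp[i], length(xs), length(ys))
  }
  img
}

# rasterize additive isotropic Gaussian spots (sigma in nm) at pixel centers
add_gaussian_spots <- function(img, ps, cx, cy, sigma, amp) {
  nx <- nrow(img); ny <- ncol(img)
  for (i in seq_along(cx)) {
    r <- 4 * sigma[i]
    i0 <- max(1L, floor((cx[i] - r) / ps)); i1 <- min(nx, ceiling((cx[i] + r) / ps))
    j0 <- max(1L, floor((cy[i] - r) / ps)); j1 <- min(ny, ceiling((cy[i] + r) / ps))
    if (i0 > i1 || j0 > j1) next
    gx <- exp(-(px_center_nm(i0:i1, ps) - cx[i])^2 / (2 * sigma[i]^2))
    gy <- exp(-(px_center_nm(j0:j1, ps) - cy[i])^2 / (2 * sigma[i]^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp[i] * outer(gx, gy)
  }
  img
}

#' Render one channel of a scene as a modality-specific image
#'
#' Structures are rasterized in physical coordinates (terminals and PSDs as
#' uniform intensity ellipses, pTDP-43 clusters as Gaussian spots whose
#' FWHM equals the true cluster diameter), convolved with the modality's
#' Gaussian PSF, offset by a constant background and, optionally, corrupted
#' by Poisson shot noise on signal + background.
#'
#' @param scene a `synapse_scene`.
#' @param modality modality name understood by [modality_config()].
#' @param channel one of `"PSD95"`, `"VGLUT1"`, `"VGLUT2"`, `"pTDP43"`.
#' @param pixel_size_nm,psf_fwhm_nm overrides of the modality preset.
#' @param peak_intensity expected photon count at a structure's peak.
#' @param background constant background level (photons/pixel).
#' @param noise apply Poisson shot noise (`TRUE`) or return the noiseless
#'   expectation.
#' @param seed optional seed governing the shot noise only.
#' @return object of class `rendered_image`: list with `pixels` (matrix
#'   indexed `[x, y]`), `channel`, `pixel_size_nm`, `psf_fwhm_nm`,
#'   `modality` and `background`.
#' @export
render_channel_image <- function(scene, modality, channel,
                                 pixel_size_nm = NULL, psf_fwhm_nm = NULL,
                                 peak_intensity = 150, background = 10,
                                 noise = TRUE, seed = NULL) {
  if (!inherits(scene, "synapse_scene"))
    stop("`scene` must be a synapse_scene", call. = FALSE)
  if (!channel %in% SCENE_CHANNELS)
    stop("unknown channel `", channel, "`", call. = FALSE)
  cfg <- modality_config(modality)
  ps <- if (is.null(pixel_size_nm)) cfg$pixel_size_nm else pixel_size_nm
  psf <- if (is.null(psf_fwhm_nm)) cfg$psf_fwhm_nm else psf_fwhm_nm
  stop_if_not_scalar_pos(ps, "pixel_size_nm")
  stop_if_not_scalar_pos(psf, "psf_fwhm_nm", allow_zero = TRUE)

  L <- scene$params$field_size_um * 1000
  npx <- as.integer(ceiling(L / ps))
  img <- matrix(0, npx, npx)
  syn <- scene$synapses
  cl <- scene$clusters

  if (nrow(syn) > 0) {
    if (channel == "VGLUT1") {
      s <- syn[syn$subtype == "VGLUT1", ]
      img <- add_ellipses(img, ps, s$tx_nm, s$ty_nm, s$ta_nm, s$tb_nm,
                          s$ttheta, rep(peak_intensity, nrow(s)))
    } else if (channel == "VGLUT2") {
      s <- syn[syn$subtype == "VGLUT2", ]
      img <- add_ellipses(img, ps, s$tx_nm, s$ty_nm, s$ta_nm, s$tb_nm,
                          s$ttheta, rep(peak_intensity, nrow(s)))
      co <- syn[syn$subtype == "VGLUT1" & syn$vglut2_coexpression, ]
      if (nrow(co) > 0)  # weak VGLUT2 signal on a minority of VGLUT1 terminals
        img <- add_ellipses(img, ps, co$tx_nm, co$ty_nm, co$ta_nm, co$tb_nm,
                            co$ttheta, rep(0.3 * peak_intensity, nrow(co)))
    } else if (channel == "PSD95") {
      img <- add_ellipses(img, ps, syn$px_nm, syn$py_nm, syn$pa_nm,
                          syn$pb_nm, syn$ptheta,
                          rep(peak_intensity, nrow(syn)))
    }
  }
  if (channel == "pTDP43" && nrow(cl) > 0) {
    img <- add_gaussian_spots(img, ps, cl$x_nm, cl$y_nm,
                              cl$diameter_nm / FWHM_PER_SIGMA,
                              rep(peak_intensity, nrow(cl)))
  }

  img <- gauss_blur(img, psf / FWHM_PER_SIGMA / ps)
  img[img < 0] <- 0
  img <- img + background
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
  }
  structure(list(pixels = img, channel = channel,
                 pixel_size_nm = c(x = ps, y = ps), psf_fwhm_nm = psf,
                 modality = modality, background = background,
                 field_nm = L),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %s / %s, %d x %d px @ %.1f nm (PSF FWHM %.0f nm)\n",
              x$modality, x$channel, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_nm[["x"]], x$psf_fwhm_nm))
  invisible(x)
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "rendered_image")) image$pixels
  else if (is.matrix(image) || is.array(image)) image
  else stop("expected a rendered_image or a numeric matrix/array",
            call. = FALSE)
}

image_pixel_size <- function(image, default = NA_real_) {
  if (inherits(image, "rendered_image")) unname(image$pixel_size_nm[["x"]])
  else default
}

#' Simulate a DNA-PAINT-style localization event stream
#'
#' Per frame, every ground-truth cluster emits a Poisson number of binding
#' events placed uniformly within its disc; each event is detected at the
#' true position plus isotropic Gaussian localization error, with a
#' log-normal photon count.
#'
#' @param scene a `synapse_scene`.
#' @param n_frames number of acquisition frames (study setting: 4000).
#' @param mean_events_per_cluster_per_frame Poisson rate per cluster/frame.
#' @param precision_nm localization error scale (study estimate ~20 nm).
#' @param photons_meanlog,photons_sdlog log-normal photon parameters.
#' @param exposure_ms frame exposure (metadata only; 50 ms in the study).
#' @param seed integer seed.
#' @return `emitter_stream`: data.frame of events (`frame`, `true_x_nm`,
#'   `true_y_nm`, `x_nm`, `y_nm`, `photons`) with attributes `n_frames`
#'   and `exposure_ms`.
#' @export
simulate_localization_events <- function(scene, n_frames = 4000,
                                         mean_events_per_cluster_per_frame = 0.005,
                                         precision_nm = 20,
                                         photons_meanlog = log(500),
                                         photons_sdlog = 0.35,
                                         exposure_ms = 50, seed = 1L) {
  if (!inherits(scene, "synapse_scene"))
    stop("`scene` must be a synapse_scene", call. = FALSE)
  if (!is.numeric(n_frames) || n_frames < 1)
    stop("`n_frames` must be >= 1", call. = FALSE)
  rate <- mean_events_per_cluster_per_frame
  if (!is.numeric(rate) || !is.finite(rate) || rate < 0)
    stop("event rate must be non-negative", call. = FALSE)
  if (precision_nm < 0) stop("`precision_nm` must be >= 0", call. = FALSE)
  set.seed(seed)
  cl <- scene$clusters
  n_frames <- as.integer(n_frames)
  empty <- data.frame(frame = integer(), true_x_nm = numeric(),
                      true_y_nm = numeric(), x_nm = numeric(),
                      y_nm = numeric(), photons = numeric())
  if (nrow(cl) == 0 || rate == 0) {
    return(structure(empty, n_frames = n_frames, exposure_ms = exposure_ms,
                     class = c("emitter_stream", "data.frame")))
  }
  # total events per cluster over the run, then frames assigned uniformly
  n_ev <- rpois(nrow(cl), rate * n_frames)
  tot <- sum(n_ev)
  if (tot == 0) {
    return(structure(empty, n_frames = n_frames, exposure_ms = exposure_ms,
                     class = c("emitter_stream", "data.frame")))
  }
  idx <- rep(seq_len(nrow(cl)), n_ev)
  r <- (cl$diameter_nm[idx] / 2) * sqrt(runif(tot))
  ang <- runif(tot, 0, 2 * pi)
  tx <- cl$x_nm[idx] + r * cos(ang)
  ty <- cl$y_nm[idx] + r * sin(ang)
  ev <- data.frame(frame = sample.int(n_frames, tot, replace = TRUE),
                   true_x_nm = tx, true_y_nm = ty,
                   x_nm = tx + rnorm(tot, 0, precision_nm),
                   y_nm = ty + rnorm(tot, 0, precision_nm),
                   photons = rlnorm(tot, photons_meanlog, photons_sdlog))
  ev <- ev[order(ev$frame), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, n_frames = n_frames, exposure_ms = exposure_ms,
            class = c("emitter_stream", "data.frame"))
}

#' Convert an event stream into a localization table
#'
#' Attaches the per-localization quality metrics used by the filtering
#' stage: precision from the Thompson-style formula
#' sqrt((sigma_psf^2 + a^2/12) / N) and signal strength modeled as fitted
#' amplitude over residual noise, amplitude = N / (2 pi sigma_px^2).
#'
#' @param stream an `emitter_stream`.
#' @param pixel_size_nm camera pixel size (107 nm default).
#' @param psf_sigma_nm PSF sigma used by the fitter.
#' @param noise_sd residual noise SD (camera counts) in the signal model.
#' @return a `localization_table`.
#' @export
events_to_localizations <- function(stream, pixel_size_nm = 107,
                                    psf_sigma_nm = 127, noise_sd = 1.5) {
  a <- pixel_size_nm
  sig_px <- psf_sigma_nm / a
  prec <- sqrt((psf_sigma_nm^2 + a^2 / 12) / pmax(stream$photons, 1))
  signal <- stream$photons / (2 * pi * sig_px^2) / noise_sd
  localization_table(
    data.frame(frame = stream$frame, x_nm = stream$x_nm,
               y_nm = stream$y_nm, photons = stream$photons,
               signal = signal, precision_nm = prec),
    pixel_size_nm = pixel_size_nm,
    n_frames = attr(stream, "n_frames"))
}
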