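#' Rolling-ball background subtraction on a frame stack
#'
#' Applies the 12-pixel rolling-ball background subtraction to each frame
#' of an SMLM acquisition before peak fitting.
#'
#' @param frames 3D array `[x, y, frame]` or list of matrices.
#' @param radius_px ball radius (study setting: 12).
#' @return same shape as the input, non-negative.
#' @export
subtract_background_frames <- function(frames, radius_px = 12) {
  if (is.list(frames)) return(lapply(frames, rolling_ball_subtract,
                                     radius_px = radius_px))
  rolling_ball_subtract(frames, radius_px)
}

# fit one candidate peak on a square ROI; returns NULL on divergence
fit_one_peak <- function(roi, x0, y0) {
  nx <- nrow(roi); ny <- ncol(roi)
  xs <- rep(seq_len(nx), ny); ys <- rep(seq_len(ny), each = nx)
  z <- as.vector(roi)
  off0 <- min(z); amp0 <- max(z) - off0
  if (amp0 <= 0) return(NULL)
  resid_fn <- function(par)
    z - (par[1] + par[2] *
           exp(-((xs - par[3])^2 + (ys - par[4])^2) / (2 * par[5]^2)))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(off0, amp0, (nx + 1) / 2, (ny + 1) / 2, 1.3),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
  cf <- fit$par
  sg <- abs(cf[5])
  if (!is.finite(sg) || sg <= 0 || sg > max(nx, ny) || cf[2] <= 0)
    return(NULL)
  if (cf[3] < 1 || cf[3] > nx || cf[4] < 1 || cf[4] > ny) return(NULL)
  res_sd <- sd(fit$fvec)
  list(cx = cf[3], cy = cf[4], sigma_px = sg,
       amp = cf[2],
       photons = 2 * pi * cf[2] * sg^2,
       signal = if (res_sd > 0) cf[2] / res_sd else Inf)
}

#' Detect and fit single-molecule peaks in a frame stack
#'
#' Per frame, candidate maxima above `detection_threshold` are fitted with
#' a 2D Gaussian by least squares. Photons are the integrated fitted
#' intensity `2 pi A sigma^2`; localization precision follows the
#' Thompson-style formula `sqrt((sigma_nm^2 + a^2/12) / N)` with `a` the
#' pixel size; signal strength is fitted amplitude over residual noise SD.
#' Diverged fits are dropped and counted in the `n_dropped` attribute.
#'
#' @param frames 3D array `[x, y, frame]` or a single matrix.
#' @param detection_threshold minimum candidate height above zero.
#' @param pixel_size_nm camera pixel size in nm.
#' @param roi_half_px half-size of the square fitting ROI.
#' @return a `localization_table`.
#' @export
fit_peaks <- function(frames, detection_threshold, pixel_size_nm = 107,
                      roi_half_px = 4) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  nf <- dim(frames)[3]
  a <- pixel_size_nm
  rows <- list()
  n_dropped <- 0L
  for (f in seq_len(nf)) {
    img <- frames[, , f]
    peaks <- find_spot_maxima(img, prominence = detection_threshold,
                              min_separation = roi_half_px)
    for (k in seq_len(nrow(peaks))) {
      x <- peaks$x_px[k]; y <- peaks$y_px[k]
      if (x - roi_half_px < 1 || x + roi_half_px > nrow(img) ||
          y - roi_half_px < 1 || y + roi_half_px > ncol(img)) next
      roi <- img[(x - roi_half_px):(x + roi_half_px),
                 (y - roi_half_px):(y + roi_half_px)]
      ft <- fit_one_peak(roi, x, y)
      if (is.null(ft)) { n_dropped <- n_dropped + 1L; next }
      # ROI-local continuous position -> global pixel index -> nm
      gx <- x - roi_half_px - 1 + ft$cx
      gy <- y - roi_half_px - 1 + ft$cy
      sigma_nm <- ft$sigma_px * a
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, x_nm = (gx - 0.5) * a, y_nm = (gy - 0.5) * a,
        photons = ft$photons, signal = ft$signal,
        precision_nm = sqrt((sigma_nm^2 + a^2 / 12) / ft$photons))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(frame = integer(), x_nm = numeric(),
                        y_nm = numeric(), photons = numeric(),
                        signal = numeric(), precision_nm = numeric())
  tab <- localization_table(df, pixel_size_nm = a, n_frames = nf)
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Quality-filter a localization table
#'
#' Keeps rows with `signal >= min_signal`, `photons >= min_photons` and
#' `precision_nm <= max_precision_nm` (all thresholds inclusive; the study
#' settings are 20, 50 and 40 nm). Row order is preserved and the filter
#' is idempotent.
#'
#' @param table a `localization_table`.
#' @param min_signal,min_photons,max_precision_nm thresholds.
#' @return filtered `localization_table`.
#' @export
filter_localizations <- function(table, min_signal = 20, min_photons = 50,
                                 max_precision_nm = 40) {
  keep <- table$signal >= min_signal & table$photons >= min_photons &
    table$precision_nm <= max_precision_nm
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  localization_table(out, pixel_size_nm = attr(table, "pixel_size_nm"),
                     n_frames = attr(table, "n_frames"))
}

#' DBSCAN clustering of localizations
#'
#' Standard DBSCAN on `(x_nm, y_nm)` with Euclidean metric; under the
#' study defaults a cluster needs at least 5 localizations within a 40 nm
#' neighbourhood. Border points join the first-discovered core cluster
#' under deterministic row-order traversal; noise is discarded.
#'
#' @param table a `localization_table` (or data.frame with `x_nm`,
#'   `y_nm`).
#' @param eps_nm clustering distance.
#' @param min_pts minimum localizations for a core point.
#' @return list with `clusters` (per-cluster `cluster_id`, `n_locs`,
#'   `centroid_x_nm`, `centroid_y_nm`, `diameter_nm`) and `membership`
#'   (per-row cluster id, 0 = noise).
#' @export
dbscan_cluster <- function(table, eps_nm = 40, min_pts = 5) {
  n <- nrow(table)
  if (n == 0)
    return(list(clusters = data.frame(cluster_id = integer(),
                                      n_locs = integer(),
                                      centroid_x_nm = numeric(),
                                      centroid_y_nm = numeric(),
                                      diameter_nm = numeric()),
                membership = integer(0)))
  cl <- cpp_dbscan(table$x_nm, table$y_nm, eps_nm, as.integer(min_pts))
  ids <- sort(unique(cl[cl > 0]))
  clusters <- do.call(rbind, lapply(ids, function(id) {
    sel <- cl == id
    geo <- cluster_geometry(table$x_nm[sel], table$y_nm[sel])
    data.frame(cluster_id = id, n_locs = sum(sel),
               centroid_x_nm = geo$centroid[1],
               centroid_y_nm = geo$centroid[2],
               diameter_nm = geo$diameter_nm)
  }))
  if (is.null(clusters))
    clusters <- data.frame(cluster_id = integer(), n_locs = integer(),
                           centroid_x_nm = numeric(),
                           centroid_y_nm = numeric(),
                           diameter_nm = numeric())
  list(clusters = clusters, membership = cl)
}

#' Geometry of one localization cluster
#'
#' Diameter is the maximum pairwise member distance; the centroid is the
#' member mean. Both are translation- and rotation-invariant.
#'
#' @param x_nm,y_nm member coordinates.
#' @return list with `diameter_nm` and `centroid` (length-2 vector).
#' @export
cluster_geometry <- function(x_nm, y_nm) {
  if (length(x_nm) == 0) stop("empty cluster", call. = FALSE)
  d <- if (length(x_nm) > 1) max(dist(cbind(x_nm, y_nm))) else 0
  list(diameter_nm = d, centroid = c(mean(x_nm), mean(y_nm)))
}

#' Associate SMLM clusters with segmented terminals
#'
#' A cluster is assigned to the terminal whose foreground contains its
#' centroid (nm mapped to the mask grid by floor division).
#'
#' @param clusters cluster table from [dbscan_cluster()].
#' @param terminal_mask a `labeled_mask` of one terminal channel.
#' @return list with `clusters` (input plus `terminal_label`, 0 = none)
#'   and `terminals` (per-terminal `label`, `contains`, `n_clusters`).
#' @export
associate_clusters_with_synapses <- function(clusters, terminal_mask) {
  if (!inherits(terminal_mask, "labeled_mask"))
    stop("`terminal_mask` must be a labeled_mask", call. = FALSE)
  ps <- rep_len(terminal_mask$pixel_size_nm, 2)
  dims <- dim(terminal_mask$labels)
  n <- nrow(clusters)
  lab <- integer(n)
  if (n > 0) {
    ix <- nm_to_px(clusters$centroid_x_nm, ps[1])
    iy <- nm_to_px(clusters$centroid_y_nm, ps[2])
    inside <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2]
    lab[inside] <- terminal_mask$labels[cbind(ix[inside], iy[inside])]
  }
  nt <- nrow(terminal_mask$objects)
  counts <- tabulate(lab[lab > 0], nt)
  clusters$terminal_label <- lab
  list(clusters = clusters,
       terminals = data.frame(label = terminal_mask$objects$label,
                              contains = counts > 0, n_clusters = counts))
}

# ring-averaged Fourier correlation of two images of identical size
frc_curve <- function(h1, h2) {
  f1 <- fft(h1); f2 <- fft(h2)
  n <- nrow(h1)
  # integer frequency indices, centered (fftshift layout avoided by
  # wrapping indices)
  ix <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  kx <- matrix(ix, n, n)
  ky <- matrix(ix, n, n, byrow = TRUE)
  ring <- floor(sqrt(kx^2 + ky^2)) + 1L
  num <- Re(f1 * Conj(f2))
  d1 <- Mod(f1)^2; d2 <- Mod(f2)^2
  rmax <- n %/% 2
  sel <- ring <= rmax
  r <- ring[sel]
  corr <- as.numeric(tapply(num[sel], r, sum)) /
    sqrt(as.numeric(tapply(d1[sel], r, sum)) *
         as.numeric(tapply(d2[sel], r, sum)))
  corr
}

#' Fourier ring correlation resolution of a localization data set
#'
#' Splits localizations into odd- and even-frame halves, renders each half
#' as a 2D histogram at `render_pixel_nm`, computes the ring-wise Fourier
#' correlation, smooths it with a running mean, and returns the inverse of
#' the spatial frequency at the first crossing of the fixed 1/7 threshold.
#'
#' @param table a `localization_table` with >= 2 rows.
#' @param render_pixel_nm super-resolution rendering pixel (default 10).
#' @param smooth_k running-mean window (rings).
#' @return `frc_result`: list with `resolution_nm` (`NA` when the curve
#'   never drops below 1/7 - the unresolved sentinel), `unresolved`, and
#'   the smoothed `curve` (data.frame `freq_per_nm`, `frc`).
#' @export
frc_resolution <- function(table, render_pixel_nm = 10, smooth_k = 7) {
  if (nrow(table) < 2) stop("need at least 2 localizations", call. = FALSE)
  odd <- table[table$frame %% 2 == 1, , drop = FALSE]
  even <- table[table$frame %% 2 == 0, , drop = FALSE]
  if (nrow(odd) == 0 || nrow(even) == 0)
    stop("odd/even split left one half empty", call. = FALSE)
  x0 <- min(table$x_nm); y0 <- min(table$y_nm)
  ext <- max(max(table$x_nm) - x0, max(table$y_nm) - y0) + render_pixel_nm
  n <- 2^ceiling(log2(ext / render_pixel_nm))
  n <- max(n, 64L)
  bin2d <- function(d) {
    ix <- pmin(floor((d$x_nm - x0) / render_pixel_nm) + 1L, n)
    iy <- pmin(floor((d$y_nm - y0) / render_pixel_nm) + 1L, n)
    matrix(tabulate(ix + (iy - 1L) * n, nbins = n * n), n, n)
  }
  corr <- frc_curve(bin2d(odd), bin2d(even))
  corr <- corr[-1]                      # drop the DC ring
  sm <- as.numeric(stats::filter(corr, rep(1 / smooth_k, smooth_k),
                                 sides = 2))
  sm[is.na(sm)] <- corr[is.na(sm)]
  freq <- seq_along(sm) / (n * render_pixel_nm)  # cycles per nm
  below <- which(sm < 1 / 7)
  if (length(below) == 0) {
    res <- structure(list(resolution_nm = NA_real_, unresolved = TRUE,
                          curve = data.frame(freq_per_nm = freq,
                                             frc = as.numeric(sm))),
                     class = "frc_result")
    return(res)
  }
  i <- below[1]
  # linear interpolation between the bracketing rings
  if (i == 1) fcross <- freq[1]
  else {
    f0 <- freq[i - 1]; f1 <- freq[i]
    c0 <- sm[i - 1]; c1 <- sm[i]
    fcross <- f0 + (c0 - 1 / 7) / (c0 - c1) * (f1 - f0)
  }
  structure(list(resolution_nm = 1 / fcross, unresolved = FALSE,
                 curve = data.frame(freq_per_nm = freq,
                                    frc = as.numeric(sm))),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  if (x$unresolved) cat("FRC: unresolved (correlation never crosses 1/7)\n")
  else cat(sprintf("FRC resolution: %.1f nm\n", x$resolution_nm))
  invisible(x)
}
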