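#' Find local intensity maxima in an image channel
#'
#' Candidate maxima are pixels not exceeded by any 8-neighbour; a candidate
#' is kept when its height exceeds the minimum of its local window (side
#' `2 * min_separation + 1`) by at least `prominence`, and accepted maxima
#' are separated by at least `min_separation` pixels. Nearby candidates are
#' merged to the brighter one, with ties broken towards the lower (row,
#' col) position.
#'
#' @param image `rendered_image` or numeric matrix.
#' @param prominence minimum height above the local background.
#' @param min_separation minimum distance between reported maxima (px).
#' @return data.frame with `x_px`, `y_px`, `value`.
#' @export
find_spot_maxima <- function(image, prominence, min_separation = 5) {
  if (!is.numeric(prominence) || prominence < 0)
    stop("`prominence` must be >= 0", call. = FALSE)
  img <- as_pixel_matrix(image)
  nx <- nrow(img); ny <- ncol(img)
  out <- data.frame(x_px = integer(), y_px = integer(), value = numeric())
  if (nx < 3 || ny < 3) return(out)

  inner <- img[2:(nx - 1), 2:(ny - 1)]
  nb_max <- pmax(img[1:(nx - 2), 1:(ny - 2)], img[1:(nx - 2), 2:(ny - 1)],
                 img[1:(nx - 2), 3:ny],       img[2:(nx - 1), 1:(ny - 2)],
                 img[2:(nx - 1), 3:ny],       img[3:nx, 1:(ny - 2)],
                 img[3:nx, 2:(ny - 1)],       img[3:nx, 3:ny])
  cand <- which(inner >= nb_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(out)
  cx <- cand[, 1] + 1L; cy <- cand[, 2] + 1L
  val <- img[cbind(cx, cy)]

  # prominence: height over the local window minimum
  if (prominence > 0) {
    w <- as.integer(max(1, min_separation))
    keep <- logical(length(cx))
    for (k in seq_along(cx)) {
      i0 <- max(1L, cx[k] - w); i1 <- min(nx, cx[k] + w)
      j0 <- max(1L, cy[k] - w); j1 <- min(ny, cy[k] + w)
      keep[k] <- (val[k] - min(img[i0:i1, j0:j1])) >= prominence
    }
    cx <- cx[keep]; cy <- cy[keep]; val <- val[keep]
  }
  if (length(cx) == 0) return(out)

  # greedy non-maximum suppression, brighter first, ties to lower (row, col)
  o <- order(-val, cx, cy)
  cx <- cx[o]; cy <- cy[o]; val <- val[o]
  sel <- integer(0)
  for (k in seq_along(cx)) {
    if (length(sel) == 0 ||
        all((cx[k] - cx[sel])^2 + (cy[k] - cy[sel])^2 >= min_separation^2))
      sel <- c(sel, k)
  }
  data.frame(x_px = cx[sel], y_px = cy[sel], value = val[sel])
}

#' Fit a 1D Gaussian to a line profile
#'
#' Least-squares fit of the four-parameter model
#' `offset + amplitude * exp(-(p - center)^2 / (2 sigma^2))` via
#' Levenberg-Marquardt. Non-convergence or a degenerate sigma is reported
#' as a `fit_failure` flag rather than an error.
#'
#' @param samples data.frame with `position_nm` and `intensity` (>= 7 rows
#'   spanning the peak).
#' @param direction label stored on the result.
#' @return `line_profile_fit`: list with fitted parameters, `r_squared`,
#'   `fwhm_nm` and `failed`.
#' @export
fit_line_profile <- function(samples, direction = "horizontal") {
  if (!is.data.frame(samples) ||
      !all(c("position_nm", "intensity") %in% names(samples)))
    stop("`samples` needs columns position_nm and intensity", call. = FALSE)
  if (nrow(samples) < 7)
    stop("need at least 7 samples spanning the peak", call. = FALSE)
  p <- samples$position_nm; y <- samples$intensity

  fail <- function() {
    structure(list(direction = direction, samples = samples,
                   amplitude = NA_real_, center_nm = NA_real_,
                   sigma_nm = NA_real_, offset = NA_real_,
                   r_squared = 0, fwhm_nm = NA_real_, failed = TRUE),
              class = "line_profile_fit")
  }
  if (max(y) - min(y) <= 0) return(fail())

  off0 <- min(y); amp0 <- max(y) - off0
  w <- pmax(y - off0, 0)
  c0 <- sum(p * w) / sum(w)
  s0 <- sqrt(sum(w * (p - c0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(p)) / 6
  resid_fn <- function(par)
    y - (par[1] + par[2] * exp(-(p - par[3])^2 / (2 * par[4]^2)))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(off0, amp0, c0, s0), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail())
  cf <- fit$par
  sg <- abs(cf[4])
  if (!is.finite(sg) || sg <= 0 || cf[2] <= 0) return(fail())
  res <- fit$fvec
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  structure(list(direction = direction, samples = samples,
                 amplitude = cf[2],
                 center_nm = cf[3], sigma_nm = sg,
                 offset = cf[1],
                 r_squared = max(0, min(1, r2)),
                 fwhm_nm = FWHM_PER_SIGMA * sg, failed = FALSE),
            class = "line_profile_fit")
}

# extract the four line profiles (horizontal, vertical, two diagonals)
# through a peak; diagonal sample spacing is sqrt(2) * pixel size
extract_profiles <- function(img, x, y, half, pixel_size_nm) {
  k <- -half:half
  dirs <- list(horizontal = c(1L, 0L), vertical = c(0L, 1L),
               diag_ne = c(1L, 1L), diag_nw = c(1L, -1L))
  lapply(names(dirs), function(d) {
    dd <- dirs[[d]]
    xi <- x + k * dd[1]; yi <- y + k * dd[2]
    spacing <- pixel_size_nm * sqrt(sum(dd^2))
    data.frame(direction = d, position_nm = k * spacing,
               intensity = img[cbind(xi, yi)], stringsAsFactors = FALSE)
  })
}

#' Measure the FWHM diameter of one spot by four line profiles
#'
#' Draws four line profiles (horizontal, vertical and both diagonals)
#' through the detected maximum, fits each with a Gaussian, and averages
#' the four FWHM values. A spot is accepted only when all four fits reach
#' the R-squared floor and the mean FWHM falls inside the expected size
#' window; otherwise the rejection reason is recorded.
#'
#' @param image `rendered_image` or matrix (pixel size then required).
#' @param peak_xy integer vector `c(x_px, y_px)`.
#' @param line_length_px profile length in pixels (odd; default 15).
#' @param r2_min per-profile R-squared floor (default 0.8).
#' @param fwhm_range_nm acceptance window for the mean FWHM.
#' @param pixel_size_nm required when `image` is a bare matrix.
#' @return `spot_measurement`: list with the four fits, `mean_fwhm_nm`,
#'   `accepted` and `rejection_reason` in
#'   `none/low_r2/out_of_range/fit_failure`.
#' @export
measure_spot_fwhm <- function(image, peak_xy, line_length_px = 15,
                              r2_min = 0.8, fwhm_range_nm = c(40, 800),
                              pixel_size_nm = NULL) {
  img <- as_pixel_matrix(image)
  ps <- if (is.null(pixel_size_nm)) image_pixel_size(image) else pixel_size_nm
  if (!is.finite(ps)) stop("pixel size is required", call. = FALSE)
  x <- as.integer(peak_xy[1]); y <- as.integer(peak_xy[2])
  if (x < 1 || x > nrow(img) || y < 1 || y > ncol(img))
    stop("peak lies outside the image", call. = FALSE)
  half <- floor(line_length_px / 2)
  out <- function(fits, mean_fwhm, accepted, reason) {
    structure(list(peak_xy = c(x_px = x, y_px = y), fits = fits,
                   mean_fwhm_nm = mean_fwhm, accepted = accepted,
                   rejection_reason = reason, pixel_size_nm = ps),
              class = "spot_measurement")
  }
  if (x - half < 1 || x + half > nrow(img) ||
      y - half < 1 || y + half > ncol(img))
    return(out(list(), NA_real_, FALSE, "out_of_range"))

  profs <- extract_profiles(img, x, y, half, ps)
  fits <- lapply(profs, function(pr)
    fit_line_profile(pr[c("position_nm", "intensity")], pr$direction[1]))
  if (any(vapply(fits, `[[`, TRUE, "failed")))
    return(out(fits, NA_real_, FALSE, "fit_failure"))
  fw <- vapply(fits, `[[`, 0, "fwhm_nm")
  r2 <- vapply(fits, `[[`, 0, "r_squared")
  mfw <- mean(fw)
  if (any(r2 < r2_min)) return(out(fits, mfw, FALSE, "low_r2"))
  if (mfw < fwhm_range_nm[1] || mfw > fwhm_range_nm[2])
    return(out(fits, mfw, FALSE, "out_of_range"))
  out(fits, mfw, TRUE, "none")
}

#' @export
print.spot_measurement <- function(x, ...) {
  cat(sprintf("spot at (%d, %d): mean FWHM %.1f nm, %s%s\n",
              x$peak_xy[1], x$peak_xy[2], x$mean_fwhm_nm,
              if (x$accepted) "accepted" else "rejected",
              if (x$accepted) "" else paste0(" (", x$rejection_reason, ")")))
  invisible(x)
}

#' Detect and measure all spots in a channel
#'
#' Convenience batch runner: [find_spot_maxima()] followed by
#' [measure_spot_fwhm()] for each peak.
#'
#' @inheritParams measure_spot_fwhm
#' @inheritParams find_spot_maxima
#' @return data.frame with one row per spot:
#'   `spot_id,x_px,y_px,fwhm_nm,r2_min_of4,accepted,reason`.
#' @export
measure_spots <- function(image, prominence = 30, min_separation = 5,
                          line_length_px = 15, r2_min = 0.8,
                          fwhm_range_nm = c(40, 800), pixel_size_nm = NULL) {
  peaks <- find_spot_maxima(image, prominence, min_separation)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    m <- measure_spot_fwhm(image, c(peaks$x_px[i], peaks$y_px[i]),
                           line_length_px, r2_min, fwhm_range_nm,
                           pixel_size_nm)
    r2s <- if (length(m$fits)) vapply(m$fits, `[[`, 0, "r_squared") else NA
    data.frame(spot_id = i, x_px = peaks$x_px[i], y_px = peaks$y_px[i],
               fwhm_nm = m$mean_fwhm_nm, r2_min_of4 = min(r2s),
               accepted = m$accepted, reason = m$rejection_reason,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(spot_id = integer(), x_px = integer(),
                      y_px = integer(), fwhm_nm = numeric(),
                      r2_min_of4 = numeric(), accepted = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summary statistics of accepted spot diameters
#'
#' @param measurements result of [measure_spots()] (or a list of
#'   `spot_measurement` objects).
#' @param bin_width_nm histogram bin width.
#' @return list with `n`, `mean_nm`, `sd_nm`, `median_nm` and `histogram`
#'   (data.frame of bin mids and counts); an empty-summary sentinel with
#'   `n = 0` when nothing was accepted.
#' @export
summarize_diameters <- function(measurements, bin_width_nm = 20) {
  if (is.list(measurements) && !is.data.frame(measurements)) {
    fw <- vapply(measurements, function(m)
      if (isTRUE(m$accepted)) m$mean_fwhm_nm else NA_real_, 0)
  } else {
    fw <- ifelse(measurements$accepted, measurements$fwhm_nm, NA_real_)
  }
  fw <- fw[is.finite(fw)]
  if (length(fw) == 0)
    return(list(n = 0L, mean_nm = NA_real_, sd_nm = NA_real_,
                median_nm = NA_real_, histogram = NULL, empty = TRUE))
  breaks <- seq(floor(min(fw) / bin_width_nm) * bin_width_nm,
                ceiling(max(fw) / bin_width_nm) * bin_width_nm + bin_width_nm,
                by = bin_width_nm)
  h <- hist(fw, breaks = breaks, plot = FALSE)
  list(n = length(fw), mean_nm = mean(fw), sd_nm = sd(fw),
       median_nm = median(fw),
       histogram = data.frame(mid_nm = h$mids, count = h$counts),
       empty = FALSE)
}
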