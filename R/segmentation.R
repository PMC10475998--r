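#' Segmentation parameters for one channel
#'
#' Mirrors the macro-style processing chain: rolling-ball background
#' subtraction, Gaussian blur, thresholding and particle-size filtering.
#' The interactive manual threshold of the original workflow is replaced
#' by a deterministic rule: `threshold = "otsu"` (default) or a fixed
#' numeric value.
#'
#' @param background_radius_px rolling-ball radius (0 disables).
#' @param blur_sigma_px Gaussian blur sigma (0 disables).
#' @param threshold `"otsu"` or a fixed numeric intensity; pixels strictly
#'   above it are foreground.
#' @param min_area_px,max_area_px particle-size window in pixels.
#' @return `seg_params` object.
#' @export
seg_params <- function(background_radius_px = 25, blur_sigma_px = 1,
                       threshold = "otsu", min_area_px = 4,
                       max_area_px = Inf) {
  stop_if_not_scalar_pos(background_radius_px, "background_radius_px",
                         allow_zero = TRUE)
  stop_if_not_scalar_pos(blur_sigma_px, "blur_sigma_px", allow_zero = TRUE)
  if (!(identical(threshold, "otsu") ||
        (is.numeric(threshold) && length(threshold) == 1 &&
         is.finite(threshold))))
    stop('`threshold` must be "otsu" or a finite number', call. = FALSE)
  if (!is.numeric(min_area_px) || min_area_px < 0 ||
      !is.numeric(max_area_px) || max_area_px < min_area_px)
    stop("need 0 <= min_area_px <= max_area_px", call. = FALSE)
  structure(list(background_radius_px = background_radius_px,
                 blur_sigma_px = blur_sigma_px, threshold = threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px),
            class = "seg_params")
}

# block-minimum downsampling by integer factor s (pad with edge values)
shrink_min <- function(m, s) {
  nx <- nrow(m); ny <- ncol(m)
  nx2 <- ceiling(nx / s); ny2 <- ceiling(ny / s)
  pad <- m[c(seq_len(nx), rep(nx, nx2 * s - nx)),
           c(seq_len(ny), rep(ny, ny2 * s - ny)), drop = FALSE]
  # min over s x s blocks
  a <- array(pad, c(s, nx2, s, ny2))
  apply(a, c(2, 4), min)
}

# bilinear enlargement of `m` (block centers) back to nx x ny
enlarge_bilinear <- function(m, s, nx, ny) {
  xs <- (seq_len(nrow(m)) - 0.5) * s   # block centers in source px
  ys <- (seq_len(ncol(m)) - 0.5) * s
  tx <- pmin(pmax(seq_len(nx) - 0.5, xs[1]), xs[length(xs)])
  ty <- pmin(pmax(seq_len(ny) - 0.5, ys[1]), ys[length(ys)])
  rowi <- vapply(seq_len(ncol(m)), function(j)
    stats::approx(xs, m[, j], xout = tx)$y, numeric(nx))
  t(vapply(seq_len(nx), function(i)
    stats::approx(ys, rowi[i, ], xout = ty)$y, numeric(ny)))
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' non-flat spherical structuring element of the given radius (the rolling
#' ball) and subtracts it; output is clamped at zero. For radii above 16
#' pixels the image is first block-minimum downsampled, the ball rolled at
#' the reduced scale, and the background re-enlarged bilinearly - the
#' usual large-radius scheme, exact up to the smoothness of the true
#' background.
#'
#' @param image `rendered_image`, matrix, or 3D array (applied per plane).
#' @param radius_px ball radius in pixels.
#' @return same shape as the input.
#' @export
rolling_ball_subtract <- function(image, radius_px) {
  stop_if_not_scalar_pos(radius_px, "radius_px", allow_zero = TRUE)
  px <- as_pixel_matrix(image)
  sub1 <- function(m) {
    if (radius_px <= 0) return(m)
    if (radius_px > 16) {
      s <- max(2L, as.integer(floor(radius_px / 8)))
      sm <- shrink_min(m, s)
      bg_s <- cpp_rolling_ball_background(sm, radius_px / s)
      bg <- enlarge_bilinear(bg_s, s, nrow(m), ncol(m))
      bg <- pmin(bg, m)
    } else {
      bg <- cpp_rolling_ball_background(m, radius_px)
    }
    r <- m - bg
    r[r < 0] <- 0
    r
  }
  res <- if (length(dim(px)) == 3) {
    out <- px
    for (z in seq_len(dim(px)[3])) out[, , z] <- sub1(px[, , z])
    out
  } else sub1(px)
  if (inherits(image, "rendered_image")) { image$pixels <- res; image }
  else res
}

#' Preprocess one channel before thresholding
#'
#' Rolling-ball background subtraction followed by Gaussian blur; the
#' output is non-negative.
#'
#' @param image `rendered_image` or matrix.
#' @param params a [seg_params()] object.
#' @return same type as `image`.
#' @export
preprocess_channel <- function(image, params) {
  if (!inherits(params, "seg_params"))
    stop("`params` must be a seg_params object", call. = FALSE)
  img <- rolling_ball_subtract(image, params$background_radius_px)
  px <- as_pixel_matrix(img)
  px <- gauss_blur(px, params$blur_sigma_px)
  px[px < 0] <- 0
  if (inherits(image, "rendered_image")) { image$pixels <- px; image }
  else px
}

otsu_threshold <- function(px) {
  rng <- range(px)
  if (diff(rng) <= 0) return(rng[2])  # flat image: nothing above threshold
  EBImage::otsu(EBImage::Image(px), range = rng, levels = 256L)
}

#' Threshold a channel and label connected particles
#'
#' Binarizes strictly above the threshold, labels connected components
#' (4-connected in 2D, 6-connected in 3D), and discards particles outside
#' the `[min_area_px, max_area_px]` window.
#'
#' @param image preprocessed `rendered_image`, matrix, or 3D array.
#' @param params a [seg_params()] object.
#' @param pixel_size_nm pixel size when `image` is a bare matrix/array;
#'   may be length 2 (x, y) or 3 (x, y, z) in nm.
#' @return `labeled_mask`: list with `labels` (integer grid, 0 =
#'   background), `objects` (per-label area and centroid) and
#'   `pixel_size_nm`.
#' @export
threshold_and_label <- function(image, params, pixel_size_nm = NULL) {
  if (!inherits(params, "seg_params"))
    stop("`params` must be a seg_params object", call. = FALSE)
  px <- as_pixel_matrix(image)
  ps <- if (is.null(pixel_size_nm)) image_pixel_size(image) else pixel_size_nm
  if (any(!is.finite(ps))) stop("pixel size is required", call. = FALSE)
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(px)
         else params$threshold
  fg <- px > thr
  labeled_mask_from_fg(fg, ps, params$min_area_px, params$max_area_px,
                       threshold = thr)
}

# label a logical grid and build the object table
labeled_mask_from_fg <- function(fg, pixel_size_nm, min_area_px = 0,
                                 max_area_px = Inf, threshold = NA_real_) {
  dims <- dim(fg)
  lab <- cpp_label_components(as.logical(fg), as.integer(dims))
  dim(lab) <- dims
  area_px <- tabulate(lab)
  keep <- which(area_px >= min_area_px & area_px <= max_area_px)
  relab <- integer(length(area_px))
  relab[keep] <- seq_along(keep)
  nz <- lab > 0
  lab[nz] <- relab[lab[nz]]
  objs <- mask_object_table(lab, pixel_size_nm)
  structure(list(labels = lab, objects = objs,
                 pixel_size_nm = pixel_size_nm, threshold = threshold),
            class = "labeled_mask")
}

mask_object_table <- function(lab, pixel_size_nm) {
  n <- max(lab, 0L)
  ps <- rep_len(pixel_size_nm, max(2L, length(dim(lab))))
  px_area_um2 <- ps[1] * ps[2] / 1e6
  if (n == 0)
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_x_px = numeric(),
                      centroid_y_px = numeric(), centroid_z_px = numeric()))
  idx <- which(lab > 0)
  lv <- lab[idx]
  dims <- dim(lab)
  x <- ((idx - 1L) %% dims[1]) + 1L
  rest <- (idx - 1L) %/% dims[1]
  y <- (rest %% dims[2]) + 1L
  z <- if (length(dims) == 3) (rest %/% dims[2]) + 1L else rep(1L, length(idx))
  cnt <- tabulate(lv, n)
  data.frame(label = seq_len(n), area_px = cnt,
             area_um2 = cnt * px_area_um2,
             centroid_x_px = as.numeric(tapply(x, lv, mean)),
             centroid_y_px = as.numeric(tapply(y, lv, mean)),
             centroid_z_px = as.numeric(tapply(z, lv, mean)))
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("labeled_mask: %s px, %d objects\n",
              paste(dim(x$labels), collapse = " x "), nrow(x$objects)))
  invisible(x)
}
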