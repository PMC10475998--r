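# internal helpers shared across modules

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0)
  if (!ok) stop(sprintf("`%s` must be a finite %s number", name,
                        if (allow_zero) "non-negative" else "positive"),
                call. = FALSE)
  invisible(x)
}

#' Gaussian blur of a 2D intensity grid
#'
#' Thin wrapper around [EBImage::gblur()] operating on plain matrices; a
#' sigma of zero is the identity. Used both for the rendering PSF and the
#' segmentation blur step.
#'
#' @param mat numeric matrix.
#' @param sigma_px Gaussian sigma in pixels.
#' @return blurred matrix of the same dimensions.
#' @keywords internal
gauss_blur <- function(mat, sigma_px) {
  if (sigma_px <= 1e-8) return(mat)
  EBImage::gblur(mat, sigma = sigma_px)
}

# nm -> 1-based pixel index by floor division; pixel i covers
# [(i-1)*ps, i*ps) and has its center at (i - 0.5)*ps.
nm_to_px <- function(x_nm, pixel_size_nm) {
  pmax(1L, as.integer(floor(x_nm / pixel_size_nm)) + 1L)
}

px_center_nm <- function(i_px, pixel_size_nm) (i_px - 0.5) * pixel_size_nm

# draws from a normal truncated below at `lower` (rejection; vectorised)
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= lower)
    guard <- guard + 1L
  }
  if (length(bad) > 0) x[bad] <- lower + abs(x[bad] - lower) * 0 + lower * 0.01
  x
}

# radius of an ellipse boundary (semi-axes a, b, orientation theta) along
# absolute direction phi, measured from the center
ellipse_radius <- function(a, b, theta, phi) {
  psi <- phi - theta
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# TRUE when point (x, y) lies inside the ellipse
inside_ellipse <- function(x, y, cx, cy, a, b, theta) {
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}
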