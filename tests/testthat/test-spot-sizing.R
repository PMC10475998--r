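test_that("maxima detection handles single, double and flat fields", {
  img <- spot_image(n = 41, sigma_px = 2)
  pk <- find_spot_maxima(img, prominence = 10)
  expect_identical(nrow(pk), 1L)
  expect_lte(max(abs(c(pk$x_px, pk$y_px) - 21)), 1)

  img2 <- matrix(10, 61, 61)
  g1 <- exp(-((seq_len(61) - 21)^2) / 8); g2 <- exp(-((seq_len(61) - 41)^2) / 8)
  img2 <- img2 + 100 * outer(g1, g1) + 100 * outer(g2, g2)
  pk2 <- find_spot_maxima(img2, prominence = 10, min_separation = 5)
  expect_identical(nrow(pk2), 2L)

  flat <- matrix(7, 50, 50)
  expect_identical(nrow(find_spot_maxima(flat, prominence = 0.001)), 0L)
})

test_that("noiseless Gaussian profile recovers the analytic FWHM", {
  # sigma = 2 px at 35 nm: FWHM = 2.3548 * 70 nm = 164.8 nm, R^2 = 1
  pos <- (-10:10) * 35
  y <- 5 + 80 * exp(-pos^2 / (2 * 70^2))
  fit <- fit_line_profile(data.frame(position_nm = pos, intensity = y))
  expect_false(fit$failed)
  expect_equal(fit$fwhm_nm, 2 * sqrt(2 * log(2)) * 70, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_equal(fit$fwhm_nm, 164.8, tolerance = 1e-3)
})

test_that("fit agrees with a brute-force grid-search oracle under noise", {
  set.seed(42)
  pos <- (-10:10) * 35
  truth <- c(amp = 100, ctr = 10, sg = 80, off = 20)
  y <- truth["off"] + truth["amp"] * exp(-(pos - truth["ctr"])^2 /
                                           (2 * truth["sg"]^2)) +
    rnorm(length(pos), 0, 10)  # SNR 10
  fit <- fit_line_profile(data.frame(position_nm = pos, intensity = y))
  oracle <- grid_gauss_fit(pos, y, c(80, 120), c(-20, 40), c(60, 100),
                           c(10, 30), n_grid = 41)
  expect_false(fit$failed)
  expect_lt(abs(fit$amplitude - oracle["amplitude"]) / oracle["amplitude"],
            0.02)
  expect_lt(abs(fit$sigma_nm - oracle["sigma"]) / oracle["sigma"], 0.02)
})

test_that("flat or degenerate profiles are flagged as failures", {
  pos <- (-5:5) * 35
  flat <- fit_line_profile(data.frame(position_nm = pos,
                                      intensity = rep(3, 11)))
  expect_true(flat$failed || flat$r_squared < 0.2)
  expect_error(fit_line_profile(data.frame(position_nm = 1:3,
                                           intensity = 1:3)), "7 samples")
})

test_that("isotropic spot measurement matches 2.3548 sigma within 3%", {
  img <- spot_image(n = 41, sigma_px = 2, amp = 150, offset = 5)
  m <- measure_spot_fwhm(img, c(21, 21), pixel_size_nm = 35)
  expect_true(m$accepted)
  expected <- 2 * sqrt(2 * log(2)) * 2 * 35
  expect_lt(abs(m$mean_fwhm_nm - expected) / expected, 0.03)
  expect_length(m$fits, 4L)
  # per-fit identity fwhm = 2.3548 sigma holds exactly
  for (f in m$fits)
    expect_equal(f$fwhm_nm, 2 * sqrt(2 * log(2)) * f$sigma_nm,
                 tolerance = 1e-9)
})

test_that("anisotropic spot FWHM equals the half-max crossing oracle", {
  n <- 61; sx <- 2; sy <- 4; ps <- 35
  gx <- exp(-((seq_len(n) - 31)^2) / (2 * sx^2))
  gy <- exp(-((seq_len(n) - 31)^2) / (2 * sy^2))
  img <- 10 + 200 * outer(gx, gy)
  m <- measure_spot_fwhm(img, c(31, 31), line_length_px = 31,
                         pixel_size_nm = ps, fwhm_range_nm = c(40, 2000))
  # oracle: dense half-max crossing on each of the four directions
  k <- -15:15
  prof <- list(h = img[31 + k, 31], v = img[31, 31 + k],
               d1 = img[cbind(31 + k, 31 + k)],
               d2 = img[cbind(31 + k, 31 - k)])
  spacing <- c(ps, ps, ps * sqrt(2), ps * sqrt(2))
  oracle <- mean(vapply(seq_along(prof), function(i)
    half_max_width(k * spacing[i], prof[[i]]), 0))
  expect_lt(abs(m$mean_fwhm_nm - oracle) / oracle, 0.05)
})

test_that("a corrupted profile triggers the R-squared exclusion rule", {
  img <- spot_image(n = 41, sigma_px = 2, amp = 150, offset = 5)
  # sawtooth corruption of one diagonal destroys its fit quality
  for (k in -10:10) img[21 + k, 21 + k] <- if (k %% 2 == 0) 60 else 5
  img[21, 21] <- 155  # keep the central maximum intact
  m <- measure_spot_fwhm(img, c(21, 21), pixel_size_nm = 35)
  expect_false(m$accepted)
  expect_true(m$rejection_reason %in% c("low_r2", "fit_failure"))
})

test_that("peaks too close to the border are rejected out of range", {
  img <- spot_image(n = 41, sigma_px = 2)
  m <- measure_spot_fwhm(img, c(3, 21), pixel_size_nm = 35)
  expect_false(m$accepted)
  expect_identical(m$rejection_reason, "out_of_range")
  expect_error(measure_spot_fwhm(img, c(100, 21), pixel_size_nm = 35),
               "outside")
})

test_that("diameter summaries cover accepted measurements only", {
  df <- data.frame(spot_id = 1:4, x_px = 1, y_px = 1,
                   fwhm_nm = c(100, 200, 300, 9999),
                   r2_min_of4 = c(0.9, 0.9, 0.9, 0.1),
                   accepted = c(TRUE, TRUE, TRUE, FALSE),
                   reason = c("none", "none", "none", "low_r2"))
  s <- summarize_diameters(df)
  expect_identical(s$n, 3L)
  expect_equal(s$mean_nm, 200)
  expect_equal(s$median_nm, 200)
  empty <- summarize_diameters(df[df$accepted == FALSE, ])
  expect_identical(empty$n, 0L)
  expect_true(empty$empty)
})

test_that("population mean under a g-STED-like PSF follows convolution law", {
  # many spots of true FWHM 140 nm blurred by a 90 nm PSF
  set.seed(11)
  ps <- 20; n <- 41
  sigma_eff_px <- sqrt(140^2 + 90^2) / (2 * sqrt(2 * log(2))) / ps
  fw <- replicate(60, {
    img <- spot_image(n = n, sigma_px = sigma_eff_px, amp = 300, offset = 20)
    img <- matrix(rpois(n * n, img), n, n)
    m <- measure_spot_fwhm(img, c(21, 21), pixel_size_nm = ps)
    if (m$accepted) m$mean_fwhm_nm else NA_real_
  })
  fw <- fw[is.finite(fw)]
  expect_gte(length(fw), 40)
  expect_lt(abs(mean(fw) - sqrt(140^2 + 90^2)) / sqrt(140^2 + 90^2), 0.10)
})
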