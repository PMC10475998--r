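make_table <- function(df, ...) localization_table(df, ...)

test_that("frame background subtraction flattens constants and limits", {
  fr <- array(25, c(30, 30, 2))
  out <- subtract_background_frames(fr, 12)
  expect_lt(max(abs(out)), 1e-9)
  # radius much larger than the frame approaches global-min subtraction
  img <- matrix(c(rep(10, 50), rep(30, 50)), 10, 10)
  out2 <- rolling_ball_subtract(img, 9)
  expect_lt(max(abs((img - 10) - out2)), 21)
})

test_that("background subtraction raises peak-to-background contrast", {
  n <- 41
  slope <- outer(seq_len(n), seq_len(n), function(i, j) 10 + 0.8 * i)
  g <- exp(-((seq_len(n) - 21)^2) / (2 * 1.5^2))
  spot <- 60 * outer(g, g)
  raw <- slope + spot
  sub <- rolling_ball_subtract(raw, 12)
  contrast <- function(m) m[21, 21] / mean(m[1:6, 1:6])
  expect_gt(contrast(sub + 1e-6), contrast(raw))
})

test_that("a noiseless emitter is recovered to sub-pixel accuracy", {
  n <- 21; ps <- 107
  x0 <- 10.3; y0 <- 11.6; sg <- 1.3; amp <- 200
  img <- 5 + amp * outer(exp(-((seq_len(n) - x0)^2) / (2 * sg^2)),
                         exp(-((seq_len(n) - y0)^2) / (2 * sg^2)))
  tab <- fit_peaks(img, detection_threshold = 50, pixel_size_nm = ps)
  expect_identical(nrow(tab), 1L)
  expect_lt(abs(tab$x_nm - (x0 - 0.5) * ps), 0.05 * ps)
  expect_lt(abs(tab$y_nm - (y0 - 0.5) * ps), 0.05 * ps)
  injected <- 2 * pi * amp * sg^2
  expect_lt(abs(tab$photons - injected) / injected, 0.02)
})

test_that("empty frames produce no localizations", {
  tab <- fit_peaks(matrix(3, 30, 30), detection_threshold = 10)
  expect_identical(nrow(tab), 0L)
})

test_that("Monte-Carlo localization error matches the precision formula", {
  set.seed(21)
  n <- 15; ps <- 107; sg <- 1.3; amp <- 60; x0 <- 8.2; y0 <- 7.7
  clean <- 10 + amp * outer(exp(-((seq_len(n) - x0)^2) / (2 * sg^2)),
                            exp(-((seq_len(n) - y0)^2) / (2 * sg^2)))
  errs <- c(); preds <- c()
  for (r in 1:100) {
    img <- matrix(rpois(n * n, clean), n, n) - 10
    tab <- fit_peaks(img, detection_threshold = 20, pixel_size_nm = ps)
    if (nrow(tab) != 1) next
    errs <- c(errs, sqrt((tab$x_nm - (x0 - 0.5) * ps)^2 +
                           (tab$y_nm - (y0 - 0.5) * ps)^2))
    preds <- c(preds, tab$precision_nm)
  }
  expect_gte(length(errs), 80)
  rmse_1d <- sqrt(mean(errs^2) / 2)
  expect_lt(rmse_1d, 2 * mean(preds))
})

test_that("localization filters are inclusive at the exact thresholds", {
  df <- data.frame(frame = 1:4, x_nm = 0, y_nm = 0,
                   photons = c(49, 50, 500, 500),
                   signal = c(25, 20, 19.9, 20),
                   precision_nm = c(30, 40, 30, 40.01))
  tab <- make_table(df)
  out <- filter_localizations(tab)
  # row 1 fails photons, row 3 fails signal, row 4 fails precision
  expect_identical(out$frame, 2L)
})

test_that("filtering equals the row predicate oracle and is idempotent", {
  set.seed(31)
  df <- data.frame(frame = 1:500, x_nm = runif(500, 0, 1e4),
                   y_nm = runif(500, 0, 1e4),
                   photons = rlnorm(500, log(80), 1),
                   signal = runif(500, 0, 60),
                   precision_nm = runif(500, 1, 80))
  tab <- make_table(df)
  out <- filter_localizations(tab)
  keep <- df$signal >= 20 & df$photons >= 50 & df$precision_nm <= 40
  expect_identical(nrow(out), sum(keep))
  expect_equal(out$x_nm, df$x_nm[keep])
  twice <- filter_localizations(out)
  expect_equal(as.data.frame(twice), as.data.frame(out))
})

test_that("DBSCAN minimal-core behaviour at min_pts", {
  ring <- function(n, r) data.frame(
    frame = 1, x_nm = r * cos(2 * pi * seq_len(n) / n),
    y_nm = r * sin(2 * pi * seq_len(n) / n), photons = 100, signal = 30,
    precision_nm = 10)
  five <- make_table(ring(5, 15))   # all pairwise within 40 nm
  out5 <- dbscan_cluster(five, eps_nm = 40, min_pts = 5)
  expect_identical(nrow(out5$clusters), 1L)
  expect_identical(out5$clusters$n_locs, 5L)
  four <- make_table(ring(4, 15))
  out4 <- dbscan_cluster(four, eps_nm = 40, min_pts = 5)
  expect_identical(nrow(out4$clusters), 0L)
  empty <- dbscan_cluster(make_table(ring(5, 15)[0, ]))
  expect_identical(nrow(empty$clusters), 0L)
})

test_that("DBSCAN equals the brute-force oracle on random point sets", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(20:100, 1)
    df <- data.frame(frame = 1, x_nm = runif(n, 0, 600),
                     y_nm = runif(n, 0, 600), photons = 100, signal = 30,
                     precision_nm = 10)
    got <- dbscan_cluster(make_table(df), eps_nm = 40, min_pts = 5)
    oracle <- brute_dbscan(df$x_nm, df$y_nm, 40, 5)
    expect_true(same_partition(got$membership, oracle))
  }
})

test_that("core-point membership is invariant to row order", {
  set.seed(43)
  n <- 80
  df <- data.frame(frame = 1, x_nm = runif(n, 0, 500),
                   y_nm = runif(n, 0, 500), photons = 100, signal = 30,
                   precision_nm = 10)
  base <- dbscan_cluster(make_table(df), 40, 5)$membership
  perm <- sample(n)
  permuted <- dbscan_cluster(make_table(df[perm, ]), 40, 5)$membership
  # core points: >= min_pts neighbours within eps (self included)
  iscore <- vapply(seq_len(n), function(i)
    sum((df$x_nm - df$x_nm[i])^2 + (df$y_nm - df$y_nm[i])^2 <= 40^2) >= 5,
    TRUE)
  back <- integer(n); back[perm] <- permuted
  core_sets <- function(memb) {
    lapply(split(which(iscore & memb > 0), memb[iscore & memb > 0]), sort)
  }
  expect_identical(unname(core_sets(base)), unname(core_sets(back)))
})

test_that("cluster geometry: diameter and invariances", {
  expect_equal(cluster_geometry(rep(5, 5), rep(7, 5))$diameter_nm, 0)
  g <- cluster_geometry(c(0, 100, 50, 50, 50), c(0, 0, 0, 0, 0))
  expect_equal(g$diameter_nm, 100)
  set.seed(47)
  x <- rnorm(20, 0, 30); y <- rnorm(20, 0, 30)
  d0 <- cluster_geometry(x, y)$diameter_nm
  expect_equal(d0, max(dist(cbind(x, y))))
  th <- 0.7
  xr <- x * cos(th) - y * sin(th) + 500
  yr <- x * sin(th) + y * cos(th) - 250
  expect_equal(cluster_geometry(xr, yr)$diameter_nm, d0, tolerance = 1e-9)
})

test_that("cluster-terminal association follows the centroid rule", {
  fg <- matrix(FALSE, 20, 20)
  fg[5:10, 5:10] <- TRUE
  mask <- mask_from(fg, pixel_size_nm = 100)
  cl <- data.frame(cluster_id = 1:2, n_locs = 5,
                   centroid_x_nm = c(750, 1500), centroid_y_nm = c(750, 1500),
                   diameter_nm = 50)
  out <- associate_clusters_with_synapses(cl, mask)
  expect_identical(out$clusters$terminal_label, c(1L, 0L))
  expect_true(out$terminals$contains[1])
  expect_identical(out$terminals$n_clusters[1], 1L)
})

test_that("identical halves leave the FRC unresolved", {
  set.seed(51)
  n <- 400
  df <- data.frame(frame = rep(1:2, each = n),
                   x_nm = rep(runif(n, 0, 3000), 2),
                   y_nm = rep(runif(n, 0, 3000), 2),
                   photons = 100, signal = 30, precision_nm = 10)
  fr <- frc_resolution(make_table(df))
  expect_true(fr$unresolved)
  expect_true(is.na(fr$resolution_nm))
})

test_that("doubling the localization error scales the FRC resolution", {
  res <- vapply(c(10, 20), function(prec) {
    sp <- scene_params(field_size_um = 8, density_vglut2 = 16,
                       cluster_diameter_nm = c(5, 0.5), seed = 3)
    sc <- generate_scene(sp)
    st <- simulate_localization_events(sc, 2000, 0.03, prec, seed = 4)
    fr <- frc_resolution(filter_localizations(events_to_localizations(st)))
    fr$resolution_nm
  }, 0)
  ratio <- res[2] / res[1]
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
})

test_that("dense 20 nm-precision data resolves in the tens of nanometres", {
  sp <- scene_params(field_size_um = 8, density_vglut2 = 16,
                     cluster_diameter_nm = c(55, 12), seed = 13)
  sc <- generate_scene(sp)
  st <- simulate_localization_events(sc, 2000, 0.04, 20, seed = 14)
  fr <- frc_resolution(filter_localizations(events_to_localizations(st)))
  expect_false(fr$unresolved)
  # Monte-Carlo band for this configuration (55 nm objects, 20 nm error)
  expect_gt(fr$resolution_nm, 35)
  expect_lt(fr$resolution_nm, 80)
})
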