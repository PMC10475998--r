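# Independent oracle implementations used to cross-check the package.
# These deliberately use the most direct (brute-force) formulation.

# classic textbook DBSCAN, O(n^2), deterministic row-order traversal
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  lab <- integer(n)        # 0 = noise/unvisited
  visited <- logical(n)
  cur <- 0L
  nbrs <- function(i) which((x - x[i])^2 + (y - y[i])^2 <= eps^2)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- nbrs(i)
    if (length(nb) < min_pts) next
    cur <- cur + 1L
    lab[i] <- cur
    seeds <- nb
    k <- 1L
    while (k <= length(seeds)) {
      j <- seeds[k]; k <- k + 1L
      if (lab[j] == 0L) lab[j] <- cur
      if (!visited[j]) {
        visited[j] <- TRUE
        nb2 <- nbrs(j)
        if (length(nb2) >= min_pts) seeds <- c(seeds, nb2)
      }
    }
  }
  lab
}

# stack-based flood fill labeling, 4-connectivity
flood_fill_label <- function(fg) {
  nx <- nrow(fg); ny <- ncol(fg)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!fg[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nx && q[2] >= 1 && q[2] <= ny &&
            fg[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# two labelings agree up to renaming when their co-occurrence is bijective
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  fg <- a > 0 | b > 0
  if (!identical(a > 0, b > 0)) return(FALSE)
  tab <- table(a[fg], b[fg])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# dense numeric half-max crossing width of a profile (positions, values)
half_max_width <- function(pos, val) {
  offset <- min(val)
  half <- offset + (max(val) - offset) / 2
  f <- stats::approxfun(pos, val)
  xs <- seq(min(pos), max(pos), length.out = 20001)
  ys <- f(xs)
  above <- which(ys >= half)
  xs[max(above)] - xs[min(above)]
}

# brute-force grid-search least-squares Gaussian fit with two local
# refinement passes around the best coarse cell
grid_gauss_fit <- function(pos, val, amp_rng, ctr_rng, sg_rng, off_rng,
                           n_grid = 21) {
  scan <- function(ar, cr, sr, or) {
    best <- NULL; best_ss <- Inf
    for (amp in seq(ar[1], ar[2], length.out = n_grid))
      for (ctr in seq(cr[1], cr[2], length.out = n_grid))
        for (sg in seq(sr[1], sr[2], length.out = n_grid))
          for (off in seq(or[1], or[2], length.out = 9)) {
            ss <- sum((val - off - amp * exp(-(pos - ctr)^2 / (2 * sg^2)))^2)
            if (ss < best_ss) { best_ss <- ss; best <- c(amp, ctr, sg, off) }
          }
    best
  }
  b <- scan(amp_rng, ctr_rng, sg_rng, off_rng)
  for (pass in 1:2) {
    shr <- function(center, rng) {
      w <- diff(rng) / 4
      c(center - w / 2, center + w / 2)
    }
    amp_rng <- shr(b[1], amp_rng); ctr_rng <- shr(b[2], ctr_rng)
    sg_rng <- shr(b[3], sg_rng); off_rng <- shr(b[4], off_rng)
    b <- scan(amp_rng, ctr_rng, sg_rng, off_rng)
  }
  names(b) <- c("amplitude", "center", "sigma", "offset")
  b
}

# render a single isotropic Gaussian spot (no noise) as a matrix
spot_image <- function(n = 41, sigma_px = 2, amp = 100, offset = 10,
                       center = (n + 1) / 2) {
  g <- exp(-((seq_len(n) - center)^2) / (2 * sigma_px^2))
  offset + amp * outer(g, g)
}

# a labeled_mask built directly from a logical matrix (test convenience)
mask_from <- function(fg, pixel_size_nm = 100) {
  synclust:::labeled_mask_from_fg(fg, pixel_size_nm)
}

# exact U-distribution via full enumeration of group assignments
enumerate_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, u_of)
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
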