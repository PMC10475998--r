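sq_mask <- function(n, ..., ps = 100) {
  fg <- matrix(FALSE, n, n)
  for (b in list(...)) fg[b[1]:b[2], b[3]:b[4]] <- TRUE
  mask_from(fg, ps)
}

test_that("disjoint masks show no colocalization", {
  a <- sq_mask(20, c(2, 4, 2, 4))
  b <- sq_mask(20, c(10, 12, 10, 12))
  cl <- colocalize_objects(a, b)
  expect_false(any(cl$colocalized))
})

test_that("a single shared pixel counts as colocalized", {
  a <- sq_mask(20, c(2, 5, 2, 5))
  b <- sq_mask(20, c(5, 8, 5, 8))  # shares exactly pixel (5, 5)
  cl <- colocalize_objects(a, b)
  expect_identical(cl$overlap_px, 1L)
  expect_true(cl$colocalized)
})

test_that("colocalization equals the exhaustive per-object scan", {
  set.seed(5)
  for (rep in 1:20) {
    fa <- matrix(runif(64 * 64) < 0.2, 64, 64)
    fb <- matrix(runif(64 * 64) < 0.2, 64, 64)
    a <- mask_from(fa); b <- mask_from(fb)
    got <- colocalize_objects(a, b)
    for (l in a$objects$label) {
      expected <- sum(a$labels == l & b$labels > 0)
      expect_identical(got$overlap_px[got$label == l], as.integer(expected))
    }
  }
})

test_that("masks on different grids are rejected", {
  expect_error(colocalize_objects(sq_mask(10, c(1, 2, 1, 2)),
                                  sq_mask(12, c(1, 2, 1, 2))), "grid")
})

test_that("VGLUT2 expression does not disqualify a VGLUT1 synapse", {
  # one structure positive for VGLUT1, VGLUT2 and PSD95 at once
  v1 <- sq_mask(20, c(5, 10, 5, 10))
  v2 <- sq_mask(20, c(5, 10, 5, 10))
  psd <- sq_mask(20, c(9, 12, 9, 12))
  rec <- classify_synapses(v1, v2, psd)
  expect_identical(sum(rec$subtype == "VGLUT1"), 1L)
  expect_identical(sum(rec$subtype == "VGLUT2"), 0L)
})

test_that("one pixel of VGLUT1 contact excludes a VGLUT2 synapse", {
  v2 <- sq_mask(20, c(5, 8, 5, 8))
  psd <- sq_mask(20, c(8, 10, 5, 8))
  v1_touch <- sq_mask(20, c(8, 10, 8, 10))  # shares pixel (8,8) with v2
  rec <- classify_synapses(v1_touch, v2, psd)
  expect_identical(sum(rec$subtype == "VGLUT2"), 0L)
  v1_far <- sq_mask(20, c(15, 18, 15, 18))
  rec2 <- classify_synapses(v1_far, v2, psd)
  expect_identical(sum(rec2$subtype == "VGLUT2"), 1L)
})

test_that("classification never assigns both subtypes to one structure", {
  set.seed(13)
  for (rep in 1:10) {
    v1 <- mask_from(matrix(runif(48 * 48) < 0.15, 48, 48))
    v2 <- mask_from(matrix(runif(48 * 48) < 0.15, 48, 48))
    psd <- mask_from(matrix(runif(48 * 48) < 0.15, 48, 48))
    rec <- classify_synapses(v1, v2, psd)
    # a VGLUT2 synapse must have zero VGLUT1 overlap by construction
    for (i in which(rec$subtype == "VGLUT2")) {
      lab <- rec$terminal_label[i]
      expect_identical(sum(v2$labels == lab & v1$labels > 0), 0L)
    }
    # PSD pairing: the paired PSD must be the max-overlap one
    for (i in seq_len(nrow(rec))) {
      tm <- if (rec$subtype[i] == "VGLUT1") v1 else v2
      sel <- tm$labels == rec$terminal_label[i] & psd$labels > 0
      if (any(sel)) {
        tab <- table(psd$labels[sel])
        best <- max(tab)
        winners <- as.integer(names(tab)[tab == best])
        expect_identical(rec$psd_label[i], min(winners))
      }
    }
  }
})

test_that("centroid rule assigns clusters on the boundary correctly", {
  term <- sq_mask(30, c(5, 14, 5, 14))
  inside <- sq_mask(30, c(7, 9, 7, 9))       # centroid (8,8) inside
  cc <- count_clusters_in_structures(term, inside)
  expect_identical(cc$structures$n_clusters, 1L)
  expect_true(cc$structures$contains)
  # straddling object whose centroid falls outside
  straddle <- sq_mask(30, c(12, 20, 7, 9))   # centroid x = 16 > 14
  cc2 <- count_clusters_in_structures(term, straddle)
  expect_identical(cc2$structures$n_clusters, 0L)
  # the same object under the overlap rule is assigned
  cc3 <- count_clusters_in_structures(term, straddle, rule = "overlap")
  expect_identical(cc3$structures$n_clusters, 1L)
})

test_that("containment counts conserve the cluster total", {
  set.seed(17)
  for (rep in 1:10) {
    s <- mask_from(matrix(runif(48 * 48) < 0.2, 48, 48))
    cl <- mask_from(matrix(runif(48 * 48) < 0.1, 48, 48))
    cc <- count_clusters_in_structures(s, cl)
    expect_lte(sum(cc$structures$n_clusters), nrow(cl$objects))
  }
})

test_that("cluster density is count over area with a zero-area sentinel", {
  expect_equal(compute_cluster_density(10, 5), 2.0)
  expect_equal(compute_cluster_density(0, 5), 0.0)
  expect_warning(d <- compute_cluster_density(3, 0), "undefined")
  expect_true(is.na(d))
})

test_that("density direction: half the clusters in a quarter of the area", {
  d1 <- compute_cluster_density(100, 40)  # VGLUT1: more clusters, more area
  d2 <- compute_cluster_density(50, 10)   # VGLUT2: half clusters, 1/4 area
  expect_equal(d2 / d1, 2.0)
})

test_that("structure size summaries aggregate image then animal", {
  rec <- data.frame(synapse_id = 1:2, subtype = "VGLUT1",
                    terminal_label = 1:2, psd_label = 1:2,
                    terminal_area_um2 = c(1, 3), psd_area_um2 = c(0.5, 0.7))
  s <- measure_structure_sizes(rec)
  expect_equal(s$mean_um2[s$compartment == "presynaptic"], 2.0)

  rec6 <- data.frame(synapse_id = 1:6, subtype = "VGLUT1",
                     terminal_label = 1:6, psd_label = 1:6,
                     terminal_area_um2 = c(1, 2, 3, 4, 5, 6),
                     psd_area_um2 = 0.5,
                     animal_id = rep(c("m1", "m2"), each = 3),
                     image_id = rep(1:3, 2))
  s6 <- measure_structure_sizes(rec6)
  pre <- s6[s6$compartment == "presynaptic", ]
  expect_identical(nrow(pre), 2L)  # one row per animal
  expect_equal(sort(pre$mean_um2), c(2, 5))

  empty <- measure_structure_sizes(rec[0, ])
  expect_identical(nrow(empty), 0L)
})
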