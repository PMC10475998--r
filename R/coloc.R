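check_same_grid <- function(a, b) {
  if (!inherits(a, "labeled_mask") || !inherits(b, "labeled_mask"))
    stop("expected labeled_mask objects", call. = FALSE)
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("masks are on different grids", call. = FALSE)
  invisible(TRUE)
}

# overlap pixel count of every object of `a` with the foreground of `b`
overlap_with_foreground <- function(a, b) {
  n <- nrow(a$objects)
  if (n == 0) return(integer(0))
  sel <- a$labels > 0 & b$labels > 0
  counts <- tabulate(a$labels[sel], n)
  counts
}

#' Object-based colocalization by intensity redirection
#'
#' Implements the binarized-overlap rule: an object of mask `a` is
#' colocalized with marker `b` when at least one of its pixels lies on
#' foreground of `b` ("any measure of intensity above zero").
#'
#' @param mask_a,mask_b `labeled_mask` objects on the same grid.
#' @return data.frame per object of `a`: `label`, `overlap_px`,
#'   `colocalized`.
#' @export
colocalize_objects <- function(mask_a, mask_b) {
  check_same_grid(mask_a, mask_b)
  ov <- overlap_with_foreground(mask_a, mask_b)
  data.frame(label = mask_a$objects$label, overlap_px = ov,
             colocalized = ov > 0)
}

# pairwise overlap table between labels of two masks:
# data.frame(label_a, label_b, overlap_px)
overlap_pairs <- function(a, b) {
  sel <- a$labels > 0 & b$labels > 0
  if (!any(sel))
    return(data.frame(label_a = integer(), label_b = integer(),
                      overlap_px = integer()))
  df <- data.frame(label_a = a$labels[sel], label_b = b$labels[sel])
  ag <- aggregate(list(overlap_px = rep(1L, nrow(df))),
                  by = df, FUN = sum)
  ag[order(ag$label_a, ag$label_b), , drop = FALSE]
}

#' Classify synapses from VGLUT1, VGLUT2 and PSD95 masks
#'
#' A VGLUT1 synapse is a VGLUT1 particle with at least one pixel of PSD95
#' overlap, regardless of any VGLUT2 signal; a VGLUT2 synapse is a VGLUT2
#' particle with PSD95 overlap and zero overlap with VGLUT1 foreground.
#' Each synapse is paired with the PSD object of largest overlap (ties to
#' the lowest PSD label).
#'
#' @param vglut1,vglut2,psd95 `labeled_mask` objects on one grid.
#' @return data.frame of synapse records: `synapse_id`, `subtype`,
#'   `terminal_label`, `psd_label`, `terminal_area_um2`, `psd_area_um2`.
#' @export
classify_synapses <- function(vglut1, vglut2, psd95) {
  check_same_grid(vglut1, psd95)
  check_same_grid(vglut2, psd95)

  build <- function(term_mask, subtype, exclude_fg = NULL) {
    pairs <- overlap_pairs(term_mask, psd95)
    if (nrow(pairs) == 0) return(NULL)
    labs <- unique(pairs$label_a)
    if (!is.null(exclude_fg)) {
      ov1 <- overlap_with_foreground(term_mask, exclude_fg)
      labs <- labs[ov1[labs] == 0]
    }
    if (length(labs) == 0) return(NULL)
    # PSD of largest overlap; overlap_pairs is sorted, so the first max
    # hit is the lowest PSD label
    psd_lab <- vapply(labs, function(l) {
      pp <- pairs[pairs$label_a == l, ]
      pp$label_b[which.max(pp$overlap_px)]
    }, 0L)
    data.frame(subtype = subtype, terminal_label = labs,
               psd_label = psd_lab,
               terminal_area_um2 = term_mask$objects$area_um2[labs],
               psd_area_um2 = psd95$objects$area_um2[psd_lab],
               stringsAsFactors = FALSE)
  }
  rec <- rbind(build(vglut1, "VGLUT1"),
               build(vglut2, "VGLUT2", exclude_fg = vglut1))
  if (is.null(rec))
    rec <- data.frame(subtype = character(), terminal_label = integer(),
                      psd_label = integer(), terminal_area_um2 = numeric(),
                      psd_area_um2 = numeric(), stringsAsFactors = FALSE)
  cbind(synapse_id = seq_len(nrow(rec)), rec)
}

#' Count clusters inside labeled structures
#'
#' Assigns each cluster object to the structure whose foreground contains
#' its centroid (default), or to the structure of largest pixel overlap
#' when `rule = "overlap"`; works identically on 2D and 3D grids.
#'
#' @param structures,clusters `labeled_mask` objects on the same grid.
#' @param rule `"centroid"` or `"overlap"`.
#' @return list with `structures` (per-structure `label`, `contains`,
#'   `n_clusters`) and `assignments` (per-cluster `cluster_label`,
#'   `structure_label`, `cluster_area_um2`; 0 = unassigned).
#' @export
count_clusters_in_structures <- function(structures, clusters,
                                         rule = c("centroid", "overlap")) {
  check_same_grid(structures, clusters)
  rule <- match.arg(rule)
  nc <- nrow(clusters$objects)
  ns <- nrow(structures$objects)
  if (rule == "centroid") {
    assig <- integer(nc)
    if (nc > 0) {
      ix <- pmin(pmax(round(clusters$objects$centroid_x_px), 1), dim(structures$labels)[1])
      iy <- pmin(pmax(round(clusters$objects$centroid_y_px), 1), dim(structures$labels)[2])
      if (length(dim(structures$labels)) == 3) {
        iz <- pmin(pmax(round(clusters$objects$centroid_z_px), 1),
                   dim(structures$labels)[3])
        assig <- structures$labels[cbind(ix, iy, iz)]
      } else {
        assig <- structures$labels[cbind(ix, iy)]
      }
    }
  } else {
    pairs <- overlap_pairs(clusters, structures)
    assig <- integer(nc)
    if (nrow(pairs) > 0) {
      for (l in unique(pairs$label_a)) {
        pp <- pairs[pairs$label_a == l, ]
        assig[l] <- pp$label_b[which.max(pp$overlap_px)]
      }
    }
  }
  counts <- tabulate(assig[assig > 0], ns)
  list(structures = data.frame(label = structures$objects$label,
                               contains = counts > 0, n_clusters = counts),
       assignments = data.frame(cluster_label = clusters$objects$label,
                                structure_label = assig,
                                cluster_area_um2 = clusters$objects$area_um2))
}

#' Cluster density inside a synaptic marker
#'
#' @param n_clusters total clusters counted inside a subtype's structures.
#' @param total_marker_area_um2 total area covered by the marker, um^2.
#' @return clusters per um^2; `NA` (with a warning) for zero area.
#' @export
compute_cluster_density <- function(n_clusters, total_marker_area_um2) {
  if (!is.finite(total_marker_area_um2) || total_marker_area_um2 <= 0) {
    warning("undefined density: marker area is zero")
    return(NA_real_)
  }
  n_clusters / total_marker_area_um2
}

#' Per-subtype structure size summaries
#'
#' Summarizes terminal and PSD areas per subtype, optionally aggregated
#' image -> animal so the animal is the statistical unit.
#'
#' @param records synapse records from [classify_synapses()], optionally
#'   with `image_id` and `animal_id` columns.
#' @return data.frame with one row per subtype x compartment (and per
#'   animal when `animal_id` is present): `mean_um2`, `sd_um2`, `n`.
#' @export
measure_structure_sizes <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(subtype = character(), compartment = character(),
                      animal_id = character(), mean_um2 = numeric(),
                      sd_um2 = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  long <- rbind(
    data.frame(records[setdiff(names(records),
                               c("terminal_area_um2", "psd_area_um2"))],
               compartment = "presynaptic", area = records$terminal_area_um2),
    data.frame(records[setdiff(names(records),
                               c("terminal_area_um2", "psd_area_um2"))],
               compartment = "postsynaptic", area = records$psd_area_um2))
  has_animal <- "animal_id" %in% names(long)
  has_image <- "image_id" %in% names(long)
  if (has_animal) {
    # image-level means first (when images are recorded), then animal level
    by1 <- if (has_image)
      aggregate(area ~ subtype + compartment + animal_id + image_id,
                long, mean)
    else long
    out <- do.call(rbind, lapply(
      split(by1, list(by1$subtype, by1$compartment, by1$animal_id),
            drop = TRUE),
      function(d) data.frame(subtype = d$subtype[1],
                             compartment = d$compartment[1],
                             animal_id = d$animal_id[1],
                             mean_um2 = mean(d$area), sd_um2 = sd(d$area),
                             n = nrow(d), stringsAsFactors = FALSE)))
  } else {
    out <- do.call(rbind, lapply(
      split(long, list(long$subtype, long$compartment), drop = TRUE),
      function(d) data.frame(subtype = d$subtype[1],
                             compartment = d$compartment[1],
                             animal_id = NA_character_,
                             mean_um2 = mean(d$area), sd_um2 = sd(d$area),
                             n = nrow(d), stringsAsFactors = FALSE)))
  }
  rownames(out) <- NULL
  out[order(out$subtype, out$compartment), , drop = FALSE]
}
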