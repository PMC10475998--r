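#' Parameters of a synthetic neuropil scene
#'
#' Bundles the generative parameters for a ground-truth field of excitatory
#' synapses in spinal-cord neuropil: sparse, large VGLUT1-type presynaptic
#' terminals and abundant, small VGLUT2-type terminals, each apposed to a
#' PSD95-positive postsynaptic density, with diffraction-limited pTDP-43
#' clusters occupying compartments at subtype-dependent probabilities.
#'
#' Defaults encode the study conditions: compartment occupancies of 87.6%
#' (VGLUT1 terminals), 59.6% (VGLUT2 terminals), 46.2% / 45.7% (PSDs of
#' VGLUT1 / VGLUT2 synapses), and true cluster diameters of 120 +/- 25 nm.
#' Absolute terminal densities and areas are not published for this tissue;
#' the defaults below follow the qualitative description (VGLUT1 terminals
#' roughly 4x larger and 4x sparser than VGLUT2) and are fully configurable.
#'
#' @param field_size_um side of the square field, in micrometres.
#' @param density_vglut1,density_vglut2 terminal densities per 100 um^2.
#' @param vglut1_area_um2,vglut2_area_um2,psd_area_um2 length-2 vectors
#'   `c(mean, sd)` of structure areas in um^2.
#' @param occupancy named probabilities that a compartment holds at least
#'   one cluster; names `vglut1_pre`, `vglut2_pre`, `vglut1_psd`,
#'   `vglut2_psd`.
#' @param clusters_per_occupied mean number of extra clusters beyond the
#'   first in an occupied compartment (shifted-Poisson parameter; the count
#'   is `1 + Poisson(clusters_per_occupied)`).
#' @param cluster_diameter_nm length-2 vector `c(mean, sd)` of true cluster
#'   diameters in nm (diameter = FWHM of the cluster's intensity profile).
#' @param genotype_effect multiplicative scale applied to VGLUT1 terminal
#'   and VGLUT1-associated PSD areas; use values < 1 for a disease arm with
#'   shrunken VGLUT1 synapses.
#' @param coexpression_frac fraction of VGLUT1 terminals that also carry a
#'   weak VGLUT2 signal.
#' @param seed integer random seed; the same parameters and seed always
#'   produce the identical scene.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(field_size_um = 30,
                         density_vglut1 = 2,
                         density_vglut2 = 8,
                         vglut1_area_um2 = c(0.60, 0.15),
                         vglut2_area_um2 = c(0.15, 0.04),
                         psd_area_um2 = c(0.10, 0.03),
                         occupancy = c(vglut1_pre = 0.876,
                                       vglut2_pre = 0.596,
                                       vglut1_psd = 0.462,
                                       vglut2_psd = 0.457),
                         clusters_per_occupied = 0.8,
                         cluster_diameter_nm = c(120, 25),
                         genotype_effect = 1,
                         coexpression_frac = 0.1,
                         seed = 1L) {
  stop_if_not_scalar_pos(field_size_um, "field_size_um")
  stop_if_not_scalar_pos(density_vglut1, "density_vglut1")
  stop_if_not_scalar_pos(density_vglut2, "density_vglut2")
  for (nm in c("vglut1_area_um2", "vglut2_area_um2", "psd_area_um2",
               "cluster_diameter_nm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || v[1] <= 0 ||
        v[2] < 0)
      stop(sprintf("`%s` must be c(mean > 0, sd >= 0)", nm), call. = FALSE)
  }
  need <- c("vglut1_pre", "vglut2_pre", "vglut1_psd", "vglut2_psd")
  if (!all(need %in% names(occupancy)))
    stop("`occupancy` must be named with ", paste(need, collapse = ", "),
         call. = FALSE)
  occupancy <- occupancy[need]
  if (any(!is.finite(occupancy)) || any(occupancy < 0) || any(occupancy > 1))
    stop("occupancy probabilities must lie in [0, 1]", call. = FALSE)
  stop_if_not_scalar_pos(clusters_per_occupied, "clusters_per_occupied",
                         allow_zero = TRUE)
  stop_if_not_scalar_pos(genotype_effect, "genotype_effect")
  if (!is.numeric(coexpression_frac) || coexpression_frac < 0 ||
      coexpression_frac > 1)
    stop("`coexpression_frac` must lie in [0, 1]", call. = FALSE)
  structure(list(field_size_um = field_size_um,
                 density_vglut1 = density_vglut1,
                 density_vglut2 = density_vglut2,
                 vglut1_area_um2 = vglut1_area_um2,
                 vglut2_area_um2 = vglut2_area_um2,
                 psd_area_um2 = psd_area_um2,
                 occupancy = occupancy,
                 clusters_per_occupied = clusters_per_occupied,
                 cluster_diameter_nm = cluster_diameter_nm,
                 genotype_effect = genotype_effect,
                 coexpression_frac = coexpression_frac,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' @export
print.scene_params <- function(x, ...) {
  cat("Synthetic scene parameters\n")
  cat(sprintf("  field: %.1f x %.1f um, seed %d\n", x$field_size_um,
              x$field_size_um, x$seed))
  cat(sprintf("  densities (per 100 um^2): VGLUT1 %.2f, VGLUT2 %.2f\n",
              x$density_vglut1, x$density_vglut2))
  cat(sprintf("  occupancy: %s\n",
              paste(sprintf("%s=%.3f", names(x$occupancy), x$occupancy),
                    collapse = ", ")))
  invisible(x)
}

# sample one ellipse (semi-axes in nm, orientation in rad) of a given area
# (um^2) with a mild random aspect ratio
sample_ellipse <- function(area_um2) {
  aspect <- runif(length(area_um2), 1.2, 2.0)
  a_um <- sqrt(area_um2 * aspect / pi)
  b_um <- sqrt(area_um2 / (aspect * pi))
  list(a = a_um * 1000, b = b_um * 1000,
       theta = runif(length(area_um2), 0, pi))
}

#' Generate a ground-truth synapse scene
#'
#' Draws synapse counts from Poisson laws at the configured densities,
#' places terminals with a hard-core constraint (no two terminals overlap)
#' and an inset border margin so whole structures stay inside the field,
#' apposes one PSD to each terminal edge, and populates compartments with
#' pTDP-43 clusters by Bernoulli occupancy followed by a shifted-Poisson
#' count. All coordinates are physical nanometres with the origin at the
#' field corner.
#'
#' @param params a [scene_params()] object.
#' @return an object of class `synapse_scene`: a list with `params`,
#'   `synapses` (one row per synapse with terminal and PSD ellipses) and
#'   `clusters` (one row per ground-truth cluster).
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "scene_params"))
    stop("`params` must be a scene_params object", call. = FALSE)
  set.seed(params$seed)
  L <- params$field_size_um * 1000       # nm
  area <- params$field_size_um^2         # um^2
  n1 <- rpois(1, params$density_vglut1 * area / 100)
  n2 <- rpois(1, params$density_vglut2 * area / 100)
  n <- n1 + n2
  subtype <- c(rep("VGLUT1", n1), rep("VGLUT2", n2))

  syn <- NULL
  if (n > 0) {
    t_area <- numeric(n)
    t_area[subtype == "VGLUT1"] <-
      rnorm_trunc(n1, params$vglut1_area_um2[1] * params$genotype_effect,
                  params$vglut1_area_um2[2], 0.01)
    t_area[subtype == "VGLUT2"] <-
      rnorm_trunc(n2, params$vglut2_area_um2[1], params$vglut2_area_um2[2],
                  0.01)
    p_area <- rnorm_trunc(n, params$psd_area_um2[1], params$psd_area_um2[2],
                          0.005)
    p_area[subtype == "VGLUT1"] <-
      p_area[subtype == "VGLUT1"] * params$genotype_effect
    tell <- sample_ellipse(t_area)
    pell <- sample_ellipse(p_area)

    # hard-core sequential placement: keep terminal centers farther apart
    # than the sum of their long semi-axes; fall back after 200 attempts so
    # dense configurations still complete
    margin <- tell$a + 2 * pell$a
    cx <- numeric(n); cy <- numeric(n)
    for (i in seq_len(n)) {
      for (att in seq_len(200L)) {
        px <- runif(1, margin[i], L - margin[i])
        py <- runif(1, margin[i], L - margin[i])
        if (i == 1L) break
        j <- seq_len(i - 1L)
        if (all(sqrt((px - cx[j])^2 + (py - cy[j])^2) >
                0.9 * (tell$a[i] + tell$a[j]))) break
      }
      cx[i] <- px; cy[i] <- py
    }

    # PSD apposed to the terminal edge along a random direction phi, long
    # axis tangential; the PSD penetrates the terminal boundary by 25-50%
    # of its short semi-axis, giving the partial overlap that defines a
    # synapse downstream while keeping the shared area small
    phi <- runif(n, 0, 2 * pi)
    rb <- ellipse_radius(tell$a, tell$b, tell$theta, phi)
    d <- rb + pell$b * (1 - runif(n, 0.25, 0.5))
    pcx <- cx + d * cos(phi)
    pcy <- cy + d * sin(phi)

    syn <- data.frame(
      id = seq_len(n), subtype = subtype,
      tx_nm = cx, ty_nm = cy, ta_nm = tell$a, tb_nm = tell$b,
      ttheta = tell$theta, terminal_area_um2 = t_area,
      px_nm = pcx, py_nm = pcy, pa_nm = pell$a, pb_nm = pell$b,
      ptheta = phi + pi / 2, psd_area_um2 = p_area,
      vglut2_coexpression = subtype == "VGLUT1" &
        runif(n) < params$coexpression_frac,
      stringsAsFactors = FALSE)
  } else {
    syn <- data.frame(id = integer(), subtype = character(),
                      tx_nm = numeric(), ty_nm = numeric(),
                      ta_nm = numeric(), tb_nm = numeric(),
                      ttheta = numeric(), terminal_area_um2 = numeric(),
                      px_nm = numeric(), py_nm = numeric(),
                      pa_nm = numeric(), pb_nm = numeric(),
                      ptheta = numeric(), psd_area_um2 = numeric(),
                      vglut2_coexpression = logical(),
                      stringsAsFactors = FALSE)
  }

  clusters <- empty_cluster_df()
  if (n > 0) {
    cl_list <- vector("list", 2L * n)
    k <- 0L
    for (i in seq_len(n)) {
      for (comp in c("presynaptic", "postsynaptic")) {
        key <- paste0(tolower(syn$subtype[i]),
                      if (comp == "presynaptic") "_pre" else "_psd")
        if (runif(1) >= params$occupancy[[key]]) next
        m <- 1L + rpois(1, params$clusters_per_occupied)
        if (comp == "presynaptic") {
          cc <- c(syn$tx_nm[i], syn$ty_nm[i])
          ax <- c(syn$ta_nm[i], syn$tb_nm[i]); th <- syn$ttheta[i]
        } else {
          cc <- c(syn$px_nm[i], syn$py_nm[i])
          ax <- c(syn$pa_nm[i], syn$pb_nm[i]); th <- syn$ptheta[i]
        }
        # uniform draws inside the compartment ellipse, inset slightly so
        # a cluster's center cannot sit on the boundary
        r <- sqrt(runif(m)) * 0.9
        ang <- runif(m, 0, 2 * pi)
        u <- r * cos(ang) * ax[1]; v <- r * sin(ang) * ax[2]
        x <- cc[1] + u * cos(th) - v * sin(th)
        y <- cc[2] + u * sin(th) + v * cos(th)
        dia <- rnorm_trunc(m, params$cluster_diameter_nm[1],
                           params$cluster_diameter_nm[2], 20)
        k <- k + 1L
        cl_list[[k]] <- data.frame(
          x_nm = x, y_nm = y, z_nm = NA_real_, diameter_nm = dia,
          compartment = comp, parent_synapse = syn$id[i],
          stringsAsFactors = FALSE)
      }
    }
    if (k > 0L) {
      clusters <- do.call(rbind, cl_list[seq_len(k)])
      clusters <- cbind(id = seq_len(nrow(clusters)), clusters)
    }
  }

  structure(list(params = params, synapses = syn, clusters = clusters),
            class = "synapse_scene")
}

empty_cluster_df <- function() {
  data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
             z_nm = numeric(), diameter_nm = numeric(),
             compartment = character(), parent_synapse = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.synapse_scene <- function(x, ...) {
  cat(sprintf("Synthetic synapse scene: %d synapses (%d VGLUT1, %d VGLUT2), %d clusters\n",
              nrow(x$synapses), sum(x$synapses$subtype == "VGLUT1"),
              sum(x$synapses$subtype == "VGLUT2"), nrow(x$clusters)))
  invisible(x)
}
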