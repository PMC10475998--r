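# derive a reproducible 31-bit sub-seed from a master seed and a stream id
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Default configuration for an Airyscan-style analysis run
#'
#' @param seed master seed; every stage seed is derived from it.
#' @param n_animals,n_images_per_animal sampling design.
#' @param scene scene parameters shared by all images (per-image seeds are
#'   derived internally).
#' @param seg named list of [seg_params()] per channel.
#' @param peak_intensity,background rendering intensities.
#' @param assignment_rule cluster-in-structure rule
#'   (`"centroid"`/`"overlap"`).
#' @return config list for [run_airyscan_analysis()].
#' @export
airyscan_config <- function(seed = 1L, n_animals = 2L,
                            n_images_per_animal = 3L,
                            scene = scene_params(),
                            seg = NULL,
                            peak_intensity = 150, background = 10,
                            assignment_rule = "centroid") {
  if (is.null(seg)) {
    structure_seg <- seg_params(background_radius_px = 30, blur_sigma_px = 1,
                                threshold = "otsu", min_area_px = 10)
    seg <- list(VGLUT1 = structure_seg, VGLUT2 = structure_seg,
                PSD95 = seg_params(background_radius_px = 30,
                                   blur_sigma_px = 1, threshold = "otsu",
                                   min_area_px = 6),
                pTDP43 = seg_params(background_radius_px = 20,
                                    blur_sigma_px = 1, threshold = "otsu",
                                    min_area_px = 4))
  }
  list(seed = as.integer(seed), n_animals = as.integer(n_animals),
       n_images_per_animal = as.integer(n_images_per_animal),
       scene = scene, modality = "airyscan", seg = seg,
       peak_intensity = peak_intensity, background = background,
       assignment_rule = assignment_rule)
}

segment_scene_channels <- function(scene, modality, seg, peak_intensity,
                                   background, seed) {
  masks <- list()
  for (ch in SCENE_CHANNELS) {
    img <- render_channel_image(scene, modality, ch,
                                peak_intensity = peak_intensity,
                                background = background, noise = TRUE,
                                seed = derive_seed(seed, match(ch, SCENE_CHANNELS)))
    pre <- preprocess_channel(img, seg[[ch]])
    masks[[ch]] <- threshold_and_label(pre, seg[[ch]])
  }
  masks
}

# per-image quantification shared by the Airyscan pipeline
quantify_image <- function(masks, rule) {
  records <- classify_synapses(masks$VGLUT1, masks$VGLUT2, masks$PSD95)
  c1 <- count_clusters_in_structures(masks$VGLUT1, masks$pTDP43, rule)
  c2 <- count_clusters_in_structures(masks$VGLUT2, masks$pTDP43, rule)
  cp <- count_clusters_in_structures(masks$PSD95, masks$pTDP43, rule)
  n_pre <- ifelse(records$subtype == "VGLUT1",
                  c1$structures$n_clusters[records$terminal_label],
                  c2$structures$n_clusters[records$terminal_label])
  records$n_clusters_presyn <- n_pre
  records$n_clusters_postsyn <- cp$structures$n_clusters[records$psd_label]

  met <- list()
  for (st in c("VGLUT1", "VGLUT2")) {
    r <- records[records$subtype == st, ]
    cc <- if (st == "VGLUT1") c1 else c2
    term_mask <- if (st == "VGLUT1") "VGLUT1" else "VGLUT2"
    marker_area <- sum(masks[[term_mask]]$objects$area_um2)
    assig <- cc$assignments
    in_syn <- assig$structure_label %in% r$terminal_label
    met[[st]] <- data.frame(
      subtype = st,
      n_synapses = nrow(r),
      pct_pre_containing = if (nrow(r)) 100 * mean(r$n_clusters_presyn > 0)
                           else NA_real_,
      pct_psd_containing = if (nrow(r)) 100 * mean(r$n_clusters_postsyn > 0)
                           else NA_real_,
      clusters_per_terminal = if (nrow(r)) mean(r$n_clusters_presyn)
                              else NA_real_,
      density_per_um2 = compute_cluster_density(sum(in_syn), marker_area),
      mean_cluster_area_um2 = if (any(in_syn))
        mean(assig$cluster_area_um2[in_syn]) else NA_real_,
      mean_terminal_area_um2 = if (nrow(r)) mean(r$terminal_area_um2)
                               else NA_real_,
      mean_psd_area_um2 = if (nrow(r)) mean(r$psd_area_um2) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(records = records, metrics = do.call(rbind, met))
}

# ground-truth occupancy of a scene, per category
scene_truth_occupancy <- function(scene) {
  syn <- scene$synapses; cl <- scene$clusters
  occ <- function(st, comp) {
    ids <- syn$id[syn$subtype == st]
    if (length(ids) == 0) return(NA_real_)
    with_cl <- unique(cl$parent_synapse[cl$compartment == comp])
    100 * mean(ids %in% with_cl)
  }
  data.frame(category = c("vglut1_pre", "vglut2_pre", "vglut1_psd",
                          "vglut2_psd"),
             truth_pct = c(occ("VGLUT1", "presynaptic"),
                           occ("VGLUT2", "presynaptic"),
                           occ("VGLUT1", "postsynaptic"),
                           occ("VGLUT2", "postsynaptic")))
}

#' Run the Airyscan-style synapse quantification pipeline
#'
#' For every animal and image: generate (or reuse) a ground-truth scene,
#' render the four channels, segment, classify synapses, count pTDP-43
#' clusters per compartment, and compute per-image metrics; image metrics
#' are then averaged per animal (the animal is the statistical unit) and
#' the four structure categories are compared by one-way ANOVA with Tukey
#' post-hoc tests.
#'
#' @param config from [airyscan_config()].
#' @return list with `synapses` (all records), `image_metrics`,
#'   `animal_summary`, `occupancy` (measured vs ground-truth percentage
#'   per category), `anova`, and a `report` of counts and settings.
#' @export
run_airyscan_analysis <- function(config) {
  rows <- list(); recs <- list(); truths <- list()
  img_id <- 0L
  for (a in seq_len(config$n_animals)) {
    for (i in seq_len(config$n_images_per_animal)) {
      img_id <- img_id + 1L
      sp <- config$scene
      sp$seed <- derive_seed(config$seed, img_id)
      scene <- generate_scene(sp)
      masks <- segment_scene_channels(scene, config$modality, config$seg,
                                      config$peak_intensity,
                                      config$background,
                                      derive_seed(config$seed, 5000L + img_id))
      q <- quantify_image(masks, config$assignment_rule)
      q$records$animal_id <- paste0("animal", a)
      q$records$image_id <- img_id
      q$metrics$animal_id <- paste0("animal", a)
      q$metrics$image_id <- img_id
      recs[[img_id]] <- q$records
      rows[[img_id]] <- q$metrics
      truths[[img_id]] <- scene_truth_occupancy(scene)
    }
  }
  image_metrics <- do.call(rbind, rows)
  synapses <- do.call(rbind, recs)

  num_cols <- setdiff(names(image_metrics),
                      c("subtype", "animal_id", "image_id"))
  animal_summary <- aggregate(image_metrics[num_cols],
                              by = list(subtype = image_metrics$subtype,
                                        animal_id = image_metrics$animal_id),
                              FUN = mean, na.rm = TRUE)

  measured <- data.frame(
    category = c("vglut1_pre", "vglut2_pre", "vglut1_psd", "vglut2_psd"),
    measured_pct = c(
      weighted_pct(image_metrics, "VGLUT1", "pct_pre_containing"),
      weighted_pct(image_metrics, "VGLUT2", "pct_pre_containing"),
      weighted_pct(image_metrics, "VGLUT1", "pct_psd_containing"),
      weighted_pct(image_metrics, "VGLUT2", "pct_psd_containing")))
  truth <- aggregate(truth_pct ~ category, do.call(rbind, truths), mean)
  occupancy <- merge(measured, truth, by = "category", sort = TRUE)

  # Fig 2C-style comparison: occupancy per category, animal as unit
  anova_res <- NULL
  if (config$n_animals >= 2) {
    g <- list()
    for (cat in c("vglut1_pre", "vglut2_pre", "vglut1_psd", "vglut2_psd")) {
      st <- if (grepl("vglut1", cat)) "VGLUT1" else "VGLUT2"
      col <- if (grepl("pre", cat)) "pct_pre_containing" else "pct_psd_containing"
      v <- animal_summary[animal_summary$subtype == st, col]
      g[[cat]] <- group_sample(cat, v, "animal")
    }
    anova_res <- tryCatch(one_way_anova_tukey(g), error = function(e) NULL)
  }

  list(synapses = synapses, image_metrics = image_metrics,
       animal_summary = animal_summary, occupancy = occupancy,
       anova = anova_res,
       report = list(seed = config$seed, modality = config$modality,
                     n_animals = config$n_animals,
                     n_images = img_id,
                     n_synapses = nrow(synapses),
                     assignment_rule = config$assignment_rule,
                     thresholds = lapply(config$seg, function(s) s$threshold)))
}

# pooled percentage across images, weighting by synapse count
weighted_pct <- function(m, st, col) {
  d <- m[m$subtype == st & is.finite(m[[col]]), ]
  if (nrow(d) == 0 || sum(d$n_synapses) == 0) return(NA_real_)
  sum(d[[col]] * d$n_synapses) / sum(d$n_synapses)
}

#' Default configuration for an SMLM (AD-PAINT-style) run
#'
#' The scene emulates the SMLM field of view: presynaptic occupancies of
#' 80% (VGLUT1) and 51% (VGLUT2) and true cluster diameters around 55 nm;
#' postsynaptic clusters are off because the association readout is
#' presynaptic.
#'
#' @param seed master seed.
#' @param scene scene parameters for the SMLM field.
#' @param n_frames,events_rate,precision_nm event-stream settings.
#' @param eps_nm,min_pts DBSCAN settings (40 nm, 5).
#' @param min_signal,min_photons,max_precision_nm localization filters.
#' @param render_pixel_nm FRC rendering pixel.
#' @return config list for [run_smlm_analysis()].
#' @export
smlm_config <- function(seed = 1L,
                        scene = scene_params(
                          field_size_um = 15,
                          occupancy = c(vglut1_pre = 0.80,
                                        vglut2_pre = 0.51,
                                        vglut1_psd = 0, vglut2_psd = 0),
                          cluster_diameter_nm = c(55, 12),
                          clusters_per_occupied = 0.6),
                        n_frames = 4000, events_rate = 0.01,
                        precision_nm = 20, eps_nm = 40, min_pts = 5,
                        min_signal = 20, min_photons = 50,
                        max_precision_nm = 40, render_pixel_nm = 10,
                        frc_crop_um = 12.8) {
  list(seed = as.integer(seed), scene = scene, n_frames = n_frames,
       events_rate = events_rate, precision_nm = precision_nm,
       eps_nm = eps_nm, min_pts = min_pts, min_signal = min_signal,
       min_photons = min_photons, max_precision_nm = max_precision_nm,
       render_pixel_nm = render_pixel_nm, frc_crop_um = frc_crop_um)
}

#' Run the AD-PAINT-style SMLM analysis pipeline
#'
#' Simulates (or ingests) a localization stream, applies the quality
#' filters, clusters with DBSCAN, associates clusters with TIRF-rendered
#' and thresholded VGLUT1/VGLUT2 terminal masks, tests the subtype
#' association by chi-squared, and estimates the image resolution by
#' Fourier ring correlation.
#'
#' @param config from [smlm_config()].
#' @param localizations optional pre-built `localization_table`; when
#'   supplied the simulation step is skipped but the scene is still used
#'   for the terminal masks.
#' @return list with `localizations`, `clusters`, `association` (per
#'   subtype percent containing + chi-squared), `diameters` (median,
#'   range, histogram), `frc`, and a `report`.
#' @export
run_smlm_analysis <- function(config, localizations = NULL) {
  sp <- config$scene
  sp$seed <- derive_seed(config$seed, 1L)
  scene <- generate_scene(sp)
  if (is.null(localizations)) {
    stream <- simulate_localization_events(
      scene, n_frames = config$n_frames,
      mean_events_per_cluster_per_frame = config$events_rate,
      precision_nm = config$precision_nm,
      seed = derive_seed(config$seed, 2L))
    localizations <- events_to_localizations(stream)
  }
  filt <- filter_localizations(localizations, config$min_signal,
                               config$min_photons, config$max_precision_nm)
  db <- dbscan_cluster(filt, config$eps_nm, config$min_pts)

  # terminal masks from mean-projected TIRF channels
  seg <- seg_params(background_radius_px = 0, blur_sigma_px = 0.5,
                    threshold = "otsu", min_area_px = 2)
  assoc <- list(); tabs <- list()
  for (st in c("VGLUT1", "VGLUT2")) {
    img <- render_channel_image(scene, "tirf", st, noise = TRUE,
                                seed = derive_seed(config$seed,
                                                   10L + match(st, SCENE_CHANNELS)))
    mask <- threshold_and_label(preprocess_channel(img, seg), seg)
    as <- associate_clusters_with_synapses(db$clusters, mask)
    assoc[[st]] <- as
    tabs[[st]] <- c(containing = sum(as$terminals$contains),
                    empty = sum(!as$terminals$contains))
  }
  cont <- rbind(VGLUT1 = tabs$VGLUT1, VGLUT2 = tabs$VGLUT2)
  chi <- if (all(rowSums(cont) > 0)) chi_squared_association(cont) else NULL

  dia <- db$clusters$diameter_nm
  diameters <- list(
    n = length(dia),
    median_nm = if (length(dia)) median(dia) else NA_real_,
    range_nm = if (length(dia)) range(dia) else c(NA_real_, NA_real_),
    histogram = if (length(dia))
      summarize_diameters(data.frame(accepted = TRUE, fwhm_nm = dia))$histogram
      else NULL)
  # FRC on a central crop so the rendering FFT stays bounded on wide fields
  frc_tab <- filt
  crop <- config$frc_crop_um
  if (!is.null(crop) && is.finite(crop)) {
    half <- crop * 1000 / 2
    cx <- sp$field_size_um * 1000 / 2
    sel <- abs(frc_tab$x_nm - cx) <= half & abs(frc_tab$y_nm - cx) <= half
    if (sum(sel) >= 100) frc_tab <- frc_tab[sel, , drop = FALSE]
  }
  frc <- if (nrow(frc_tab) >= 100)
    frc_resolution(localization_table(frc_tab,
                                      attr(filt, "pixel_size_nm"),
                                      attr(filt, "n_frames")),
                   config$render_pixel_nm)
    else NULL
  truth <- scene_truth_occupancy(scene)

  list(localizations = filt, clusters = db$clusters,
       association = list(
         contingency = cont,
         pct_containing = 100 * cont[, "containing"] / rowSums(cont),
         chi_squared = chi),
       diameters = diameters, frc = frc,
       truth_occupancy = truth,
       report = list(seed = config$seed,
                     n_localizations_raw = nrow(localizations),
                     n_localizations_kept = nrow(filt),
                     n_clusters = nrow(db$clusters),
                     n_terminals = vapply(tabs, sum, 0),
                     filters = c(config$min_signal, config$min_photons,
                                 config$max_precision_nm),
                     dbscan = c(eps_nm = config$eps_nm,
                                min_pts = config$min_pts)))
}

#' Default configuration for a two-arm group comparison
#'
#' Emulates the control vs disease-model design: a size effect on VGLUT1
#' structures in the disease arm (default 0.7x) and, by default, no effect
#' on pTDP-43 occupancy, counts or sizes. Between-animal variability is a
#' log-normal scale on structure areas and a logit-normal jitter on
#' occupancies.
#'
#' @param seed master seed.
#' @param n_control,n_disease animals per arm (5 and 6).
#' @param n_images_per_animal scenes per animal.
#' @param scene base scene parameters.
#' @param vglut1_size_effect multiplicative disease effect on VGLUT1
#'   terminal and PSD areas.
#' @param occupancy_odds_effect multiplicative disease effect on occupancy
#'   odds (1 = null).
#' @param animal_area_cv between-animal log-normal CV of areas.
#' @param animal_occ_sd between-animal logit-scale occupancy SD.
#' @return config list for [run_group_comparison()].
#' @export
group_comparison_config <- function(seed = 1L, n_control = 5L,
                                    n_disease = 6L,
                                    n_images_per_animal = 2L,
                                    scene = scene_params(field_size_um = 20),
                                    vglut1_size_effect = 0.7,
                                    occupancy_odds_effect = 1,
                                    animal_area_cv = 0.05,
                                    animal_occ_sd = 0.15) {
  list(seed = as.integer(seed), n_control = as.integer(n_control),
       n_disease = as.integer(n_disease),
       n_images_per_animal = as.integer(n_images_per_animal),
       scene = scene, vglut1_size_effect = vglut1_size_effect,
       occupancy_odds_effect = occupancy_odds_effect,
       animal_area_cv = animal_area_cv, animal_occ_sd = animal_occ_sd)
}

# per-animal ground-truth metrics for the group comparison
animal_metrics_from_scenes <- function(scenes) {
  syn <- do.call(rbind, lapply(scenes, `[[`, "synapses"))
  cl <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    d <- scenes[[i]]$clusters
    if (nrow(d)) d$scene_i <- i
    d
  }))
  occ_of <- function(st, comp) {
    tot <- 0L; hit <- 0L
    for (s in scenes) {
      ids <- s$synapses$id[s$synapses$subtype == st]
      with_cl <- unique(s$clusters$parent_synapse[
        s$clusters$compartment == comp])
      tot <- tot + length(ids); hit <- hit + sum(ids %in% with_cl)
    }
    if (tot == 0) NA_real_ else 100 * hit / tot
  }
  counts_per_terminal <- function(st) {
    out <- numeric(0)
    for (s in scenes) {
      ids <- s$synapses$id[s$synapses$subtype == st]
      if (!length(ids)) next
      pre <- s$clusters[s$clusters$compartment == "presynaptic", ]
      out <- c(out, tabulate(match(pre$parent_synapse, ids),
                             length(ids)))
    }
    mean(out)
  }
  dia_in <- function(st) {
    out <- numeric(0)
    for (s in scenes) {
      ids <- s$synapses$id[s$synapses$subtype == st]
      pre <- s$clusters[s$clusters$compartment == "presynaptic" &
                          s$clusters$parent_synapse %in% ids, ]
      out <- c(out, pre$diameter_nm)
    }
    out
  }
  list(
    vglut1_terminal_area = mean(syn$terminal_area_um2[syn$subtype == "VGLUT1"]),
    vglut1_psd_area = mean(syn$psd_area_um2[syn$subtype == "VGLUT1"]),
    vglut2_terminal_area = mean(syn$terminal_area_um2[syn$subtype == "VGLUT2"]),
    vglut2_psd_area = mean(syn$psd_area_um2[syn$subtype == "VGLUT2"]),
    occ_vglut1_pre = occ_of("VGLUT1", "presynaptic"),
    occ_vglut2_pre = occ_of("VGLUT2", "presynaptic"),
    occ_vglut1_psd = occ_of("VGLUT1", "postsynaptic"),
    occ_vglut2_psd = occ_of("VGLUT2", "postsynaptic"),
    count_vglut1 = counts_per_terminal("VGLUT1"),
    count_vglut2 = counts_per_terminal("VGLUT2"),
    diam_vglut1 = mean(dia_in("VGLUT1")),
    diam_vglut2 = mean(dia_in("VGLUT2")),
    pooled_diam_vglut1 = dia_in("VGLUT1"),
    pooled_diam_vglut2 = dia_in("VGLUT2"))
}

#' Run a control vs disease group comparison
#'
#' Simulates both arms at the ground-truth level (per animal, per image),
#' with the configured disease effects and between-animal variability,
#' then runs the statistical battery: pooled-variance t tests on the four
#' structure sizes, two-way genotype x structure ANOVAs on pTDP-43
#' occupancy, cluster counts and cluster sizes, Mann-Whitney tests on
#' pooled cluster diameters, and control-normalized percentage tables.
#'
#' @param config from [group_comparison_config()].
#' @return list with `animal_metrics` (one row per animal), `tests`,
#'   `normalized` (disease values as % of control mean) and `report`.
#' @export
run_group_comparison <- function(config) {
  arms <- list(control = config$n_control, disease = config$n_disease)
  rows <- list(); pooled <- list(control = list(), disease = list())
  aidx <- 0L
  for (arm in names(arms)) {
    for (a in seq_len(arms[[arm]])) {
      aidx <- aidx + 1L
      seed_a <- derive_seed(config$seed, aidx)
      set.seed(seed_a)
      area_scale <- rlnorm(1, 0, config$animal_area_cv)
      occ_jit <- rnorm(4, 0, config$animal_occ_sd)
      sp <- config$scene
      sp$vglut1_area_um2[1] <- sp$vglut1_area_um2[1] * area_scale
      sp$vglut2_area_um2[1] <- sp$vglut2_area_um2[1] * area_scale
      sp$psd_area_um2[1] <- sp$psd_area_um2[1] * area_scale
      occ <- sp$occupancy
      lo <- stats::qlogis(pmin(pmax(occ, 1e-6), 1 - 1e-6)) + occ_jit
      if (arm == "disease" && config$occupancy_odds_effect != 1)
        lo <- lo + log(config$occupancy_odds_effect)
      sp$occupancy <- setNames(stats::plogis(lo), names(occ))
      sp$occupancy[occ == 0] <- 0
      if (arm == "disease")
        sp$genotype_effect <- config$vglut1_size_effect
      scenes <- lapply(seq_len(config$n_images_per_animal), function(i) {
        s2 <- sp; s2$seed <- derive_seed(seed_a, i); generate_scene(s2)
      })
      m <- animal_metrics_from_scenes(scenes)
      pooled[[arm]]$d1 <- c(pooled[[arm]]$d1, m$pooled_diam_vglut1)
      pooled[[arm]]$d2 <- c(pooled[[arm]]$d2, m$pooled_diam_vglut2)
      m$pooled_diam_vglut1 <- NULL; m$pooled_diam_vglut2 <- NULL
      rows[[aidx]] <- data.frame(arm = arm, animal = aidx,
                                 as.data.frame(m),
                                 stringsAsFactors = FALSE)
    }
  }
  met <- do.call(rbind, rows)
  ctrl <- met[met$arm == "control", ]
  dis <- met[met$arm == "disease", ]

  t_on <- function(col) two_sample_t(group_sample("control", ctrl[[col]]),
                                     group_sample("disease", dis[[col]]))
  tests <- list(
    vglut1_terminal_area = t_on("vglut1_terminal_area"),
    vglut1_psd_area = t_on("vglut1_psd_area"),
    vglut2_terminal_area = t_on("vglut2_terminal_area"),
    vglut2_psd_area = t_on("vglut2_psd_area"))

  two_way_on <- function(cols) {
    vals <- unlist(lapply(cols, function(c) met[[c]]))
    geno <- rep(met$arm, length(cols))
    struct <- rep(cols, each = nrow(met))
    two_way_anova(vals, geno, struct)
  }
  tests$occupancy_anova <- two_way_on(c("occ_vglut1_pre", "occ_vglut2_pre",
                                        "occ_vglut1_psd", "occ_vglut2_psd"))
  tests$count_anova <- two_way_on(c("count_vglut1", "count_vglut2"))
  tests$size_anova <- two_way_on(c("diam_vglut1", "diam_vglut2"))
  tests$diam_vglut1_mw <- mann_whitney_u(
    group_sample("control", pooled$control$d1, "cluster"),
    group_sample("disease", pooled$disease$d1, "cluster"))
  tests$diam_vglut2_mw <- mann_whitney_u(
    group_sample("control", pooled$control$d2, "cluster"),
    group_sample("disease", pooled$disease$d2, "cluster"))

  norm_cols <- c("occ_vglut1_pre", "occ_vglut2_pre", "count_vglut1",
                 "count_vglut2", "diam_vglut1", "diam_vglut2")
  normalized <- do.call(rbind, lapply(norm_cols, function(col) {
    data.frame(metric = col,
               disease_pct_of_control =
                 mean(normalize_to_control(dis[[col]], ctrl[[col]])),
               stringsAsFactors = FALSE)
  }))

  list(animal_metrics = met, tests = tests, normalized = normalized,
       report = list(seed = config$seed,
                     n_control = config$n_control,
                     n_disease = config$n_disease,
                     vglut1_size_effect = config$vglut1_size_effect,
                     occupancy_odds_effect = config$occupancy_odds_effect))
}
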