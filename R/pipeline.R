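#' Bundle a CE-SSFP + LGE study
#'
#' Collects everything the pipeline needs: the CE-SSFP cine stacks at
#' end-diastole and end-systole, their contours, the optional LGE stack
#' with its own contours, the RV insertion angles and the culprit artery.
#'
#' @param grid [voxel_grid()] of the CE-SSFP stacks.
#' @param ce_images Named list with elements `ED` and/or `ES`, each a
#'   numeric array on `grid`.
#' @param contours [contour_set()] for the CE-SSFP stacks.
#' @param culprit Culprit artery: `"LAD"`, `"LCx"`, `"RCA"` or `"LM"`.
#' @param rv_anterior Anterior RV insertion angle (degrees) of the CE-SSFP
#'   stacks.
#' @param lge_images Optional LGE intensity array.
#' @param lge_grid [voxel_grid()] of the LGE stack (defaults to `grid`).
#' @param lge_contours [contour_set()] for the LGE stack (timeframe `ED`).
#' @param rv_anterior_lge RV insertion angle of the LGE stack.
#' @return Object of class `mar_study`.
#' @export
mar_study <- function(grid, ce_images, contours, culprit, rv_anterior,
                      lge_images = NULL, lge_grid = grid,
                      lge_contours = NULL, rv_anterior_lge = rv_anterior) {
  timeframes <- intersect(c("ED", "ES"), names(ce_images))
  timeframes <- timeframes[!vapply(ce_images[timeframes], is.null, logical(1))]
  if (length(timeframes) == 0) stop("study must contain an ED and/or ES stack")
  if (length(timeframes) == 1)
    warning("single-timeframe study; %LVM will use one timeframe only")
  if (!is.null(lge_images) && is.null(lge_contours))
    stop("LGE images require LGE contours")
  structure(list(grid = grid, ce_images = ce_images[timeframes],
                 contours = contours, culprit = culprit,
                 rv_anterior = rv_anterior, lge_images = lge_images,
                 lge_grid = lge_grid, lge_contours = lge_contours,
                 rv_anterior_lge = rv_anterior_lge,
                 timeframes = timeframes),
            class = "mar_study")
}

#' Pipeline configuration
#'
#' @param use_correction,use_priors,use_lge Enable/disable processing
#'   blocks 1 (surface-coil correction), 3 (a-priori regional criteria) and
#'   4 (LGE infarct fusion); block 2 (EM classification) always runs. Used
#'   by the block-ablation analysis.
#' @param em An [em_config()].
#' @param territory_path Optional path to a replacement territory table.
#' @param otsu_bins Histogram bins for the Otsu baseline.
#' @param min_infarct_frac Minimum LGE connected-component size (fraction
#'   of myocardial voxels).
#' @param min_contrast_margin No-signal guard: MaR is segmented only when
#'   the mean culprit-territory intensity exceeds the remote mean by this
#'   relative margin; below it the myocardium is treated as free of MaR
#'   (a two-component EM would otherwise split pure noise).
#' @export
mar_config <- function(use_correction = TRUE, use_priors = TRUE,
                       use_lge = TRUE, em = em_config(),
                       territory_path = NULL, otsu_bins = 256,
                       min_infarct_frac = 0.01, min_contrast_margin = 0.03) {
  list(use_correction = use_correction, use_priors = use_priors,
       use_lge = use_lge, em = em, territory_path = territory_path,
       otsu_bins = otsu_bins, min_infarct_frac = min_infarct_frac,
       min_contrast_margin = min_contrast_margin)
}

# Rasterized geometry shared by the pipeline, the baselines and the
# ablation analysis (rasterization dominates runtime, so it is cached).
prepare_geometry <- function(study, config = mar_config()) {
  table <- if (is.null(config$territory_path)) territory_table()
           else territory_table(config$territory_path)
  extent <- build_maximal_extent(study$culprit, table)
  tf_geo <- list()
  for (tf in study$timeframes) {
    myo <- rasterize_contours(study$contours, study$grid, tf)
    if (!any(myo)) stop(sprintf("timeframe %s: empty myocardial mask", tf))
    centroid <- lv_centroid(study$contours, tf)
    sectors <- divide_sectors(myo, study$grid, centroid, study$rv_anterior)
    levels <- slice_levels(delineated_slices(study$contours, tf),
                           study$grid$n_slices)
    tf_geo[[tf]] <- list(
      myo = myo, sectors = sectors, levels = levels,
      blood = rasterize_blood_pool(study$contours, study$grid, tf),
      remote = remote_region(sectors, extent, levels),
      culprit_vox = extent_voxel_mask(sectors, extent, levels) & myo)
  }
  lge <- NULL
  if (!is.null(study$lge_images)) {
    myo <- rasterize_contours(study$lge_contours, study$lge_grid, "ED")
    centroid <- lv_centroid(study$lge_contours, "ED")
    sectors <- divide_sectors(myo, study$lge_grid, centroid,
                              study$rv_anterior_lge)
    levels <- slice_levels(delineated_slices(study$lge_contours, "ED"),
                           study$lge_grid$n_slices)
    lge <- list(myo = myo, sectors = sectors, levels = levels,
                remote = remote_region(sectors, extent, levels))
  }
  list(extent = extent, tf = tf_geo, lge = lge)
}

#' Run the automatic MaR segmentation pipeline
#'
#' Executes the four processing blocks per timeframe: (1) conditional
#' surface-coil intensity correction, (2) EM classification of myocardial
#' intensities into normal and MaR Gaussian classes initialized from the
#' culprit maximal extent model, (3) a-priori regional criteria (sector-wise
#' decision within the territory, circumferential continuity, assumed
#' transmurality), and (4) fusion of the LGE infarct region so that
#' hypointense microvascular obstruction is included in the MaR. MaR is
#' reported as percent of left-ventricular mass, averaged over the
#' available timeframes.
#'
#' @param study A [mar_study()].
#' @param config A [mar_config()].
#' @param geometry Optional precomputed [prepare_geometry()] result (used
#'   by the ablation analysis to share rasterization across block subsets).
#' @return Object of class `mar_result`: per-timeframe masks, `%LVM`, and
#'   per-block provenance.
#' @export
run_segment_mar <- function(study, config = mar_config(), geometry = NULL) {
  if (is.null(geometry)) geometry <- prepare_geometry(study, config)
  extent <- geometry$extent
  infarct <- NULL
  lge_prov <- NULL
  if (config$use_lge && !is.null(study$lge_images)) {
    if (!config$use_priors) {
      warning("block 4 requires the a-priori block; LGE fusion skipped")
    } else {
      lg <- geometry$lge
      inf <- lge_infarct_helper(study$lge_images, lg$myo, lg$remote,
                                config$min_infarct_frac)
      infarct <- inf$infarct
      lge_prov <- list(threshold = inf$threshold,
                       n_infarct = sum(inf$infarct), n_mvo = sum(inf$mvo))
    }
  } else if (config$use_lge && is.null(study$lge_images)) {
    message("block 4 skipped: no LGE stack")
  }

  masks <- list()
  pct <- c()
  provenance <- list()
  for (tf in study$timeframes) {
    g <- geometry$tf[[tf]]
    img <- study$ce_images[[tf]]

    # block 1: surface-coil intensity correction (conditional)
    detection_img <- img
    if (config$use_correction) {
      cc <- correct_if_beneficial(img, study$grid, g$blood, g$remote,
                                  g$culprit_vox)
      img <- cc$images
      decision <- cc$decision
      # judge territory contrast on the flattest available intensities,
      # even when the correction was declined for output
      if (!is.null(cc$candidate)) detection_img <- cc$candidate
    } else decision <- list(applied = FALSE, reason = "block disabled")

    # block 2: EM classification of myocardial intensities
    intens <- img[g$myo]
    init <- initialize_from_extent(intens, g$culprit_vox[g$myo], config$em)
    fit <- em_fit(intens, init, config$em)
    # no-signal guard: without a hyperintense culprit territory there is no
    # MaR to segment, and a two-component EM would otherwise split noise
    detected <- mean(detection_img[g$culprit_vox]) >
      (1 + config$min_contrast_margin) * mean(detection_img[g$remote])
    post <- array(NA_real_, dim = dim(img))
    post[g$myo] <- if (detected) mar_posterior(intens, fit) else 0

    if (config$use_priors) {
      # block 3: a-priori regional criteria
      raw_labels <- classify_sectors(post, g$sectors, extent, g$levels)
      labels <- enforce_continuity(raw_labels, extent, g$levels)
      fused <- NULL
      if (!is.null(infarct)) {
        # block 4: LGE infarct fusion
        fz <- fuse_lge(labels, infarct, geometry$lge$sectors,
                       geometry$lge$levels, g$levels, extent)
        labels <- fz$labels
        fused <- fz$fused
      }
      mask <- make_transmural(labels, g$sectors)
    } else {
      raw_labels <- labels <- fused <- NULL
      mask <- g$myo & !is.na(post) & post > 0.5
    }

    masks[[tf]] <- mask
    pct[tf] <- 100 * sum(mask) / sum(g$myo)
    provenance[[tf]] <- list(
      correction = decision,
      mixture = unclass(fit)[c("mu_normal", "sigma_normal", "mu_mar",
                               "sigma_mar", "w_mar")],
      em_iterations = attr(fit, "iterations"),
      mar_detected = detected,
      threshold = tryCatch(decision_threshold(fit), error = function(e) NA_real_),
      labels_raw = raw_labels, labels = labels, fused = fused)
  }

  structure(list(masks = masks, percent_lvm = mean(pct),
                 percent_lvm_by_timeframe = pct,
                 provenance = provenance, lge = lge_prov,
                 culprit = study$culprit,
                 blocks = config[c("use_correction", "use_priors", "use_lge")]),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat(sprintf("<mar_result> MaR %.1f %%LVM (%s), culprit %s\n",
              x$percent_lvm,
              paste(sprintf("%s %.1f", names(x$percent_lvm_by_timeframe),
                            x$percent_lvm_by_timeframe), collapse = ", "),
              x$culprit))
  invisible(x)
}
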