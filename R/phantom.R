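#' Specification of a synthetic CE-SSFP + LGE phantom study
#'
#' Describes an annular left-ventricular phantom over a short-axis stack at
#' ED and ES: a transmural, circumferentially contiguous hyperintense MaR
#' wedge inside one coronary territory, an infarct sub-wedge with an
#' optional hypointense microvascular-obstruction (MVO) core, a
#' multiplicative second-order surface-coil gradient, and additive Gaussian
#' noise. Defaults follow typical short-axis acquisitions: 8 mm slices with
#' no gap, 1.5 mm in-plane resolution.
#'
#' @param rows,cols,n_slices,in_plane_spacing,slice_thickness Grid.
#' @param epi_radius,endo_radius ED epicardial / endocardial radii (mm).
#' @param es_scale ES epicardial radius as a fraction of ED; the ES
#'   endocardial radius is chosen to preserve myocardial mass (wall
#'   thickening at systole).
#' @param apex_taper Radius scale factor at the most apical slice (linear
#'   from 1 at the base).
#' @param culprit Culprit artery label.
#' @param wedge_extent Angular extent of the MaR wedge (degrees); the wedge
#'   is clipped to the culprit territory at each slice level.
#' @param wedge_center Wedge center angle (degrees); default is the angular
#'   center of the culprit territory at the mid level.
#' @param contrast MaR / normal-myocardium intensity ratio (>= 1).
#' @param infarct_extent Angular extent of the infarct wedge (default half
#'   the MaR wedge; must not exceed it).
#' @param mvo Whether to plant an MVO core.
#' @param mvo_extent Angular extent of the MVO core (default half the
#'   infarct wedge).
#' @param mvo_radial Radial band of the MVO core as fractions of wall depth
#'   (endo 0 to epi 1); mid-wall so the core is enclosed by infarct
#'   in-plane.
#' @param mvo_attenuation CE-SSFP intensity factor in the MVO core; the
#'   default 0.7 pushes the core below the normal-myocardium mean
#'   (0.7 x 1.3 < 1), so intensity classification alone must miss it and
#'   only LGE fusion can recover it.
#' @param bias Whether to apply the coil gradient.
#' @param bias_coef Coefficients (x, y, x^2, x*y, y^2) of the multiplicative
#'   field `1 + p(x, y)` over in-plane coordinates normalized to `[-1, 1]`.
#'   The default emulates a surface coil at one chest wall: a dominant ramp
#'   with curvature giving roughly a 30 % intensity swing across the
#'   ventricle.
#' @param bias_slice_gain Linear through-plane modulation of the field.
#' @param noise_sd CE-SSFP noise SD as a fraction of the normal-myocardium
#'   mean.
#' @param lge_noise_sd LGE noise SD (absolute, viable myocardium ~0.2).
#' @param rv_anterior,rv_anterior_lge Anterior RV insertion angles.
#' @param center_offset LV center offset from the grid center (mm, x/y).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 128, cols = 128, n_slices = 8,
                         in_plane_spacing = 1.5, slice_thickness = 8,
                         epi_radius = 30, endo_radius = 20, es_scale = 0.85,
                         apex_taper = 0.9, culprit = "LAD",
                         wedge_extent = 90, wedge_center = NULL,
                         contrast = 1.3, infarct_extent = NULL, mvo = TRUE,
                         mvo_extent = NULL, mvo_radial = c(0.25, 0.75),
                         mvo_attenuation = 0.7, bias = TRUE,
                         bias_coef = c(0.10, 0.45, 0.05, 0.08, 0.20),
                         bias_slice_gain = 0.2, noise_sd = 0.05,
                         lge_noise_sd = 0.03, rv_anterior = 120,
                         rv_anterior_lge = 120, center_offset = c(0, 0),
                         seed = 1) {
  if (is.null(infarct_extent)) infarct_extent <- wedge_extent / 2
  if (is.null(mvo_extent)) mvo_extent <- infarct_extent / 2
  if (infarct_extent > wedge_extent)
    stop("infarct extent must not exceed the MaR wedge extent")
  stopifnot(contrast >= 1, noise_sd >= 0, epi_radius > endo_radius,
            mvo_radial[1] >= 0, mvo_radial[2] <= 1,
            mvo_radial[1] < mvo_radial[2])
  spec <- as.list(environment())
  structure(spec, class = "phantom_spec")
}

circle_polygon <- function(center, radius, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

ang_dist <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# base intensities of the phantom signal model (arbitrary units)
phantom_intensities <- list(
  ce = c(background = 0.1, blood = 1.8, myocardium = 1.0),
  lge = c(background = 0.05, blood = 0.6, viable = 0.2,
          infarct = 1.0, mvo = 0.22))

phantom_bias_field <- function(spec, grid) {
  pc <- pixel_centers(grid)
  xn <- 2 * pc$x / (grid$cols * grid$in_plane_spacing) - 1
  yn <- 2 * pc$y / (grid$rows * grid$in_plane_spacing) - 1
  b <- spec$bias_coef
  plane <- 1 + b[1] * xn + b[2] * yn + b[3] * xn^2 + b[4] * xn * yn + b[5] * yn^2
  field <- array(NA_real_, dim = c(grid$rows, grid$cols, grid$n_slices))
  zc <- if (grid$n_slices > 1)
    (seq_len(grid$n_slices) - 1) / (grid$n_slices - 1) - 0.5 else 0
  for (s in seq_len(grid$n_slices))
    field[, , s] <- plane * (1 + spec$bias_slice_gain * zc[s])
  field
}

#' Generate one synthetic phantom study with ground truth
#'
#' Builds contours, CE-SSFP ED/ES stacks, an LGE stack and the ground-truth
#' MaR, infarct and MVO masks from a [phantom_spec()]. The CE-SSFP signal
#' is `base x contrast (in MaR) x MVO attenuation (in the core) x coil
#' field + noise`; the LGE stack has nulled viable myocardium, a
#' hyperenhanced infarct wedge and a hypointense mid-wall MVO core.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_case`: `$study` (a [mar_study()]),
#'   `$truth` (`mar` masks per timeframe, `infarct`, `mvo`,
#'   `percent_lvm`), and `$spec`.
#' @export
generate_case <- function(spec = phantom_spec()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  grid <- voxel_grid(spec$rows, spec$cols, spec$n_slices,
                     spec$in_plane_spacing, spec$slice_thickness)
  center <- c(spec$cols, spec$rows) / 2 * spec$in_plane_spacing +
    spec$center_offset

  # per-slice radii: base-to-apex taper; ES preserves myocardial mass
  taper <- seq(1, spec$apex_taper, length.out = spec$n_slices)
  epi_ed <- spec$epi_radius * taper
  endo_ed <- spec$endo_radius * taper
  epi_es <- spec$es_scale * epi_ed
  endo_es <- sqrt(pmax(epi_es^2 - (epi_ed^2 - endo_ed^2), (0.2 * endo_ed)^2))
  radii <- list(ED = list(epi = epi_ed, endo = endo_ed),
                ES = list(epi = epi_es, endo = endo_es))

  frames <- lapply(radii, function(r)
    lapply(seq_len(spec$n_slices), function(s)
      list(endo = circle_polygon(center, r$endo[s]),
           epi = circle_polygon(center, r$epi[s]))))
  contours <- contour_set(ED = frames$ED, ES = frames$ES)
  lge_contours <- contour_set(ED = frames$ED)

  extent <- build_maximal_extent(spec$culprit)
  levels <- slice_levels(seq_len(spec$n_slices), spec$n_slices)
  wedge_center <- if (is.null(spec$wedge_center))
    (spec$rv_anterior + 15 * arc_center(extent["mid", ])) %% 360
    else spec$wedge_center

  pc <- pixel_centers(grid)
  ang <- (atan2(pc$y - center[2], pc$x - center[1]) * 180 / pi) %% 360
  rad <- sqrt((pc$x - center[1])^2 + (pc$y - center[2])^2)
  field <- phantom_bias_field(spec, grid)

  regions <- function(tf) {
    myo <- rasterize_contours(contours, grid, tf)
    blood <- rasterize_blood_pool(contours, grid, tf, erode = FALSE)
    sectors <- divide_sectors(myo, grid, center, spec$rv_anterior)
    territory <- extent_voxel_mask(sectors, extent, levels)
    in_wedge <- function(extent_deg) {
      w <- array(FALSE, dim = dim(myo))
      for (s in seq_len(spec$n_slices))
        w[, , s] <- ang_dist(ang, wedge_center) <= extent_deg / 2
      w
    }
    mar <- myo & in_wedge(spec$wedge_extent) & territory
    infarct <- myo & in_wedge(spec$infarct_extent) & territory
    mvo <- array(FALSE, dim = dim(myo))
    if (spec$mvo) {
      r <- radii[[tf]]
      for (s in seq_len(spec$n_slices)) {
        depth <- (rad - r$endo[s]) / (r$epi[s] - r$endo[s])
        mvo[, , s] <- myo[, , s] &
          ang_dist(ang, wedge_center) <= spec$mvo_extent / 2 &
          depth >= spec$mvo_radial[1] & depth <= spec$mvo_radial[2]
      }
      mvo <- mvo & infarct
    }
    list(myo = myo, blood = blood, mar = mar, infarct = infarct, mvo = mvo)
  }

  ce_base <- phantom_intensities$ce
  ce_images <- list()
  truth_mar <- list()
  truth_pct <- c()
  reg <- list()
  for (tf in c("ED", "ES")) {
    rg <- regions(tf)
    reg[[tf]] <- rg
    img <- array(ce_base["background"], dim = c(grid$rows, grid$cols,
                                                grid$n_slices))
    img[rg$blood] <- ce_base["blood"]
    img[rg$myo] <- ce_base["myocardium"]
    img[rg$mar] <- img[rg$mar] * spec$contrast
    img[rg$mvo] <- img[rg$mvo] * spec$mvo_attenuation
    if (spec$bias) img <- img * field
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img),
                                sd = spec$noise_sd * ce_base["myocardium"])
    ce_images[[tf]] <- img
    truth_mar[[tf]] <- rg$mar
    truth_pct[tf] <- 100 * sum(rg$mar) / sum(rg$myo)
  }

  lge_base <- phantom_intensities$lge
  rg <- reg$ED
  lge <- array(lge_base["background"], dim = c(grid$rows, grid$cols,
                                               grid$n_slices))
  lge[rg$blood] <- lge_base["blood"]
  lge[rg$myo] <- lge_base["viable"]
  lge[rg$infarct] <- lge_base["infarct"]
  lge[rg$mvo] <- lge_base["mvo"]
  if (spec$lge_noise_sd > 0)
    lge <- lge + stats::rnorm(length(lge), sd = spec$lge_noise_sd)

  study <- mar_study(grid = grid, ce_images = ce_images, contours = contours,
                     culprit = spec$culprit, rv_anterior = spec$rv_anterior,
                     lge_images = lge, lge_contours = lge_contours,
                     rv_anterior_lge = spec$rv_anterior_lge)
  structure(list(
    study = study,
    truth = list(mar = truth_mar, myo = list(ED = reg$ED$myo, ES = reg$ES$myo),
                 infarct = rg$infarct, mvo = rg$mvo,
                 percent_lvm = mean(truth_pct),
                 percent_lvm_by_timeframe = truth_pct),
    spec = spec), class = "phantom_case")
}

#' Generate a reproducible phantom cohort
#'
#' Samples per-case phantom parameters uniformly from the given ranges with
#' a seeded stream. Defaults emulate a clinical acute-infarct population:
#' MaR wedges of 60-150 degrees, contrast ratios 1.2-1.5, noise up to 10 %
#' of the normal-myocardium mean, coil gradient on, and an MVO core in
#' every second case.
#'
#' @param n Number of cases (>= 1).
#' @param seed Cohort seed; per-case seeds are drawn from it.
#' @param wedge_extent,contrast,noise_sd Length-2 ranges sampled uniformly.
#' @param culprit Artery labels sampled per case.
#' @param mvo Logical vector recycled across cases (default: MVO in half).
#' @param ... Further [phantom_spec()] fields held fixed across the cohort.
#' @return List of [generate_case()] results.
#' @export
generate_cohort <- function(n, seed = 1, wedge_extent = c(60, 150),
                            contrast = c(1.2, 1.5), noise_sd = c(0.02, 0.10),
                            culprit = c("LAD", "LCx", "RCA"),
                            mvo = c(TRUE, FALSE), ...) {
  stopifnot(n >= 1, length(wedge_extent) == 2, length(contrast) == 2,
            length(noise_sd) == 2, diff(wedge_extent) >= 0,
            diff(contrast) >= 0, diff(noise_sd) >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  params <- data.frame(
    wedge_extent = stats::runif(n, wedge_extent[1], wedge_extent[2]),
    contrast = stats::runif(n, contrast[1], contrast[2]),
    noise_sd = stats::runif(n, noise_sd[1], noise_sd[2]),
    culprit = sample(culprit, n, replace = TRUE),
    mvo = rep_len(mvo, n),
    seed = sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i)
    generate_case(phantom_spec(
      wedge_extent = params$wedge_extent[i], contrast = params$contrast[i],
      noise_sd = params$noise_sd[i], culprit = params$culprit[i],
      mvo = params$mvo[i], seed = params$seed[i], ...)))
}
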