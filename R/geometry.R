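#' Voxel grid description of a short-axis image stack
#'
#' The image grid on which all masks and intensity volumes live. In-plane
#' resolution is isotropic; slices are ordered base to apex with no gap.
#'
#' @param rows,cols,n_slices Grid dimensions (all >= 1).
#' @param in_plane_spacing In-plane pixel size in mm (isotropic).
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(128, 128, 8, 1.5, 8)
#' @export
voxel_grid <- function(rows, cols, n_slices, in_plane_spacing = 1.5,
                       slice_thickness = 8) {
  stopifnot(rows >= 1, cols >= 1, n_slices >= 1,
            in_plane_spacing > 0, slice_thickness > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 n_slices = as.integer(n_slices),
                 in_plane_spacing = as.numeric(in_plane_spacing),
                 slice_thickness = as.numeric(slice_thickness)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d slices, %.2f mm in-plane, %.1f mm thick\n",
              x$rows, x$cols, x$n_slices, x$in_plane_spacing, x$slice_thickness))
  invisible(x)
}

voxel_volume_mm3 <- function(grid) {
  grid$in_plane_spacing^2 * grid$slice_thickness
}

# mm coordinates of every pixel center on one slice, row-major like R arrays:
# x along columns, y along rows, both measured from the grid corner.
pixel_centers <- function(grid) {
  dx <- grid$in_plane_spacing
  x <- (seq_len(grid$cols) - 0.5) * dx
  y <- (seq_len(grid$rows) - 0.5) * dx
  list(x = matrix(rep(x, each = grid$rows), grid$rows, grid$cols),
       y = matrix(rep(y, times = grid$cols), grid$rows, grid$cols))
}

# rasterize one closed polygon into a logical rows x cols matrix; the
# point-in-polygon test is restricted to the polygon's bounding box
polygon_mask <- function(poly, grid) {
  dx <- grid$in_plane_spacing
  xs <- (seq_len(grid$cols) - 0.5) * dx
  ys <- (seq_len(grid$rows) - 0.5) * dx
  ci <- which(xs >= min(poly[, 1]) - dx & xs <= max(poly[, 1]) + dx)
  ri <- which(ys >= min(poly[, 2]) - dx & ys <= max(poly[, 2]) + dx)
  out <- matrix(FALSE, grid$rows, grid$cols)
  if (length(ci) == 0 || length(ri) == 0) return(out)
  gx <- rep(xs[ci], each = length(ri))
  gy <- rep(ys[ri], times = length(ci))
  out[ri, ci] <- pracma::inpolygon(gx, gy, poly[, 1], poly[, 2])
  out
}

#' Per-slice endocardial and epicardial contours for one or two timeframes
#'
#' Contours are closed simple polygons in mm coordinates (n x 2 matrices,
#' columns x and y; the closing edge from last to first vertex is implicit).
#' Slices without delineation carry `NULL`.
#'
#' @param ED,ES Lists (one element per slice) of `list(endo = , epi = )`
#'   polygon pairs, or `NULL` for an absent timeframe.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(ED = NULL, ES = NULL) {
  cs <- structure(list(ED = ED, ES = ES), class = "contour_set")
  validate_contour_set(cs)
  cs
}

validate_contour_set <- function(cs) {
  for (tf in c("ED", "ES")) {
    frames <- cs[[tf]]
    if (is.null(frames)) next
    for (s in seq_along(frames)) {
      sl <- frames[[s]]
      if (is.null(sl)) next
      for (nm in c("endo", "epi")) {
        p <- sl[[nm]]
        if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
          stop(sprintf("slice %d %s %s: polygon must be an n x 2 matrix, n >= 3",
                       s, tf, nm))
      }
      # epicardial interior must strictly contain the endocardial polygon
      inside <- pracma::inpolygon(sl$endo[, 1], sl$endo[, 2],
                                  sl$epi[, 1], sl$epi[, 2], boundary = TRUE)
      if (!all(inside))
        stop(sprintf("slice %d %s: endocardium not enclosed by epicardium", s, tf))
    }
  }
  invisible(cs)
}

delineated_slices <- function(contours, timeframe) {
  frames <- contours[[timeframe]]
  if (is.null(frames)) return(integer(0))
  which(!vapply(frames, is.null, logical(1)))
}

#' Rasterize endo/epicardial contours into a myocardial mask
#'
#' A pixel belongs to the myocardium when its center lies inside the
#' epicardial polygon and outside the endocardial polygon.
#'
#' @param contours A [contour_set()].
#' @param grid A [voxel_grid()] covering the contour bounding box.
#' @param timeframe `"ED"` or `"ES"`.
#' @return Logical array `rows x cols x n_slices`; `FALSE` everywhere on
#'   slices without delineation.
#' @export
rasterize_contours <- function(contours, grid, timeframe = "ED") {
  validate_contour_set(contours)
  mask <- array(FALSE, dim = c(grid$rows, grid$cols, grid$n_slices))
  for (s in delineated_slices(contours, timeframe)) {
    sl <- contours[[timeframe]][[s]]
    mask[, , s] <- polygon_mask(sl$epi, grid) & !polygon_mask(sl$endo, grid)
  }
  mask
}

# Interior of the endocardium (the blood pool), optionally eroded by one
# pixel to avoid the partial-volume rim.
rasterize_blood_pool <- function(contours, grid, timeframe = "ED", erode = TRUE) {
  mask <- array(FALSE, dim = c(grid$rows, grid$cols, grid$n_slices))
  kern <- matrix(1, 3, 3)
  for (s in delineated_slices(contours, timeframe)) {
    sl <- contours[[timeframe]][[s]]
    in_endo <- polygon_mask(sl$endo, grid)
    if (erode)
      in_endo <- EBImage::erode(in_endo * 1, kern) > 0.5
    mask[, , s] <- in_endo
  }
  mask
}

polygon_centroid <- function(p) {
  # area-weighted centroid of a closed simple polygon (shoelace)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cross) / (6 * a), sum((y + y2) * cross) / (6 * a))
}

#' Per-slice LV centroid from the endocardial contours
#'
#' @inheritParams rasterize_contours
#' @return Numeric matrix `n_slices x 2` (x, y in mm); `NA` rows for slices
#'   without delineation.
#' @export
lv_centroid <- function(contours, timeframe = "ED") {
  frames <- contours[[timeframe]]
  out <- matrix(NA_real_, length(frames), 2)
  for (s in delineated_slices(contours, timeframe))
    out[s, ] <- polygon_centroid(frames[[s]]$endo)
  out
}

#' Divide the myocardium into 24 circumferential sectors
#'
#' Sector 0 starts at the anterior right-ventricular insertion angle and
#' sectors proceed counterclockwise in 15 degree half-open bins
#' `[a, a + 15)`.
#'
#' @param mask Logical myocardial mask (`rows x cols x n_slices`).
#' @param grid The [voxel_grid()] of `mask`.
#' @param centroid `n_slices x 2` matrix of per-slice LV centers (mm), or a
#'   length-2 vector used for all slices.
#' @param rv_anterior Anterior RV insertion angle in degrees `[0, 360)`
#'   (counterclockwise, same frame as the contours); one global value or one
#'   per slice.
#' @return Integer array like `mask` with sector index 0..23 on myocardial
#'   voxels and `NA` elsewhere.
#' @export
divide_sectors <- function(mask, grid, centroid, rv_anterior) {
  if (is.vector(centroid) && length(centroid) == 2)
    centroid <- matrix(centroid, grid$n_slices, 2, byrow = TRUE)
  if (any(rv_anterior < 0 | rv_anterior >= 360))
    stop("rv_anterior must be in [0, 360)")
  rv <- rep_len(rv_anterior, grid$n_slices)
  pc <- pixel_centers(grid)
  dx <- grid$in_plane_spacing
  sectors <- array(NA_integer_, dim = dim(mask))
  for (s in seq_len(grid$n_slices)) {
    m <- mask[, , s]
    if (!any(m)) next
    cx <- centroid[s, 1]; cy <- centroid[s, 2]
    xr <- range(pc$x[m]); yr <- range(pc$y[m])
    if (cx < xr[1] - dx || cx > xr[2] + dx || cy < yr[1] - dx || cy > yr[2] + dx)
      stop(sprintf("slice %d: centroid outside the mask bounding box", s))
    ang <- atan2(pc$y[m] - cy, pc$x[m] - cx) * 180 / pi
    rel <- (ang - rv[s]) %% 360
    sectors[, , s][m] <- as.integer(floor(rel / 15)) %% 24L
  }
  sectors
}

#' Default maximal-extent territory table
#'
#' Reads the shipped per-artery sector coverage table (24 sectors at each of
#' three slice levels). The default is derived from the standard AHA
#' 17-segment coronary assignment, dilated by one 15 degree sector on each
#' circumferential edge so that each territory represents the maximal extent
#' of a proximal occlusion. Users may supply their own table in the same
#' CSV schema (columns `artery`, `level`, `sector`, `covered`).
#'
#' @param path CSV path; default is the table shipped with the package.
#' @return Data frame with columns `artery`, `level`, `sector`, `covered`.
#' @export
territory_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "territory_default.csv", package = "marseg",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("artery", "level", "sector", "covered")
  if (!all(need %in% names(tab)))
    stop("territory table must have columns artery, level, sector, covered")
  tab
}

territory_levels <- c("basal", "mid", "apical")

#' Maximal extent model of a coronary perfusion territory
#'
#' Boolean sector coverage (3 slice levels x 24 sectors) of the largest
#' possible perfusion territory of the culprit artery. `LM` is defined as
#' the union of the LAD and LCx territories.
#'
#' @param culprit One of `"LAD"`, `"LCx"`, `"RCA"`, `"LM"`.
#' @param table A territory table as returned by [territory_table()].
#' @return Logical matrix `3 x 24` (rows basal/mid/apical) of class
#'   `maximal_extent`, with the artery stored as attribute `artery`.
#' @export
build_maximal_extent <- function(culprit, table = territory_table()) {
  if (!is.character(culprit) || length(culprit) != 1 ||
      !culprit %in% c("LAD", "LCx", "RCA", "LM"))
    stop("culprit must be one of LAD, LCx, RCA, LM")
  one <- function(art) {
    ext <- matrix(FALSE, 3, 24, dimnames = list(territory_levels, NULL))
    sub <- table[table$artery == art, ]
    if (nrow(sub) == 0) stop(sprintf("artery %s missing from territory table", art))
    for (i in seq_len(nrow(sub)))
      ext[sub$level[i], sub$sector[i] + 1L] <- sub$covered[i] > 0
    ext
  }
  ext <- if (culprit == "LM") one("LAD") | one("LCx") else one(culprit)
  if (any(rowSums(ext) == 0))
    stop("territory must cover at least one sector at every level")
  structure(ext, class = "maximal_extent", artery = culprit)
}

#' Assign basal/mid/apical levels to delineated slices
#'
#' Slices are ordered base to apex; the delineated range is split into
#' thirds.
#'
#' @param slice_idx Integer indices of delineated slices.
#' @param n_slices Total slice count of the grid.
#' @return Character vector of length `n_slices`; `NA` for slices outside
#'   the delineated range.
#' @export
slice_levels <- function(slice_idx, n_slices) {
  lev <- rep(NA_character_, n_slices)
  if (length(slice_idx) == 0) return(lev)
  thirds <- as.integer(cut(seq_along(slice_idx), breaks = 3, labels = FALSE))
  lev[sort(slice_idx)] <- territory_levels[thirds]
  lev
}

# TRUE where a myocardial voxel's sector is covered by the extent at its
# slice level.
extent_voxel_mask <- function(sector_map, extent, levels) {
  out <- array(FALSE, dim = dim(sector_map))
  for (s in seq_len(dim(sector_map)[3])) {
    if (is.na(levels[s])) next
    sec <- sector_map[, , s]
    sel <- !is.na(sec)
    if (!any(sel)) next
    cov <- extent[levels[s], ]
    out[, , s][sel] <- cov[sec[sel] + 1L]
  }
  out
}

#' Remote myocardium: the region outside the culprit territory
#'
#' Remote myocardium serves as the reference for intensity statistics; it is
#' every myocardial voxel whose sector is not covered by the maximal extent
#' model at that slice level.
#'
#' @param sector_map Integer sector array from [divide_sectors()].
#' @param extent A [build_maximal_extent()] model.
#' @param levels Slice levels from [slice_levels()].
#' @return Logical mask of remote myocardial voxels.
#' @export
remote_region <- function(sector_map, extent, levels) {
  myo <- !is.na(sector_map)
  inext <- extent_voxel_mask(sector_map, extent, levels)
  used <- unique(stats::na.omit(levels))
  if (any(rowSums(extent[used, , drop = FALSE]) == 24))
    stop("extent covers all 24 sectors at a slice level; remote region undefined")
  myo & !inext
}
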