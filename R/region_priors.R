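#' Sector-wise classification within the culprit territory
#'
#' Applies the EM classification sector-wise: a sector covered by the
#' maximal extent model at its slice level is flagged as MaR when the mean
#' MaR posterior over its voxels exceeds 0.5 (strict; a mean of exactly 0.5
#' is not flagged). Sectors outside the extent are never flagged here.
#'
#' @param posterior Numeric array of per-voxel MaR posteriors (NA outside
#'   the myocardium is allowed).
#' @param sector_map Integer sector array from [divide_sectors()].
#' @param extent A [build_maximal_extent()] model.
#' @param levels Slice levels from [slice_levels()].
#' @return Logical matrix `n_slices x 24` of MaR sector flags.
#' @export
classify_sectors <- function(posterior, sector_map, extent, levels) {
  n_sl <- dim(sector_map)[3]
  labels <- matrix(FALSE, n_sl, 24)
  for (s in seq_len(n_sl)) {
    if (is.na(levels[s])) next
    sec <- sector_map[, , s]
    post <- posterior[, , s]
    cov <- extent[levels[s], ]
    for (k in which(cov) - 1L) {
      vox <- which(sec == k)
      if (length(vox) == 0) {
        warning(sprintf("slice %d sector %d: no voxels", s, k))
        next
      }
      labels[s, k + 1L] <- mean(post[vox]) > 0.5
    }
  }
  labels
}

# contiguous runs of flagged sectors under circular adjacency; returns a
# list of integer vectors of 0-based sector indices
circular_runs <- function(flags) {
  idx <- which(flags)
  if (length(idx) == 0) return(list())
  if (length(idx) == 24) return(list(0:23))
  runs <- list()
  cur <- idx[1]
  for (i in idx[-1]) {
    if (i == cur[length(cur)] + 1) cur <- c(cur, i) else {
      runs[[length(runs) + 1]] <- cur
      cur <- i
    }
  }
  runs[[length(runs) + 1]] <- cur
  # merge the wrap-around pair (sector 23 adjacent to sector 0)
  if (length(runs) > 1 && runs[[1]][1] == 1 &&
      runs[[length(runs)]][length(runs[[length(runs)]])] == 24) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  lapply(runs, function(r) r - 1L)
}

# circular center (0-based sector units) of a contiguous covered arc
arc_center <- function(covered) {
  runs <- circular_runs(covered)
  r <- runs[[which.max(lengths(runs))]]
  start <- r[1]
  (start + (length(r) - 1) / 2) %% 24
}

circ_dist <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

#' Keep only the largest contiguous run of MaR sectors per slice
#'
#' MaR is a continuous region within the perfusion territory: on each slice
#' only the largest circumferentially contiguous run of flagged sectors
#' survives. Ties are broken toward the run whose center is closer to the
#' angular center of the culprit territory.
#'
#' @param labels Logical `n_slices x 24` sector flags.
#' @inheritParams classify_sectors
#' @return Filtered logical `n_slices x 24` matrix.
#' @export
enforce_continuity <- function(labels, extent, levels) {
  out <- matrix(FALSE, nrow(labels), 24)
  for (s in seq_len(nrow(labels))) {
    runs <- circular_runs(labels[s, ])
    if (length(runs) == 0) next
    len <- lengths(runs)
    best <- which(len == max(len))
    if (length(best) > 1 && !is.na(levels[s])) {
      ctr <- arc_center(extent[levels[s], ])
      d <- vapply(runs[best], function(r)
        min(circ_dist((r[1] + (length(r) - 1) / 2) %% 24, ctr)), numeric(1))
      best <- best[which.min(d)]
    } else best <- best[1]
    out[s, runs[[best]] + 1L] <- TRUE
  }
  out
}

#' Expand sector flags into a transmural voxel mask
#'
#' Every myocardial voxel of a flagged sector becomes MaR, endocardium to
#' epicardium (MaR is assumed transmural).
#'
#' @inheritParams enforce_continuity
#' @param sector_map Integer sector array from [divide_sectors()].
#' @return Logical voxel mask.
#' @export
make_transmural <- function(labels, sector_map) {
  mask <- array(FALSE, dim = dim(sector_map))
  for (s in seq_len(dim(sector_map)[3])) {
    flagged <- which(labels[s, ]) - 1L
    if (length(flagged) == 0) next
    sec <- sector_map[, , s]
    mask[, , s] <- !is.na(sec) & (sec %in% flagged)
  }
  mask
}

#' Fuse the LGE infarct region into the MaR sector labels
#'
#' Infarcted myocardium is by definition inside the MaR even when
#' microvascular obstruction makes it hypointense on CE-SSFP. Any CE-SSFP
#' sector whose corresponding LGE sector (matched by slice level and sector
#' index) contains infarct is flagged before continuity is re-enforced;
#' infarct-bearing sectors are guaranteed present in the output.
#'
#' @param labels Logical `n_slices x 24` CE-SSFP sector flags.
#' @param infarct Logical LGE infarct voxel mask.
#' @param lge_sector_map Sector map of the LGE stack (its own RV insertion).
#' @param lge_levels,ce_levels Slice levels of the LGE and CE-SSFP stacks.
#' @inheritParams classify_sectors
#' @return `list(labels = , fused = )`: the re-filtered flags and the
#'   logical matrix of sectors forced by LGE fusion (provenance).
#' @export
fuse_lge <- function(labels, infarct, lge_sector_map, lge_levels, ce_levels,
                     extent) {
  if (is.null(infarct)) return(list(labels = labels, fused = labels & FALSE))
  # infarct-bearing (level, sector) pairs on the LGE side
  pairs <- matrix(FALSE, 3, 24, dimnames = list(territory_levels, NULL))
  for (s in seq_len(dim(lge_sector_map)[3])) {
    if (is.na(lge_levels[s])) next
    sec <- lge_sector_map[, , s][infarct[, , s]]
    sec <- unique(sec[!is.na(sec)])
    if (length(sec)) pairs[lge_levels[s], sec + 1L] <- TRUE
  }
  fused <- matrix(FALSE, nrow(labels), 24)
  for (s in seq_len(nrow(labels))) {
    if (is.na(ce_levels[s])) next
    add <- pairs[ce_levels[s], ] & !labels[s, ]
    fused[s, ] <- add
    if (any(pairs[ce_levels[s], ] & !extent[ce_levels[s], ]))
      warning(sprintf("slice %d: infarct outside the culprit territory fused into MaR", s))
  }
  out <- enforce_continuity(labels | fused, extent, ce_levels)
  # infarct-containing sectors always end up in the MaR
  must <- matrix(FALSE, nrow(labels), 24)
  for (s in seq_len(nrow(labels)))
    if (!is.na(ce_levels[s])) must[s, ] <- pairs[ce_levels[s], ]
  list(labels = out | must, fused = fused)
}

#' Simplified LGE infarct delineation
#'
#' Thresholds the LGE myocardium at remote mean + 1.8 SD, discards
#' connected components smaller than a minimum fraction of the myocardium
#' (region analysis), and fills enclosed hypointense regions as
#' microvascular obstruction counted as 100 % infarction.
#'
#' @param images LGE intensity array.
#' @param myo_mask Logical LGE myocardial mask.
#' @param remote_mask Logical LGE remote-myocardium mask (outside the
#'   culprit territory).
#' @param min_region_frac Minimum connected-component size as a fraction of
#'   the myocardial voxel count (default 0.01).
#' @return `list(infarct = , mvo = , threshold = )`; `mvo` is a subset of
#'   `infarct`.
#' @export
lge_infarct_helper <- function(images, myo_mask, remote_mask,
                               min_region_frac = 0.01) {
  if (sum(remote_mask) < 2) stop("LGE remote region is empty")
  thr <- mean(images[remote_mask]) + 1.8 * stats::sd(images[remote_mask])
  supra <- myo_mask & images > thr
  n_myo <- sum(myo_mask)
  infarct <- array(FALSE, dim = dim(images))
  mvo <- array(FALSE, dim = dim(images))
  for (s in seq_len(dim(images)[3])) {
    sl <- supra[, , s]
    if (!any(sl)) next
    lab <- EBImage::bwlabel(sl * 1)
    keep <- which(tabulate(lab[lab > 0]) >= min_region_frac * n_myo)
    sl <- matrix(lab %in% keep, nrow(sl), ncol(sl))
    if (!any(sl)) next
    filled <- EBImage::fillHull(sl * 1) > 0.5
    holes <- filled & !sl & myo_mask[, , s]
    infarct[, , s] <- sl | holes
    mvo[, , s] <- holes
  }
  list(infarct = infarct, mvo = mvo, threshold = thr)
}
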