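#' 2SD-from-remote intensity threshold
#'
#' @param remote Numeric vector of remote-myocardium intensities on the
#'   slice (at least 2 voxels).
#' @return `mean(remote) + 2 * sd(remote)` (sample SD).
#' @export
threshold_2sd <- function(remote) {
  if (length(remote) < 2) stop("2SD threshold needs >= 2 remote voxels")
  mean(remote) + 2 * stats::sd(remote)
}

#' FWHM intensity threshold
#'
#' Midway between the mean remote-myocardium intensity and the maximal
#' intensity within the myocardium on the slice.
#'
#' @param myocardium Numeric vector of all myocardial intensities on the
#'   slice.
#' @param remote Numeric vector of remote intensities on the slice.
#' @return `(mean(remote) + max(myocardium)) / 2`.
#' @export
threshold_fwhm <- function(myocardium, remote) {
  if (length(remote) < 1 || length(myocardium) < 1)
    stop("FWHM threshold needs non-empty remote and myocardium")
  (mean(remote) + max(myocardium)) / 2
}

#' Otsu intensity threshold
#'
#' Histogram threshold minimizing the within-class intensity variance
#' (equivalently maximizing the between-class variance) over the candidate
#' cuts of an equal-width histogram of the slice's myocardial intensities.
#' The returned threshold is the bin boundary of the optimal cut, so it is
#' equivariant under intensity shifts.
#'
#' @param myocardium Numeric vector with at least 2 distinct values.
#' @param bins Number of histogram bins (default 256).
#' @return The threshold intensity.
#' @export
threshold_otsu <- function(myocardium, bins = 256) {
  x <- as.numeric(myocardium)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("Otsu threshold undefined for constant intensities")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L), bins),
                nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  s0 <- cumsum(h * mids)
  mu0 <- s0 / w0
  mu1 <- (sum(h * mids) - s0) / w1
  valid <- seq_len(bins - 1)
  between <- w0[valid] * w1[valid] * (mu0[valid] - mu1[valid])^2
  between[w0[valid] == 0 | w1[valid] == 0] <- -Inf
  k <- valid[which.max(between)]
  breaks[k + 1]
}

#' Threshold-based MaR segmentation, slice by slice
#'
#' The three comparison methods (2SD from remote, FWHM, Otsu) compute and
#' apply their threshold slice by slice on the uncorrected intensities, to
#' account for the intensity gradient across slices; the mask is simply the
#' suprathreshold myocardium with no sector, continuity or LGE
#' post-processing.
#'
#' @param study A [mar_study()].
#' @param method `"2SD"`, `"FWHM"` or `"OTSU"`.
#' @param config A [mar_config()] (`otsu_bins`, territory table).
#' @param geometry Optional precomputed [prepare_geometry()] result.
#' @return Object of class `threshold_result`: per-slice thresholds, masks
#'   per timeframe, `%LVM`, and the method tag.
#' @export
segment_by_threshold <- function(study, method = c("2SD", "FWHM", "OTSU"),
                                 config = mar_config(), geometry = NULL) {
  method <- match.arg(toupper(method), c("2SD", "FWHM", "OTSU"))
  if (is.null(geometry)) geometry <- prepare_geometry(study, config)
  masks <- list(); thresholds <- list(); pct <- c()
  for (tf in study$timeframes) {
    g <- geometry$tf[[tf]]
    img <- study$ce_images[[tf]]
    n_sl <- study$grid$n_slices
    thr <- rep(NA_real_, n_sl)
    mask <- array(FALSE, dim = dim(img))
    for (s in seq_len(n_sl)) {
      myo_s <- g$myo[, , s]
      if (!any(myo_s)) next
      res <- tryCatch({
        thr[s] <- switch(method,
          "2SD" = threshold_2sd(img[, , s][g$remote[, , s]]),
          "FWHM" = threshold_fwhm(img[, , s][myo_s],
                                  img[, , s][g$remote[, , s]]),
          "OTSU" = threshold_otsu(img[, , s][myo_s], config$otsu_bins))
        mask[, , s] <- myo_s & img[, , s] > thr[s]
        TRUE
      }, error = function(e) {
        warning(sprintf("%s slice %d: %s; slice left empty", method, s,
                        conditionMessage(e)))
        FALSE
      })
    }
    masks[[tf]] <- mask
    thresholds[[tf]] <- thr
    pct[tf] <- 100 * sum(mask) / sum(g$myo)
  }
  structure(list(method = method, thresholds = thresholds, masks = masks,
                 percent_lvm = mean(pct), percent_lvm_by_timeframe = pct),
            class = "threshold_result")
}
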