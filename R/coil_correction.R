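#' Fit a second-order surface-coil bias field
#'
#' Surface coils impose a smooth multiplicative intensity gradient
#' (approximately proportional to squared coil distance). The field is
#' modelled per slice as `exp(p(x, y))` with `p` a full degree-2 polynomial
#' (6 coefficients) over normalized in-plane coordinates, fitted by least
#' squares to the log-intensities of blood-pool and remote-myocardium
#' sample voxels after removing each class's per-slice mean log-intensity.
#' Working in the log domain turns the multiplicative coil model into an
#' additive one. Because the two sample classes occupy different parts of
#' the field, their mean-centered responses differ by a class-dependent
#' offset; the fit therefore carries a blood-class indicator column so that
#' this offset cannot leak into the spatial coefficients (which would
#' corrupt the field where only one class samples it). Slices where either
#' sample class has six or fewer voxels inherit the coefficients of the
#' nearest fitted slice.
#'
#' @param images Numeric intensity array `rows x cols x n_slices`.
#' @param grid The [voxel_grid()] of `images`.
#' @param blood_mask,remote_mask Logical sample masks on the same grid.
#' @return Object of class `bias_field_model`: per-slice 6-coefficient rows
#'   (constant, x, y, x^2, x*y, y^2) plus the grid.
#' @export
fit_bias_field <- function(images, grid, blood_mask, remote_mask) {
  n_sl <- grid$n_slices
  coef <- matrix(NA_real_, n_sl, 6)
  design <- bias_design(grid)
  fitted_any <- FALSE
  for (s in seq_len(n_sl)) {
    b <- blood_mask[, , s]; r <- remote_mask[, , s]
    # slices with an empty sample class (e.g. the eroded ES blood pool on
    # apical slices) inherit from the nearest fitted slice
    if (!any(b) || !any(r)) next
    if (sum(b) <= 6 || sum(r) <= 6)
      stop(sprintf("slice %d: need > 6 blood and > 6 remote sample voxels", s))
    ib <- images[, , s][b]; ir <- images[, , s][r]
    if (any(ib <= 0) || any(ir <= 0))
      stop(sprintf("slice %d: non-positive intensities in sample voxels", s))
    resp <- c(log(ib) - mean(log(ib)), log(ir) - mean(log(ir)))
    X <- rbind(design[as.vector(b), , drop = FALSE],
               design[as.vector(r), , drop = FALSE])
    X <- cbind(X, c(rep(1, sum(b)), rep(0, sum(r))))  # blood-class offset
    coef[s, ] <- stats::lm.fit(X, resp)$coefficients[1:6]
    fitted_any <- TRUE
  }
  if (!fitted_any) stop("no slice had sample voxels to fit")
  # slices skipped for lack of samples inherit the nearest fitted slice
  done <- which(!is.na(coef[, 1]))
  for (s in seq_len(n_sl)[-done])
    coef[s, ] <- coef[done[which.min(abs(done - s))], ]
  structure(list(coef = coef, grid = grid), class = "bias_field_model")
}

# degree-2 polynomial design matrix over pixel centers, coordinates
# normalized to [-1, 1] across the grid
bias_design <- function(grid) {
  pc <- pixel_centers(grid)
  xn <- as.vector(2 * pc$x / (grid$cols * grid$in_plane_spacing) - 1)
  yn <- as.vector(2 * pc$y / (grid$rows * grid$in_plane_spacing) - 1)
  cbind(1, xn, yn, xn^2, xn * yn, yn^2)
}

#' Reconstruct the multiplicative bias field
#'
#' @param model A `bias_field_model` from [fit_bias_field()].
#' @return Numeric array of the strictly positive multiplicative field.
#' @export
bias_field <- function(model) {
  grid <- model$grid
  design <- bias_design(grid)
  field <- array(NA_real_, dim = c(grid$rows, grid$cols, grid$n_slices))
  for (s in seq_len(grid$n_slices))
    field[, , s] <- exp(matrix(design %*% model$coef[s, ], grid$rows, grid$cols))
  field
}

apply_bias_correction <- function(images, model, remote_mask) {
  corrected <- images / bias_field(model)
  # preserve the remote-myocardium mean intensity
  corrected * (mean(images[remote_mask]) / mean(corrected[remote_mask]))
}

#' Apply surface-coil correction only when beneficial
#'
#' The correction is accepted only if it reduces intensity variability
#' (coefficient of variation) in the remote myocardium AND leaves the mean
#' intensity in the culprit region higher than in the remote region;
#' otherwise the input is returned unchanged. A failed fit degrades
#' gracefully to "not applied".
#'
#' @inheritParams fit_bias_field
#' @param culprit_mask Logical mask of myocardium inside the culprit
#'   territory.
#' @return `list(images = , decision = , candidate = )` where `decision`
#'   records `applied`, remote CoV before/after, culprit/remote means after
#'   correction, and any fit failure reason. `candidate` always holds the
#'   corrected images when the fit succeeded (even when the correction was
#'   declined for output), for consumers that need the flattest available
#'   intensities.
#' @export
correct_if_beneficial <- function(images, grid, blood_mask, remote_mask,
                                  culprit_mask) {
  if (!any(remote_mask)) stop("remote region is empty")
  cov_before <- stats::sd(images[remote_mask]) / mean(images[remote_mask])
  decision <- list(applied = FALSE, cov_before = cov_before, cov_after = NA_real_,
                   culprit_mean_after = NA_real_, remote_mean_after = NA_real_,
                   reason = NULL)
  model <- tryCatch(fit_bias_field(images, grid, blood_mask, remote_mask),
                    error = function(e) e)
  if (inherits(model, "error")) {
    decision$reason <- conditionMessage(model)
    return(list(images = images, decision = decision, candidate = NULL))
  }
  corrected <- apply_bias_correction(images, model, remote_mask)
  cov_after <- stats::sd(corrected[remote_mask]) / mean(corrected[remote_mask])
  culprit_mean <- mean(corrected[culprit_mask])
  remote_mean <- mean(corrected[remote_mask])
  decision$cov_after <- cov_after
  decision$culprit_mean_after <- culprit_mean
  decision$remote_mean_after <- remote_mean
  if (cov_after < cov_before && culprit_mean > remote_mean) {
    decision$applied <- TRUE
    list(images = corrected, decision = decision, candidate = corrected)
  } else {
    decision$reason <- if (cov_after >= cov_before)
      "remote variability not reduced" else "culprit mean not above remote mean"
    list(images = images, decision = decision, candidate = corrected)
  }
}
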