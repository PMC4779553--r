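#' Dice similarity coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`: 0 when the regions do not overlap, 1
#' when they overlap perfectly. Volumes are voxel counts times the voxel
#' volume, which cancels on a shared grid.
#'
#' @param a,b Logical arrays on the same grid; lists of per-timeframe masks
#'   are pooled, so ED and ES contribute jointly to the volumes.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (is.list(a)) a <- unlist(a)
  if (is.list(b)) b <- unlist(b)
  if (length(a) != length(b)) stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("Dice undefined: both masks empty")
  2 * sum(a & b) / (na + nb)
}

#' MaR as percent of left-ventricular mass
#'
#' Per timeframe `100 * |MaR| / |myocardium|` (uniform tissue density and
#' the voxel volume cancel), averaged over the available timeframes.
#'
#' @param mar_masks,myo_masks Named lists of logical masks per timeframe
#'   (or single arrays).
#' @return Percent in `[0, 100]`.
#' @export
mar_percent_lvm <- function(mar_masks, myo_masks) {
  if (!is.list(mar_masks)) mar_masks <- list(mar_masks)
  if (!is.list(myo_masks)) myo_masks <- list(myo_masks)
  stopifnot(length(mar_masks) == length(myo_masks))
  pct <- mapply(function(mar, myo) {
    if (sum(myo) == 0) stop("empty myocardium")
    if (any(mar & !myo)) stop("MaR mask extends outside the myocardium")
    100 * sum(mar) / sum(myo)
  }, mar_masks, myo_masks)
  mean(pct)
}

#' Bland-Altman agreement analysis
#'
#' Differences `method - reference`; bias is their mean, variability their
#' sample SD, and the limits of agreement are bias -/+ 1.96 SD.
#'
#' @param method,reference Paired numeric vectors (n >= 2).
#' @return `list(bias, sd, limits)` with `limits = c(lower, upper)`.
#' @export
bland_altman <- function(method, reference) {
  stopifnot(length(method) == length(reference))
  if (length(method) < 2) stop("Bland-Altman needs >= 2 pairs")
  d <- method - reference
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, limits = c(bias - 1.96 * s, bias + 1.96 * s))
}

#' Pearson correlation coefficient
#'
#' @param x,y Paired numeric vectors (n >= 2, neither constant).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Two-sided paired t-test with Bonferroni correction
#'
#' @param a,b Paired numeric vectors.
#' @param n_comparisons Number of comparisons in the family; the raw
#'   p-value is multiplied by it and capped at 1.
#' @return `list(t, p, p_adjusted)`.
#' @export
paired_ttest_bonferroni <- function(a, b, n_comparisons = 1) {
  stopifnot(length(a) == length(b), length(a) >= 2, n_comparisons >= 1)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, p_adjusted = 1))
    stop("zero-variance differences")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       p_adjusted = min(1, tt$p.value * n_comparisons))
}

#' Cohort agreement report
#'
#' Summarizes method-vs-reference agreement the way segmentation validation
#' studies report it: Bland-Altman bias (mean and SD of the paired `%LVM`
#' differences), limits of agreement, correlation coefficient, and Dice
#' (mean and SD).
#'
#' @param method_pct,reference_pct Paired `%LVM` values per case.
#' @param dice_values Per-case Dice coefficients.
#' @return `list` with `bias`, `bias_sd`, `limits`, `r`, `dice_mean`,
#'   `dice_sd`, `n`.
#' @export
agreement_report <- function(method_pct, reference_pct, dice_values) {
  ba <- bland_altman(method_pct, reference_pct)
  list(bias = ba$bias, bias_sd = ba$sd, limits = ba$limits,
       r = pearson_r(method_pct, reference_pct),
       dice_mean = mean(dice_values), dice_sd = stats::sd(dice_values),
       n = length(method_pct))
}
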