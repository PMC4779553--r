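#' Two-class Gaussian mixture fit of myocardial intensities
#'
#' Container for the intensity model of normal myocardium and myocardium at
#' risk (MaR). MaR is hyperintense in contrast-enhanced SSFP, so components
#' are always ordered with `mu_mar >= mu_normal`.
#'
#' @param mu_normal,sigma_normal Mean / SD of the normal-myocardium class.
#' @param mu_mar,sigma_mar Mean / SD of the MaR class.
#' @param w_mar Mixing weight of the MaR class, in (0, 1).
#' @return Object of class `gaussian_mixture_fit`.
#' @export
gaussian_mixture_fit <- function(mu_normal, sigma_normal, mu_mar, sigma_mar,
                                 w_mar) {
  stopifnot(sigma_normal > 0, sigma_mar > 0, w_mar > 0, w_mar < 1)
  fit <- list(mu_normal = mu_normal, sigma_normal = sigma_normal,
              mu_mar = mu_mar, sigma_mar = sigma_mar, w_mar = w_mar)
  structure(order_components(fit), class = "gaussian_mixture_fit")
}

order_components <- function(fit) {
  if (fit$mu_mar < fit$mu_normal) {
    fit <- list(mu_normal = fit$mu_mar, sigma_normal = fit$sigma_mar,
                mu_mar = fit$mu_normal, sigma_mar = fit$sigma_normal,
                w_mar = 1 - fit$w_mar)
  }
  fit
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("<gaussian_mixture_fit> normal N(%.4g, %.4g^2), MaR N(%.4g, %.4g^2), w_mar %.3f\n",
              x$mu_normal, x$sigma_normal, x$mu_mar, x$sigma_mar, x$w_mar))
  invisible(x)
}

#' EM configuration
#'
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor_frac Lower bound on component SDs, as a fraction of
#'   the intensity range (guards against collapsing components).
#' @export
em_config <- function(tol = 1e-6, max_iter = 500, sigma_floor_frac = 1e-3) {
  stopifnot(tol > 0, max_iter >= 1, sigma_floor_frac > 0)
  list(tol = tol, max_iter = max_iter, sigma_floor_frac = sigma_floor_frac)
}

#' Initialize the mixture from the maximal extent model
#'
#' Class statistics are seeded from the a-priori territory: voxels inside
#' the culprit territory initialize the MaR component, voxels outside
#' initialize the normal component; the initial weight is the inside
#' fraction.
#'
#' @param intensities Numeric vector of myocardial voxel intensities.
#' @param inside_extent Logical vector, `TRUE` for voxels inside the
#'   culprit maximal extent model.
#' @param config An [em_config()].
#' @return A [gaussian_mixture_fit()].
#' @export
initialize_from_extent <- function(intensities, inside_extent,
                                   config = em_config()) {
  stopifnot(length(intensities) == length(inside_extent))
  if (!any(inside_extent) || all(inside_extent))
    stop("both classes (inside and outside the extent) must be non-empty")
  floor_sd <- sigma_floor(intensities, config)
  inside <- intensities[inside_extent]
  outside <- intensities[!inside_extent]
  sd_in <- stats::sd(inside); sd_out <- stats::sd(outside)
  if (is.na(sd_in) || sd_in == 0) {
    warning("inside-extent sample SD is zero; clamped to sigma floor")
    sd_in <- floor_sd
  }
  if (is.na(sd_out) || sd_out == 0) {
    warning("outside-extent sample SD is zero; clamped to sigma floor")
    sd_out <- floor_sd
  }
  gaussian_mixture_fit(mu_normal = mean(outside), sigma_normal = sd_out,
                       mu_mar = mean(inside), sigma_mar = sd_in,
                       w_mar = mean(inside_extent))
}

sigma_floor <- function(intensities, config) {
  rng <- diff(range(intensities))
  if (rng == 0) rng <- max(abs(intensities), 1)
  config$sigma_floor_frac * rng
}

mixture_loglik <- function(x, fit) {
  sum(log((1 - fit$w_mar) * stats::dnorm(x, fit$mu_normal, fit$sigma_normal) +
          fit$w_mar * stats::dnorm(x, fit$mu_mar, fit$sigma_mar)))
}

#' Expectation-Maximization fit of the two-class intensity mixture
#'
#' Standard EM for a two-component Gaussian mixture: posterior
#' responsibilities in the E-step, weighted mean/SD/weight updates in the
#' M-step, iterated until the relative log-likelihood change falls below
#' tolerance. The log-likelihood is non-decreasing across iterations. A
#' component SD falling below the floor is clamped and flagged.
#'
#' @param intensities Numeric vector (at least two distinct values).
#' @param init A [gaussian_mixture_fit()] starting point, typically from
#'   [initialize_from_extent()].
#' @param config An [em_config()].
#' @return A [gaussian_mixture_fit()] with attributes `loglik` (per-
#'   iteration trace), `iterations`, `converged`, `sigma_clamped`.
#' @export
em_fit <- function(intensities, init, config = em_config()) {
  x <- as.numeric(intensities)
  if (length(unique(x)) < 2)
    stop("intensities are degenerate (fewer than 2 distinct values)")
  floor_sd <- sigma_floor(x, config)
  fit <- init
  clamped <- FALSE
  ll_trace <- mixture_loglik(x, fit)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    # E-step
    p1 <- (1 - fit$w_mar) * stats::dnorm(x, fit$mu_normal, fit$sigma_normal)
    p2 <- fit$w_mar * stats::dnorm(x, fit$mu_mar, fit$sigma_mar)
    tot <- p1 + p2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- p2 / tot
    # M-step
    n2 <- sum(r2); n1 <- length(x) - n2
    mu2 <- sum(r2 * x) / n2
    mu1 <- sum((1 - r2) * x) / n1
    s2 <- sqrt(sum(r2 * (x - mu2)^2) / n2)
    s1 <- sqrt(sum((1 - r2) * (x - mu1)^2) / n1)
    if (s1 < floor_sd) { s1 <- floor_sd; clamped <- TRUE }
    if (s2 < floor_sd) { s2 <- floor_sd; clamped <- TRUE }
    fit <- list(mu_normal = mu1, sigma_normal = s1,
                mu_mar = mu2, sigma_mar = s2, w_mar = n2 / length(x))
    ll <- mixture_loglik(x, fit)
    ll_trace <- c(ll_trace, ll)
    prev <- ll_trace[length(ll_trace) - 1]
    if (abs(ll - prev) < config$tol * abs(prev)) { converged <- TRUE; break }
  }
  fit <- structure(order_components(fit), class = "gaussian_mixture_fit")
  attr(fit, "loglik") <- ll_trace
  attr(fit, "iterations") <- length(ll_trace) - 1
  attr(fit, "converged") <- converged
  attr(fit, "sigma_clamped") <- clamped
  fit
}

#' Posterior probability of the MaR class
#'
#' @param intensities Numeric vector or array.
#' @param fit A [gaussian_mixture_fit()].
#' @return Posterior probabilities in `[0, 1]`, same shape as the input.
#' @export
mar_posterior <- function(intensities, fit) {
  p1 <- (1 - fit$w_mar) * stats::dnorm(intensities, fit$mu_normal, fit$sigma_normal)
  p2 <- fit$w_mar * stats::dnorm(intensities, fit$mu_mar, fit$sigma_mar)
  tot <- p1 + p2
  tot[tot == 0] <- .Machine$double.xmin
  out <- p2 / tot
  if (!is.null(dim(intensities))) dim(out) <- dim(intensities)
  out
}

#' Equal-posterior decision threshold between the two classes
#'
#' The smallest intensity at which the MaR-class posterior reaches 0.5,
#' i.e. the crossing of the two weighted component densities on the
#' hyperintense side. Solved in closed form from the quadratic equality of
#' weighted log-densities.
#'
#' @param fit A [gaussian_mixture_fit()].
#' @return A single intensity value; the MaR posterior there equals 0.5.
#' @export
decision_threshold <- function(fit) {
  m1 <- fit$mu_normal; s1 <- fit$sigma_normal
  m2 <- fit$mu_mar; s2 <- fit$sigma_mar
  w2 <- fit$w_mar; w1 <- 1 - w2
  if (m1 == m2 && s1 == s2)
    stop("identical components: no separating threshold")
  # log(w1 phi1(x)) = log(w2 phi2(x))  =>  a x^2 + b x + c = 0
  a <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  b <- m2 / s2^2 - m1 / s1^2
  cc <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) + log(w2 / s2) - log(w1 / s1)
  if (abs(a) < .Machine$double.eps * max(1, abs(b))) {
    if (b == 0) stop("identical components: no separating threshold")
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("densities never cross: no separating threshold")
    roots <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  }
  # smallest root where the posterior crosses 0.5 upward
  eps <- 1e-9 * max(1, abs(m2 - m1), s1, s2)
  for (r in roots) {
    if (mar_posterior(r + eps, fit) >= 0.5) return(r)
  }
  stop("no upward crossing of posterior 0.5 found")
}
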