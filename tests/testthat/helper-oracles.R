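# Independent brute-force oracles used to cross-check the implementation.

# ray-casting point-in-polygon, written independently of the rasterizer
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# exhaustive within-class variance minimizer over all histogram cuts
oracle_otsu <- function(x, bins = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L), bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  v <- rep(Inf, bins - 1)
  for (k in seq_len(bins - 1)) {
    lo <- mids[bin][bin <= k]; hi <- mids[bin][bin > k]
    if (length(lo) == 0 || length(hi) == 0) next
    v[k] <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }
  breaks[which.min(v) + 1]
}

# largest circumferentially contiguous run of flagged sectors by direct
# enumeration of every candidate run start/length
oracle_largest_run <- function(flags) {
  n <- length(flags)
  if (all(flags)) return(which(flags) - 1L)
  best <- integer(0)
  for (start in seq_len(n)) {
    for (len in seq_len(n)) {
      idx <- ((start - 1 + seq_len(len) - 1) %% n) + 1
      if (all(flags[idx])) {
        if (len > length(best)) best <- as.integer(idx - 1)
      } else break
    }
  }
  sort(best)
}

# random star-convex polygon around a center (radius varies by angle)
random_star_polygon <- function(center, r_base, n = 24) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- r_base * stats::runif(n, 0.6, 1.4)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
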