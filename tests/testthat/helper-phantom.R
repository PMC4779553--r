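# small, fast phantom used by most tests: coarser grid, same physiology
small_spec <- function(...) {
  phantom_spec(rows = 64, cols = 64, in_plane_spacing = 3, n_slices = 6, ...)
}

annulus_contours <- function(epi = 30, endo = 20, n_slices = 1,
                             center = c(48, 48), points = 48) {
  frames <- lapply(seq_len(n_slices), function(s)
    list(endo = circle_poly(center, endo, points),
         epi = circle_poly(center, epi, points)))
  contour_set(ED = frames)
}

circle_poly <- function(center, radius, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
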