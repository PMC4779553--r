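test_that("rasterized annulus area matches the analytic ring area", {
  grid <- voxel_grid(64, 64, 1, in_plane_spacing = 1.5)
  cs <- annulus_contours(epi = 30, endo = 20, center = c(48, 48))
  mask <- rasterize_contours(cs, grid, "ED")
  area <- sum(mask) * 1.5^2
  expect_lt(abs(area - pi * (30^2 - 20^2)) / (pi * (30^2 - 20^2)), 0.02)
})

test_that("rasterization agrees with a point-in-polygon oracle on random star-convex contours", {
  set.seed(11)
  grid <- voxel_grid(40, 40, 1, in_plane_spacing = 2)
  for (rep in 1:5) {
    epi <- random_star_polygon(c(40, 40), 25)
    endo <- epi * 0.4 + matrix(rep(c(40, 40) * 0.6, each = nrow(epi)), ncol = 2)
    cs <- contour_set(ED = list(list(endo = endo, epi = epi)))
    mask <- rasterize_contours(cs, grid, "ED")
    xs <- (seq_len(40) - 0.5) * 2
    for (i in seq(2, 40, by = 3)) for (j in seq(2, 40, by = 3)) {
      expected <- oracle_point_in_polygon(xs[j], xs[i], epi) &&
        !oracle_point_in_polygon(xs[j], xs[i], endo)
      expect_identical(mask[i, j, 1], expected)
    }
  }
})

test_that("degenerate and invalid contours are handled per contract", {
  grid <- voxel_grid(64, 64, 1, in_plane_spacing = 1.5)
  p <- circle_poly(c(48, 48), 25)
  # zero-thickness wall: endo identical to epi
  cs <- contour_set(ED = list(list(endo = p, epi = p)))
  expect_equal(sum(rasterize_contours(cs, grid, "ED")), 0)
  # endocardium sticking out of the epicardium
  expect_error(
    contour_set(ED = list(list(endo = circle_poly(c(60, 48), 25),
                               epi = circle_poly(c(48, 48), 25)))),
    "not enclosed")
  # open / malformed polygon input
  expect_error(contour_set(ED = list(list(endo = p[1:2, ], epi = p))),
               "polygon")
})

test_that("sector division produces 24 approximately uniform sectors", {
  grid <- voxel_grid(64, 64, 1, in_plane_spacing = 1.5)
  cs <- annulus_contours(epi = 30, endo = 20, center = c(48, 48))
  mask <- rasterize_contours(cs, grid, "ED")
  sec <- divide_sectors(mask, grid, c(48, 48), rv_anterior = 77)
  counts <- table(sec[!is.na(sec)])
  expect_equal(length(counts), 24)
  expect_setequal(as.integer(names(counts)), 0:23)
  expect_true(all(abs(counts - mean(counts)) / mean(counts) <= 0.2))
})

test_that("rotating the RV insertion by +15 degrees shifts every label down by one", {
  grid <- voxel_grid(64, 64, 1, in_plane_spacing = 1.5)
  cs <- annulus_contours(epi = 30, endo = 20, center = c(48, 48))
  mask <- rasterize_contours(cs, grid, "ED")
  s0 <- divide_sectors(mask, grid, c(48, 48), rv_anterior = 40)
  s1 <- divide_sectors(mask, grid, c(48, 48), rv_anterior = 55)
  m <- !is.na(s0)
  expect_identical(s1[m], (s0[m] - 1L) %% 24L)
})

test_that("sector boundaries follow the half-open binning convention", {
  # a voxel center exactly on the rv + 15k boundary takes the bin starting there
  grid <- voxel_grid(9, 9, 1, in_plane_spacing = 10)
  cs <- annulus_contours(epi = 40, endo = 12, n_slices = 1, center = c(45, 45))
  mask <- rasterize_contours(cs, grid, "ED")
  sec <- divide_sectors(mask, grid, c(45, 45), rv_anterior = 0)
  # pixel center at (75, 45): angle exactly 0 relative to the insertion
  expect_identical(sec[5, 8, 1], 0L)
  # centroid far outside the mask errors
  expect_error(divide_sectors(mask, grid, c(500, 500), 0), "bounding box")
})

test_that("maximal extent models satisfy the territory invariants", {
  for (artery in c("LAD", "LCx", "RCA", "LM")) {
    ext <- build_maximal_extent(artery)
    expect_equal(dim(ext), c(3, 24))
    expect_true(all(rowSums(ext) >= 1))
    for (lev in rownames(ext)) {
      runs <- marseg:::circular_runs(ext[lev, ])
      expect_length(runs, 1)  # circumferentially contiguous at each level
    }
  }
  lm <- build_maximal_extent("LM")
  expect_identical(unclass(lm) & TRUE,
                   (build_maximal_extent("LAD") | build_maximal_extent("LCx")) & TRUE)
  expect_error(build_maximal_extent("XX"), "culprit")
  # LAD includes the first sector counterclockwise of the anterior insertion
  expect_true(build_maximal_extent("LAD")["mid", 1])
})

test_that("remote region is the exact complement of the territory inside the myocardium", {
  grid <- voxel_grid(64, 64, 3, in_plane_spacing = 1.5)
  cs <- annulus_contours(epi = 30, endo = 20, n_slices = 3, center = c(48, 48))
  mask <- rasterize_contours(cs, grid, "ED")
  sec <- divide_sectors(mask, grid, c(48, 48), 120)
  levels <- slice_levels(1:3, 3)
  ext <- build_maximal_extent("LAD")
  remote <- remote_region(sec, ext, levels)
  inext <- marseg:::extent_voxel_mask(sec, ext, levels)
  expect_identical(remote | inext, !is.na(sec))
  expect_false(any(remote & inext))
  # covered sector count at a level determines the remote sector count
  k <- sum(ext["mid", ])
  expect_equal(length(unique(sec[, , 2][remote[, , 2]])), 24 - k)
  # a territory covering all sectors leaves remote undefined
  full <- ext; full[] <- TRUE
  expect_error(remote_region(sec, full, levels), "remote")
  # an empty extent makes the whole myocardium remote
  none <- ext; none[] <- FALSE; none[, 1] <- TRUE
  expect_equal(sum(remote_region(sec, none, levels)) + sum(sec[!is.na(sec)] == 0),
               sum(!is.na(sec)))
})
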