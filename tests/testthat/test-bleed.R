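# Bleed-through estimation and correction.

test_that("background is the outside-cell median, with fallback", {
  g <- voxel_geometry(108, 108, 200)
  d <- c(32, 32, 8)
  sep <- array(10, d); mt <- array(10, d)
  sep[10:20, 10:20, 3:6] <- 500; mt[10:20, 10:20, 3:6] <- 800
  cell <- array(FALSE, d); cell[8:22, 8:22, 2:7] <- TRUE
  pair <- field_pair(channel_stack(sep, g, "SEP"), channel_stack(mt, g, "MT"))
  bg <- estimate_background(pair, cell)
  expect_equal(bg$bg_sep, 10)
  expect_equal(bg$bg_mt, 10)
  expect_false(bg$fallback)
  # cell covering everything: 1st-percentile fallback, flagged
  bg2 <- estimate_background(pair, array(TRUE, d))
  expect_true(bg2$fallback)
})

test_that("an exact linear relation is recovered exactly", {
  g <- voxel_geometry(108, 108, 200)
  d <- c(48, 48, 8)
  set.seed(12)
  mt <- array(50 + 400 * runif(prod(d)), d)
  sep <- 0.15 * mt + 10
  pair <- field_pair(channel_stack(sep, g, "SEP"), channel_stack(mt, g, "MT"))
  exnuc <- array(TRUE, d)
  est <- estimate_bleed_slope(pair, exnuc, list(bg_sep = 10, bg_mt = 0),
                              min_voxels = 20, floor_k = 0.5)
  expect_equal(est$status, "accepted")
  expect_equal(est$alpha, 0.15, tolerance = 1e-12)
})

test_that("diffuse septin (slope above the bound) is rejected", {
  g <- voxel_geometry(108, 108, 200)
  d <- c(48, 48, 8)
  set.seed(13)
  mt <- array(50 + 400 * runif(prod(d)), d)
  sep <- 1.5 * mt
  pair <- field_pair(channel_stack(sep, g, "SEP"), channel_stack(mt, g, "MT"))
  est <- estimate_bleed_slope(pair, array(TRUE, d),
                              list(bg_sep = 0, bg_mt = 0),
                              min_voxels = 20, floor_k = 0.5)
  expect_equal(est$status, "rejected")
  expect_error(correct_bleed(pair, est), "rejected")
  # between cap and reject bound: capped
  sep2 <- 0.45 * mt
  pair2 <- field_pair(channel_stack(sep2, g, "SEP"), channel_stack(mt, g, "MT"))
  est2 <- estimate_bleed_slope(pair2, array(TRUE, d),
                               list(bg_sep = 0, bg_mt = 0),
                               min_voxels = 20, floor_k = 0.5)
  expect_equal(est2$status, "capped")
  expect_equal(est2$alpha, 0.30)
})

test_that("the correction formula is max(0, SEP - alpha * MT)", {
  g <- voxel_geometry(108, 108, 200)
  sep <- array(10, c(32, 32, 8)); mt <- array(100, c(32, 32, 8))
  pair <- field_pair(channel_stack(sep, g, "SEP"), channel_stack(mt, g, "MT"))
  est <- structure(list(alpha = 0.05, bg_sep = 0, bg_mt = 0,
                        n_voxels_used = 100L, status = "accepted",
                        reason = NA_character_), class = "bleed_estimate")
  corr <- correct_bleed(pair, est)
  expect_true(all(corr == 5))  # 10 - 0.05 * 100
  est$alpha <- 0
  expect_identical(correct_bleed(pair, est), pair$sep$values)
  est$alpha <- 0.1
  expect_true(all(correct_bleed(pair, est) == 0))  # SEP = alpha * MT
  # bounds: non-negative and never above the input
  ph <- fixture_phantom_3d()
  est2 <- structure(list(alpha = 0.2, bg_sep = 0, bg_mt = 0,
                         n_voxels_used = 100L, status = "capped",
                         reason = NA_character_), class = "bleed_estimate")
  corr2 <- correct_bleed(ph$pair, est2)
  expect_true(all(corr2 >= 0))
  expect_true(all(corr2 <= ph$pair$sep$values + 1e-9))
})

test_that("slope recovery on default-noise phantoms", {
  alphas <- sapply(2:4, function(s) {
    ph <- suppressWarnings(make_filament_stack_3d(phantom_spec_3d(
      alpha_true = 0.15, coincidence_fraction = 0, seed = s)))
    cm <- compute_cell_mask(ph$pair)
    masks <- compute_nucleus_mask(ph$pair, cm)
    bg <- estimate_background(ph$pair, cm)
    est <- estimate_bleed_slope(ph$pair, masks$exnuc, bg)
    expect_equal(est$status, "accepted")
    est$alpha
  })
  expect_lt(median(abs(alphas - 0.15)), 0.03)
})
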