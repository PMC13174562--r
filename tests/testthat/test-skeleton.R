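# 3-D thinning, component lengths, pruning.

test_that("a solid tube thins to one centerline of the right length", {
  tb <- make_tube(len = 100, radius = 2.5)
  g <- voxel_geometry(100, 100, 100)  # isotropic 100 nm voxels
  sk <- skeletonize_3d_lee(tb, g)
  expect_equal(nrow(sk$components), 1)
  # 100-voxel tube at 100 nm/voxel = 10 um; within 3 voxels of that
  expect_lt(abs(sk$components$length_um - 10), 0.35)
  expect_true(all(tb[sk$mask]))  # skeleton inside the input mask
})

test_that("degenerate and multi-component masks are handled", {
  g <- voxel_geometry(100, 100, 100)
  single <- array(FALSE, c(9, 9, 5)); single[5, 5, 3] <- TRUE
  sk <- skeletonize_3d_lee(single, g)
  expect_equal(sum(sk$mask), 1)
  expect_equal(sk$components$length_um, 0)
  two <- array(FALSE, c(40, 15, 7))
  two[3:15, 5:7, 3:4] <- TRUE
  two[25:38, 9:11, 3:4] <- TRUE
  expect_equal(nrow(skeletonize_3d_lee(two, g)$components), 2)
  empty <- skeletonize_3d_lee(array(FALSE, c(8, 8, 8)), g)
  expect_equal(sum(empty$mask), 0)
  expect_equal(nrow(empty$components), 0)
})

test_that("anisotropic step costs scale physical lengths", {
  # straight line along z: 20 steps at dz = 200 nm -> 4 um
  m <- array(FALSE, c(9, 9, 24)); m[5, 5, 2:22] <- TRUE
  sk <- skeletonize_3d_lee(m, voxel_geometry(108, 108, 200))
  expect_equal(sk$components$length_um, 20 * 0.2, tolerance = 1e-9)
})

test_that("pruning removes short components and is idempotent", {
  g <- voxel_geometry(1000)  # 1 um per voxel: lengths in voxels = um
  m <- array(FALSE, c(40, 12, 3))
  m[2:3, 2, 2] <- TRUE      # ~1 voxel long
  m[10:12, 5, 2] <- TRUE    # 2 voxels
  m[20:36, 9, 2] <- TRUE    # 16 voxels
  sk <- skeletonize_3d_lee(m, g)
  expect_equal(nrow(sk$components), 3)
  pr <- prune_skeleton(sk, 1.5)
  expect_equal(nrow(pr$components), 2)
  expect_identical(prune_skeleton(pr, 1.5)$mask, pr$mask)
  expect_identical(prune_skeleton(sk, 0)$mask, sk$mask)
  none <- prune_skeleton(sk, 100)
  expect_equal(sum(none$mask), 0)
})

test_that("thinning a 2-D ribbon gives its medial line", {
  rb <- array(FALSE, c(60, 21, 1)); rb[6:55, 8:13, 1] <- TRUE
  sk <- skeletonize_3d_lee(rb, voxel_geometry(1000))
  expect_equal(nrow(sk$components), 1)
  expect_lt(abs(sk$components$length_um - 49), 4)
  # skeleton stays near the ribbon midline (away from the flared ends)
  vox <- which(sk$mask, arr.ind = TRUE)
  interior <- vox[vox[, 1] >= 15 & vox[, 1] <= 45, ]
  expect_true(all(interior[, 2] >= 9 & interior[, 2] <= 12))
})
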