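# Colocalization metrics and the line-profile measurement.

test_that("skeleton-overlap fraction: containment, disjointness, NA", {
  g <- voxel_geometry(108, 108, 200)
  skel <- array(FALSE, c(40, 20, 6)); skel[5:35, 10, 3] <- TRUE
  mask <- array(FALSE, c(40, 20, 6)); mask[4:36, 8:12, 2:4] <- TRUE
  ov <- skeleton_overlap_fraction(skel, mask, 2, g)
  expect_equal(ov$fraction, 1)
  far <- array(FALSE, c(40, 20, 6)); far[5:35, 2, 1] <- TRUE
  ov2 <- skeleton_overlap_fraction(far, mask, 2, g)
  expect_equal(ov2$fraction, 0)
  ov3 <- skeleton_overlap_fraction(array(FALSE, c(10, 10, 2)),
                                   mask[1:10, 1:10, 1:2], 2, g)
  expect_true(is.na(ov3$fraction))
  expect_match(ov3$reason, "empty")
})

test_that("overlap fraction never decreases with dilation radius", {
  set.seed(40)
  g <- voxel_geometry(108, 108, 200)
  for (i in 1:5) {
    skel <- array(runif(20 * 20 * 6) > 0.95, c(20, 20, 6))
    mask <- array(runif(20 * 20 * 6) > 0.8, c(20, 20, 6))
    if (!any(skel)) next
    fr <- sapply(0:4, function(k)
      skeleton_overlap_fraction(skel, mask, k, g)$fraction)
    expect_true(all(diff(fr) >= -1e-12))
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("Manders coefficient: proportionality and invariances", {
  d <- c(30, 30, 4)
  exnuc <- array(TRUE, d)
  mt <- array(FALSE, d)
  mt[1:9, , ] <- TRUE  # 30 percent of the volume
  sep <- array(5, d)   # uniform septin
  expect_equal(manders_coefficient(sep, mt, exnuc), 0.30)
  expect_equal(manders_coefficient(sep * 17, mt, exnuc), 0.30)
  expect_equal(manders_coefficient(sep, array(TRUE, d), exnuc), 1)
  expect_equal(manders_coefficient(sep, array(FALSE, d), exnuc), 0)
  res <- manders_coefficient(array(0, d), mt, exnuc)
  expect_true(is.na(res))
})

test_that("area overlap percent counts reference coverage", {
  a <- matrix(FALSE, 10, 10); b <- matrix(FALSE, 10, 10)
  b[3:6, 3:6] <- TRUE
  a[3:6, 3:4] <- TRUE  # covers half of b
  expect_equal(area_overlap_percent(a, b), 50)
  expect_equal(area_overlap_percent(b, b), 100)
  expect_equal(area_overlap_percent(!b, b), 0)
  expect_true(is.na(area_overlap_percent(a, matrix(FALSE, 10, 10))))
})

test_that("line profiles subtract the background line", {
  img <- matrix(7, 40, 40)
  lp <- line_profile_mean(img, cbind(c(5, 35), c(10, 10)),
                          cbind(c(5, 35), c(30, 30)))
  expect_equal(lp$corrected_mean, 0)
  img2 <- matrix(2, 40, 40); img2[, 9:11] <- 10
  lp2 <- line_profile_mean(img2, cbind(c(5, 35), c(10, 10)),
                           cbind(c(5, 35), c(30, 30)))
  expect_equal(lp2$corrected_mean, 8)
  # diagonal line across a ramp: mean equals the midpoint value
  ramp <- matrix(rep(1:40, each = 40), 40, 40, byrow = TRUE)
  lp3 <- line_profile_mean(ramp, cbind(c(5, 35), c(5, 35)),
                           cbind(c(1, 1), c(1, 2)))
  mid <- ramp[20, 20]
  expect_lt(abs(lp3$mean_intensity - mid) / mid, 0.01)
  expect_error(line_profile_mean(img, cbind(c(5, 60), c(10, 10)),
                                 cbind(c(5, 35), c(30, 30))),
               "outside")
})
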