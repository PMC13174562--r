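# Cardano eigensolver, Frangi vesselness and the 2-D Sato ridge filter.

test_that("Cardano eigenvalues match the iterative solver", {
  set.seed(20)
  max_err <- 0
  for (i in 1:1000) {
    a <- matrix(rnorm(9, sd = runif(1, 0.1, 10)), 3)
    a <- (a + t(a)) / 2
    e <- septcoloc:::.eig3_cardano(a[1, 1], a[2, 2], a[3, 3], a[1, 2], a[1, 3], a[2, 3])
    got <- sort(c(e$lam1, e$lam2, e$lam3))
    ref <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
    max_err <- max(max_err, max(abs(got - ref)))
  }
  expect_lt(max_err, 1e-8)
  # ordering convention and degenerate roots
  e <- septcoloc:::.eig3_cardano(3, 2, 1, 0, 0, 0)
  expect_equal(c(e$lam1, e$lam2, e$lam3), c(1, 2, 3))
  e2 <- septcoloc:::.eig3_cardano(2, 2, 5, 0, 0, 0)
  expect_equal(sort(c(e2$lam1, e2$lam2, e2$lam3)), c(2, 2, 5))
  expect_all_finite(unlist(e2))
})

test_that("Hessian eigenvalues satisfy trace and determinant identities", {
  ph <- fixture_phantom_3d()
  e <- hessian_eigs_cardano(ph$pair$mt, 250)
  g <- ph$pair$mt$geometry
  v <- ph$pair$mt$values
  H <- septcoloc:::.hessian_3d(v, 250, g)
  tr <- H$xx + H$yy + H$zz
  det_h <- H$xx * (H$yy * H$zz - H$yz^2) - H$xy * (H$xy * H$zz - H$yz * H$xz) +
    H$xz * (H$xy * H$yz - H$yy * H$xz)
  scale_tr <- max(abs(tr))
  scale_det <- max(abs(det_h))
  expect_lt(max(abs(e$lam1 + e$lam2 + e$lam3 - tr)) / scale_tr, 1e-6)
  expect_lt(max(abs(e$lam1 * e$lam2 * e$lam3 - det_h)) / scale_det, 1e-6)
})

test_that("Frangi responds to tubes, not blobs or flat fields", {
  g <- voxel_geometry(100, 100, 100)
  expect_equal(max(frangi_3d(array(0, c(24, 24, 12)), geometry = g)), 0)
  d <- c(48, 25, 25)
  tube <- array(0, d)
  for (y in 1:25) for (z in 1:25)
    tube[, y, z] <- 300 * exp(-((y - 13)^2 + (z - 13)^2) / (2 * 2.5^2))
  rp <- ridge_params(frangi_scales_nm = c(150, 250, 400))
  resp_t <- frangi_3d(tube, rp, geometry = g)
  on_axis <- median(resp_t[10:38, 13, 13])
  off_axis <- max(resp_t[10:38, 3, 3])  # 10 px ~ 3 diameters away
  expect_gt(on_axis, 10 * max(off_axis, 1e-6))
  expect_true(all(resp_t >= 0 & resp_t <= 1))
  # equal-intensity isotropic blob: strongly suppressed vs the tube
  blob <- array(0, c(25, 25, 25))
  for (x in 1:25) for (y in 1:25) for (z in 1:25)
    blob[x, y, z] <- 300 * exp(-((x - 13)^2 + (y - 13)^2 + (z - 13)^2) / (2 * 2.5^2))
  resp_b <- frangi_3d(blob, rp, geometry = g)
  expect_lt(resp_b[13, 13, 13], 0.2 * on_axis)
})

test_that("Sato enhances ribbons over disks and is rotation-tolerant", {
  expect_equal(max(sato_2d(matrix(0, 32, 32))), 0)
  img <- matrix(0, 64, 64)
  img[, 31:34] <- 100  # ribbon width 4
  disk <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64)
    if ((i - 32)^2 + (j - 32)^2 <= 16) disk[i, j] <- 100
  r_rib <- sato_2d(img)
  r_disk <- sato_2d(disk)
  expect_gt(median(r_rib[10:54, 32]), 3 * r_disk[32, 32])
  expect_true(all(r_rib >= 0))
  # rotation equivariance within 10 percent: ribbon at 0 vs 37 degrees
  rot <- matrix(0, 101, 101)
  th <- 37 * pi / 180
  for (i in 1:101) for (j in 1:101) {
    dist <- abs(-sin(th) * (i - 51) + cos(th) * (j - 51))
    if (dist <= 2) rot[i, j] <- 100
  }
  r_rot <- sato_2d(rot)
  axis_resp <- function(r, pts) median(r[pts])
  pts0 <- cbind(20:80, 32)
  resp0 <- axis_resp(sato_2d({m <- matrix(0, 101, 101); m[, 31:34] <- 100; m}),
                     cbind(20:80, 32))
  ii <- 20:80
  jj <- round(51 + tan(th) * (ii - 51))
  keep <- jj >= 1 & jj <= 101
  resp37 <- axis_resp(r_rot, cbind(ii[keep], jj[keep]))
  expect_lt(abs(resp37 - resp0) / resp0, 0.10)
})
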