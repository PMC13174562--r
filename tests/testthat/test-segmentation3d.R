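# Cell, nucleus and exNuc segmentation.

test_that("a bright blob on dark background is recovered almost fully", {
  g <- voxel_geometry(108, 108, 200)
  d <- c(64, 64, 12)
  blob <- array(FALSE, d)
  ctr <- (d + 1) / 2
  for (z in 1:d[3]) {
    r2 <- outer(((1:d[1]) - ctr[1]) / 20, ((1:d[2]) - ctr[2]) / 20,
                function(a, b) a^2 + b^2) + ((z - ctr[3]) / 5)^2
    blob[, , z] <- r2 <= 1
  }
  set.seed(11)
  base <- array(rpois(prod(d), 20), d)
  v <- base + blob * 400
  pair <- field_pair(channel_stack(v, g, "SEP"), channel_stack(v, g, "MT"))
  cm <- compute_cell_mask(pair)
  expect_gte(sum(cm & blob) / sum(blob), 0.95)
  # a 2-voxel speck far away does not change the mask
  v2 <- v; v2[3, 3, 2] <- 5000; v2[4, 3, 2] <- 5000
  pair2 <- field_pair(channel_stack(v2, g, "SEP"), channel_stack(v2, g, "MT"))
  cm2 <- compute_cell_mask(pair2)
  expect_gte(sum(cm2 & cm) / sum(cm), 0.98)
  expect_false(cm2[3, 3, 2])
})

test_that("an all-zero stack yields an empty mask with a warning", {
  g <- voxel_geometry(108, 108, 200)
  z <- array(0, c(48, 48, 8))
  pair <- field_pair(channel_stack(z, g, "SEP"), channel_stack(z, g, "MT"))
  expect_warning(cm <- compute_cell_mask(pair), "empty")
  expect_false(any(cm))
})

test_that("the nucleus is recovered on the default phantom", {
  ph <- suppressWarnings(make_filament_stack_3d(phantom_spec_3d(seed = 1)))
  cm <- compute_cell_mask(ph$pair)
  masks <- compute_nucleus_mask(ph$pair, cm)
  tn <- ph$truth$nucleus_true
  expect_gte(sum(masks$nucleus & tn) / sum(tn), 0.8)
  # structural invariants
  expect_true(all(masks$cell[masks$nucleus]))
  expect_false(any(masks$exnuc & masks$nucleus))
  expect_identical(masks$exnuc, masks$cell & !masks$nucleus)
})

test_that("absent nucleus leaves exNuc equal to the cell", {
  ph <- suppressWarnings(make_filament_stack_3d(phantom_spec_3d(
    shape = c(96, 96, 12), n_mt_filaments = 8, n_sep_filaments = 4,
    include_nucleus = FALSE, seed = 6)))
  cm <- compute_cell_mask(ph$pair)
  masks <- compute_nucleus_mask(ph$pair, cm)
  expect_identical(masks$exnuc, masks$cell)
})

test_that("the cell mask is stable under intensity rescaling", {
  ph <- fixture_phantom_3d()
  cm <- compute_cell_mask(ph$pair)
  g <- ph$pair$sep$geometry
  pair10 <- field_pair(channel_stack(ph$pair$sep$values * 10, g, "SEP"),
                       channel_stack(ph$pair$mt$values * 10, g, "MT"))
  cm10 <- compute_cell_mask(pair10)
  agree <- sum(cm & cm10) / sum(cm | cm10)
  expect_gte(agree, 0.98)
})

test_that("candidates at the MT median boundary are rejected", {
  # strict inequality: a candidate whose internal MT median equals the
  # cell-wide median must not become nucleus
  g <- voxel_geometry(108, 108, 200)
  d <- c(48, 48, 8)
  mt <- array(100, d)
  sep <- array(50, d)
  sep[20:28, 20:28, 3:6] <- 400  # diffuse septin blob, same MT as rest
  pair <- field_pair(channel_stack(sep, g, "SEP"), channel_stack(mt, g, "MT"))
  cell <- array(TRUE, d)
  masks <- compute_nucleus_mask(pair, cell)
  expect_false(any(masks$nucleus))
})
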