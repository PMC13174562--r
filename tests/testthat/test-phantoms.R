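# Synthetic generators: determinism, truth consistency, noise-free limit.

test_that("identical spec and seed give bit-identical stacks", {
  sp <- phantom_spec_3d(shape = c(48, 48, 8), n_mt_filaments = 3,
                        n_sep_filaments = 2, seed = 5)
  a <- make_filament_stack_3d(sp)
  b <- make_filament_stack_3d(sp)
  expect_identical(a$pair$sep$values, b$pair$sep$values)
  expect_identical(a$pair$mt$values, b$pair$mt$values)
  expect_identical(a$truth$sep_skeleton_true, b$truth$sep_skeleton_true)
})

test_that("truth skeletons lie inside truth masks; coincidence is exact", {
  ph <- fixture_phantom_3d()
  tr <- ph$truth
  expect_true(all(tr$mt_mask_true[tr$mt_skeleton_true]))
  expect_true(all(tr$sep_mask_true[tr$sep_skeleton_true]))
  recomputed <- sum(tr$sep_skeleton_true & tr$mt_skeleton_true) /
    sum(tr$sep_skeleton_true)
  expect_identical(tr$coincidence_fraction_true, recomputed)
})

test_that("fully coincident septin lies on the microtubule centerlines", {
  sp <- phantom_spec_3d(shape = c(64, 64, 10), n_mt_filaments = 5,
                        n_sep_filaments = 5, coincidence_fraction = 1,
                        seed = 9)
  ph <- make_filament_stack_3d(sp)
  dil <- dilate_voxels(ph$truth$mt_skeleton_true, 1, sp$geometry)
  expect_true(all(dil[ph$truth$sep_skeleton_true]))
  expect_equal(ph$truth$coincidence_fraction_true, 1)
})

test_that("separated septin filaments keep their minimum distance", {
  sp <- phantom_spec_3d(shape = c(96, 96, 12), n_mt_filaments = 6,
                        n_sep_filaments = 4, coincidence_fraction = 0,
                        min_separation_um = 1, seed = 3)
  ph <- make_filament_stack_3d(sp)
  d <- distance_to_mask(ph$truth$mt_skeleton_true, sp$geometry)
  expect_gte(min(d[ph$truth$sep_skeleton_true]), 1000)
  expect_equal(ph$truth$coincidence_fraction_true, 0)
})

test_that("an empty channel stays empty and the noise-free limit is exact", {
  sp <- phantom_spec_3d(shape = c(48, 48, 8), n_mt_filaments = 0,
                        n_sep_filaments = 0, coincidence_fraction = 0,
                        alpha_true = 0, read_noise_sd = 0,
                        background_level = 0, cytoplasm_mt_level = 0,
                        cytoplasm_sep_level = 0, include_nucleus = FALSE,
                        shot_noise = FALSE, denoise_sigma_nm = 0, seed = 2)
  ph <- make_filament_stack_3d(sp)
  expect_true(all(ph$pair$mt$values == 0))
  expect_true(all(ph$pair$sep$values == 0))
  # with a near-delta PSF the noise-free grid is raster + background
  sp2 <- phantom_spec_3d(shape = c(48, 48, 8), n_mt_filaments = 2,
                         n_sep_filaments = 0, coincidence_fraction = 0,
                         alpha_true = 0, read_noise_sd = 0,
                         background_level = 7, cytoplasm_mt_level = 0,
                         cytoplasm_sep_level = 0, include_nucleus = FALSE,
                         filament_intensity = 50,
                         psf_sigma_xy_nm = 1e-3, psf_sigma_z_nm = 1e-3,
                         shot_noise = FALSE, denoise_sigma_nm = 0, seed = 2)
  ph2 <- make_filament_stack_3d(sp2)
  mt <- ph2$pair$mt$values
  on <- ph2$truth$mt_skeleton_true
  expect_equal(unique(round(mt[on], 6)), 57)
  expect_equal(unique(round(mt[!on], 6)), 7)
})

test_that("generator rejects invalid specs", {
  expect_error(phantom_spec_3d(alpha_true = 1), "below 1")
  expect_error(phantom_spec_3d(shape = c(16, 16, 4)))
  expect_error(phantom_spec_3d(coincidence_fraction = 1.2))
})

test_that("bundle fields record their objects and reproduce exactly", {
  sp <- bundle_field_spec(n_singles = 0, n_bundles = 5, n_aggregates = 0,
                          n_puncta = 0, bundle_width_px = c(14, 14),
                          bundle_length_um = c(12.96, 12.96), seed = 4)
  f <- make_bundle_field_2d(sp)
  expect_equal(nrow(f$truth$object_table), 5)
  expect_true(all(f$truth$object_table$class == "bundle"))
  expect_equal(f$truth$object_table$width_px, rep(14, 5))
  f2 <- make_bundle_field_2d(sp)
  expect_identical(f$image, f2$image)
  # aggregates alone: aspect ratios below 3 by construction
  fa <- make_bundle_field_2d(bundle_field_spec(n_singles = 0, n_bundles = 0,
                                               n_aggregates = 3,
                                               n_puncta = 0, seed = 6))
  expect_true(all(fa$truth$object_table$aspect_ratio < 3))
})

test_that("neuron phantom truth records geometry and correlations", {
  sp <- neuron_field_spec(seed = 8, ps9_rho = 1, noise_sd = 0.5)
  nf <- make_neuron_field_2d(sp)
  expect_equal(nf$truth$neurite_lengths_um, sp$neurite_lengths_um)
  # rho = 1: pS9 is an affine function of septin over the truth shaft
  sh <- nf$truth$shaft_mask
  expect_gt(cor(nf$channels$sep9[sh], nf$channels$ps9[sh]), 0.999)
  # the drawn bulb hits its target circularity (Ramanujan-based aspect)
  expect_equal(nf$truth$cone_table$circularity, 0.5)
  expect_gt(nf$truth$cone_table$area_um2, 10)
  # a disk-shaped bulb has circularity ~1 as measured on the raster
  k1 <- septcoloc:::.aspect_for_circularity(1)
  expect_equal(k1, 1)
})

test_that("polarity call is a pure inclusive ratio rule", {
  expect_equal(classify_polarity(c(100, 40, 30))$label, "polarized")
  expect_equal(classify_polarity(c(50, 45, 40))$label, "multipolar")
  expect_equal(classify_polarity(c(80, 40))$label, "polarized")  # exactly 2x
  expect_equal(classify_polarity(42)$label, "polarized")
  # unit invariance
  expect_equal(classify_polarity(c(0.08, 0.04))$label, "polarized")
  expect_error(classify_polarity(numeric(0)))
})
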