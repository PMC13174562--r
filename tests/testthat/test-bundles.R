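# 2-D filament measurement and bundle classification.

test_that("measure_filament recovers rectangle geometry", {
  rect <- matrix(FALSE, 120, 30)
  rect[11:110, 9:22] <- TRUE  # 100 x 14 px
  f <- measure_filament(rect, 0.108)
  expect_lt(abs(f$length_px - 100), 8)
  expect_lt(abs(f$mean_width_px - 14), 1.5)
  expect_gte(f$aspect_ratio, 6)
  disk <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30)
    if ((i - 15)^2 + (j - 15)^2 <= 100) disk[i, j] <- TRUE
  expect_lt(abs(measure_filament(disk, 0.108)$aspect_ratio - 1), 0.05)
  line <- matrix(FALSE, 60, 9); line[6:55, 5] <- TRUE
  expect_lte(measure_filament(line, 0.108)$mean_width_px, 2)
})

test_that("classification applies the width/aspect/length rules", {
  mk <- function(w, a, l) structure(list(length_px = l / 0.108,
                                         length_um = l, mean_width_px = w,
                                         aspect_ratio = a, area_px = 100),
                                    class = "filament_2d")
  fil <- list(mk(2, 8, 15), mk(2, 8, 15), mk(14, 8, 15), mk(14, 8, 15),
              mk(14, 8, 15))
  bs <- classify_and_summarize(fil)
  expect_equal(bs$n_bundles, 3)
  expect_equal(sum(bs$objects$klass == "single"), 2)
  # aspect rule rejects round aggregates; length rule rejects fragments
  expect_equal(classify_and_summarize(list(mk(14, 2, 15)))$n_bundles, 0)
  expect_equal(classify_and_summarize(list(mk(14, 8, 6)))$n_bundles, 0)
  expect_equal(classify_and_summarize(list(mk(14, 8, 6)))$objects$klass,
               "rejected")
  # permutation invariance
  bs2 <- classify_and_summarize(rev(fil))
  expect_equal(bs2$n_bundles, bs$n_bundles)
})

test_that("blank noise fields yield no components", {
  set.seed(50)
  n_comp <- sapply(1:10, function(i) {
    img <- matrix(rnorm(256 * 256, 100, 3), 256, 256)
    max(segment_ridges_2d(img))
  })
  expect_gte(mean(n_comp == 0), 0.9)
})

test_that("a single ribbon is segmented as one covering component", {
  f <- make_bundle_field_2d(bundle_field_spec(
    n_singles = 0, n_bundles = 1, n_aggregates = 0, n_puncta = 0,
    bundle_width_px = c(14, 14), bundle_length_um = c(13, 13), seed = 7))
  lab <- segment_ridges_2d(f$image)
  expect_equal(max(lab), 1)
  # the component covers most of the drawn ribbon
  drawn <- f$image > 150  # ribbon amplitude 150 over bg 100
  expect_gte(sum(lab > 0 & drawn) / sum(drawn), 0.8)
})

test_that("isolated bright puncta never classify as filaments", {
  # saturated puncta leave ring-like halo fragments at segmentation (the
  # line filter suppresses their centers, not their rims); the aspect and
  # length rules reject every one of them
  f <- make_bundle_field_2d(bundle_field_spec(
    n_singles = 0, n_bundles = 0, n_aggregates = 0, n_puncta = 10, seed = 8))
  bs <- quantify_bundles_2d(f$image, f$truth$pixel_size_um)
  expect_equal(bs$n_bundles, 0)
  expect_false(any(bs$objects$klass == "single"))
})

test_that("the full field quantification finds exactly the bundles", {
  f <- make_bundle_field_2d(bundle_field_spec(seed = 3))
  bs <- quantify_bundles_2d(f$image, f$truth$pixel_size_um)
  expect_equal(bs$n_bundles, 5)
  expect_equal(length(bs$bundle_lengths_um), 5)
  expect_true(all(bs$bundle_lengths_um >= 10))
})
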