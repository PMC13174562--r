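# Neuron morphometry: masks, growth cones, shaft, correlations, effects.

test_that("neurite mask keeps the neuron and drops small blobs", {
  nf <- make_neuron_field_2d(neuron_field_spec(seed = 4))
  nm <- neurite_mask(nf$channels$factin, nf$channels$sep9)
  tr <- nf$truth$neuron_mask
  expect_gte(sum(nm & tr) / sum(tr), 0.9)
  # scale invariance by construction
  nm10 <- neurite_mask(nf$channels$factin * 10, nf$channels$sep9 * 10)
  expect_identical(nm, nm10)
  # an isolated small blob above threshold is removed (< 100 px)
  fa <- nf$channels$factin
  fa[10:16, 10:16] <- max(fa)  # 49 px blob
  nm2 <- neurite_mask(fa, nf$channels$sep9)
  expect_false(any(nm2[10:16, 10:16]))
})

test_that("growth cones appear at decorated tips only", {
  nf <- make_neuron_field_2d(neuron_field_spec(seed = 5))
  nm <- neurite_mask(nf$channels$factin, nf$channels$sep9)
  cones <- detect_growth_cones(nm, 0.108)
  expect_length(cones, 1)
  expect_gt(cones[[1]]$area_um2, 5)
  expect_lt(cones[[1]]$circularity, 0.7)
  # flush tips: no cones
  nf0 <- make_neuron_field_2d(neuron_field_spec(seed = 5,
                                                cone_area_um2 = c(NA, NA)))
  nm0 <- neurite_mask(nf0$channels$factin, nf0$channels$sep9)
  expect_length(detect_growth_cones(nm0, 0.108), 0)
})

test_that("mid-shaft varicosities without endpoints are excluded", {
  m <- matrix(FALSE, 160, 60)
  m[11:150, 28:33] <- TRUE            # straight tube, flush ends
  for (i in 1:160) for (j in 1:60)    # wide mid-shaft bump
    if ((i - 80)^2 + (j - 30)^2 <= 13^2) m[i, j] <- TRUE
  cones <- detect_growth_cones(m, 0.108)
  expect_length(cones, 0)
})

test_that("the shaft is elongated, proximal and disjoint from its cone", {
  nf <- make_neuron_field_2d(neuron_field_spec(seed = 6))
  nm <- neurite_mask(nf$channels$factin, nf$channels$sep9)
  cones <- detect_growth_cones(nm, 0.108)
  sh <- shaft_region(nm, cones, 0.108, reach_um = 8)
  expect_gt(sum(sh), 200)
  expect_false(any(sh & cones[[1]]$pixels))
  # longer reach gives a longer shaft (until the neurite is exhausted)
  sh20 <- shaft_region(nm, cones, 0.108, reach_um = 20)
  expect_gt(sum(sh20), sum(sh))
})

test_that("compartment Pearson handles affine, anti and null relations", {
  set.seed(60)
  a <- matrix(rnorm(50 * 50, 100, 10), 50, 50)
  region <- matrix(TRUE, 50, 50)
  r1 <- compartment_pearson(a, 2 * a + 3, region, bg_a = 0, bg_b = 0)
  expect_equal(r1$pearson_r, 1)
  r2 <- compartment_pearson(a, -a, region, bg_a = 0, bg_b = 0,
                            clamp = FALSE)
  expect_equal(r2$pearson_r, -1)
  b <- matrix(rnorm(50 * 50, 100, 10), 50, 50)
  r3 <- compartment_pearson(a, b, region, bg_a = 0, bg_b = 0)
  expect_lt(abs(r3$pearson_r), 0.05)
  # zero variance is a missing value with a reason
  r4 <- compartment_pearson(a, matrix(5, 50, 50), region, bg_a = 0, bg_b = 0)
  expect_true(is.na(r4$pearson_r))
  expect_match(r4$reason, "variance")
  # invariance under positive affine rescaling of either channel
  r5 <- compartment_pearson(3 * a + 7, 0.5 * b + 1, region,
                            bg_a = 0, bg_b = 0)
  expect_equal(r5$pearson_r, r3$pearson_r, tolerance = 1e-12)
})

test_that("Cohen's d uses the n-weighted pooled SD", {
  d <- cohens_d(c(-1, 1), c(0, 2))
  expect_equal(d$cohen_d, 1 / sqrt(2))
  expect_equal(cohens_d(c(0, 2), c(-1, 1))$cohen_d, -1 / sqrt(2))
  expect_true(is.na(cohens_d(c(1, 1), c(2, 2))$cohen_d))
  set.seed(61)
  x <- rnorm(20); y <- rnorm(15, 1)
  pooled <- sqrt((19 * var(x) + 14 * var(y)) / 33)
  expect_equal(cohens_d(x, y)$cohen_d, (mean(y) - mean(x)) / pooled)
})

test_that("growth cones satisfy their defining rules post hoc", {
  for (seed in c(2, 7)) {
    nf <- make_neuron_field_2d(neuron_field_spec(seed = seed))
    nm <- neurite_mask(nf$channels$factin, nf$channels$sep9)
    for (cn in detect_growth_cones(nm, 0.108)) {
      expect_gt(cn$area_um2, 5)
      expect_lt(cn$circularity, 0.7)
    }
  }
})
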