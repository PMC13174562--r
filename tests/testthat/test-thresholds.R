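# Threshold rules: triangle, robust MAD, Otsu wrapper, hysteresis.

test_that("triangle threshold separates a skewed bimodal sample", {
  set.seed(7)
  x <- c(rnorm(10000, 10, 1), rnorm(500, 100, 1))
  thr <- triangle_threshold(x)
  # brute-force oracle: maximize the peak-to-tail perpendicular distance
  # over all bins of the realized 256-bin histogram
  lo <- min(x); hi <- max(x)
  h <- tabulate(pmin(256L, as.integer((x - lo) / (hi - lo) * 256) + 1L),
                nbins = 256)
  peak <- which.max(h)
  tail_bin <- max(which(h > 0))
  idx <- peak:tail_bin
  dist <- abs((h[tail_bin] - h[peak]) * idx - (tail_bin - peak) * h[idx] +
                tail_bin * h[peak] - h[tail_bin] * peak)
  expected <- lo + (idx[which.max(dist)] - 0.5) / 256 * (hi - lo)
  expect_equal(thr, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(thr, 13)
  expect_lt(thr, 97)
})

test_that("triangle threshold handles constants and is affine-equivariant", {
  thr <- triangle_threshold(rep(5, 100))
  expect_equal(as.numeric(thr), 5)
  expect_true(isTRUE(attr(thr, "degenerate")))
  set.seed(1)
  x <- c(rexp(5000, 1 / 10), rnorm(300, 80, 2))
  t0 <- as.numeric(triangle_threshold(x))
  t1 <- as.numeric(triangle_threshold(3 * x + 7))
  bin_w <- 3 * diff(range(x)) / 256
  expect_lt(abs(t1 - (3 * t0 + 7)), bin_w + 1e-9)
})

test_that("MAD threshold follows median + 5 * 1.4826 * MAD", {
  expect_equal(mad_threshold(rep(3, 10)), 3)
  expect_equal(mad_threshold(1:9), 5 + 5 * 1.4826 * 2)
  set.seed(2)
  x <- rnorm(1e6)
  level <- (mad_threshold(x) - mean(x)) / sd(x)
  expect_lt(abs(level - 5), 0.05)
})

test_that("MAD threshold resists saturated outliers where Otsu does not", {
  set.seed(3)
  x <- rnorm(20000, 100, 3)
  x_out <- x
  x_out[seq_len(1000)] <- 65535  # 5 percent saturated pixels
  mad_shift <- abs(mad_threshold(x_out) - mad_threshold(x)) / mad_threshold(x)
  otsu_shift <- abs(otsu_threshold(x_out) - otsu_threshold(x)) /
    otsu_threshold(x)
  expect_lt(mad_shift, 0.05)
  expect_gt(otsu_shift, 0.20)
})

test_that("hysteresis keeps seeded plateaus with their skirts", {
  r <- array(0, c(20, 20, 1))
  r[5:8, 5:8, 1] <- 0.9         # plateau (seed)
  r[9:12, 5:8, 1] <- 0.4        # connected skirt
  r[16:18, 16:18, 1] <- 0.5     # isolated, never seeded
  m <- hysteresis_mask(r, low = 0.3, high = 0.8)
  expect_true(all(m[5:12, 5:8, 1]))
  expect_false(any(m[16:18, 16:18, 1]))
  # low == high collapses to a simple threshold
  m2 <- hysteresis_mask(r, low = 0.5, high = 0.5)
  expect_identical(m2, array(r >= 0.5, dim(r)))
  expect_false(any(hysteresis_mask(r, 0.95, 0.99)))
})

test_that("hysteresis output is monotone in both levels", {
  set.seed(4)
  r <- array(runif(16 * 16 * 4), c(16, 16, 4))
  for (i in 1:5) {
    hi <- runif(1, 0.5, 0.9); lo <- runif(1, 0.1, 0.5)
    base <- hysteresis_mask(r, lo, hi)
    expect_true(all(base[hysteresis_mask(r, lo + 0.05, hi)]))
    expect_true(all(base[hysteresis_mask(r, lo, hi + 0.05)]))
  }
})
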