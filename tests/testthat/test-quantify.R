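# Yen thresholding, per-cell measurement, Mann-Whitney, group comparison.

test_that("a perfectly bimodal image is split between the two values", {
  px <- c(rep(10L, 50), rep(200L, 50))
  thr <- yen_threshold(px)
  expect_gte(thr, 10L)
  expect_lte(thr, 199L)
  expect_equal(sum(px > thr), 50L)  # foreground exactly the 200-valued pixels
})

test_that("yen threshold equals the exhaustive criterion argmax on random histograms", {
  set.seed(29)
  for (i in 1:100) {
    px <- random_pixels()
    expect_identical(yen_threshold(px), oracle_yen(px))
  }
})

test_that("adding a constant shifts the yen threshold by that constant", {
  set.seed(37)
  for (i in 1:20) {
    px <- pmin(200L, pmax(0L, as.integer(random_pixels())))
    c0 <- sample(5:50, 1)
    expect_identical(yen_threshold(px + c0), yen_threshold(px) + c0)
  }
})

test_that("degenerate histograms are rejected", {
  expect_error(yen_threshold(rep(7L, 100)), "degenerate histogram")
  expect_error(yen_threshold(integer(0)), "no pixels")
  expect_error(yen_threshold(c(1, 300)), "outside 0..255")
})

test_that("measure_cell recovers the constructed contrast on clean fields", {
  # noiseless-construction limit: no read noise and no PSF blur, so the
  # segmentation must recover the constructed disc-mask ratio
  sp <- tiny_field_spec(image_size = 160L, n_mitochondria = 8L,
                        mito_intensity = 200, cytosol_intensity = 20,
                        er_intensity = 0, noise_sd = 0, psf_sigma = 0,
                        seed = 41L)
  f <- generate_field(sp)
  m <- measure_cell(f$reporter, f$cell_mask)
  truth <- mean(f$reporter[f$mito_mask]) / mean(f$reporter[f$cell_mask])
  expect_lt(abs(m$intensity_ratio - truth) / truth, 0.05)
  expect_gte(m$intensity_ratio, 1)
  expect_gte(m$mito_area_fraction, 0)
  expect_lte(m$mito_area_fraction, 1)
  # with a realistic PSF on well-resolved organelles the recovered ratio
  # stays within 20% (the threshold admits part of the PSF skirt)
  sp2 <- tiny_field_spec(image_size = 320L, n_mitochondria = 4L,
                         mito_radius = 8, mito_radius_sd = 0,
                         mito_intensity = 200, cytosol_intensity = 20,
                         er_intensity = 0, noise_sd = 1, seed = 41L)
  f2 <- generate_field(sp2)
  m2 <- measure_cell(f2$reporter, f2$cell_mask)
  truth2 <- mean(f2$reporter[f2$mito_mask]) / mean(f2$reporter[f2$cell_mask])
  expect_lt(abs(m2$intensity_ratio - truth2) / truth2, 0.2)
})

test_that("measure_cell rejects empty masks and uniform cells", {
  img <- matrix(10L, 32, 32)
  expect_error(measure_cell(img, matrix(FALSE, 32, 32)), "empty cell mask")
  expect_error(measure_cell(img, matrix(TRUE, 32, 32)), "degenerate histogram")
})

test_that("a cell of pure noise without mitochondria segments less than half its area", {
  # a roomy field: Yen needs a well-sampled histogram to behave on
  # near-unimodal data
  sp <- tiny_field_spec(image_size = 256L, n_mitochondria = 0L,
                        er_intensity = 0,
                        cytosol_intensity = 40, noise_sd = 5, seed = 43L)
  f <- generate_field(sp)
  m <- measure_cell(f$reporter, f$cell_mask)
  expect_lte(m$mito_area_fraction, 0.5)
})

test_that("mann_whitney reproduces the textbook examples", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)
  # identical multisets: U = n1*n2/2 and p = 1
  mw2 <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(mw2$U, 4.5)
  expect_equal(mw2$p_value, 1)
  mw3 <- mann_whitney(c(3, 3), c(3, 3))
  expect_equal(mw3$p_value, 1)
})

test_that("exact p-values match wilcox.test enumeration to 1e-10", {
  set.seed(47)
  for (i in 1:30) {
    x <- rnorm(6); y <- rnorm(6)
    ours <- mann_whitney(x, y)
    expect_equal(ours$method, "exact enumeration")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the normal approximation tracks the exact distribution for small n", {
  # 0.031 is the worst case over every possible U with n1, n2 >= 3 and
  # n1 + n2 <= 12, established by exhaustive enumeration; the continuity
  # correction is what keeps it this tight
  set.seed(53)
  for (i in 1:40) {
    n1 <- sample(3:6, 1); n2 <- sample((8 - n1):min(9, 12 - n1), 1)
    x <- rnorm(n1); y <- rnorm(n2)
    p_exact <- mann_whitney(x, y, method = "exact")$p_value
    p_norm <- mann_whitney(x, y, method = "normal")$p_value
    expect_lt(abs(p_exact - p_norm), 0.031)
  }
})

test_that("U is always within [0, n1*n2] and symmetric under group swap", {
  set.seed(59)
  for (i in 1:20) {
    x <- sample(1:50, 7, replace = TRUE); y <- sample(1:50, 9, replace = TRUE)
    a <- mann_whitney(x, y); b <- mann_whitney(y, x)
    expect_gte(a$U, 0); expect_lte(a$U, 63)
    expect_equal(a$U + b$U, 63)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("compare_groups summarises both metrics and degenerate input gives p = 1", {
  m1 <- measure_cell(generate_field(tiny_field_spec(seed = 61L))$reporter,
                     generate_field(tiny_field_spec(seed = 61L))$cell_mask)
  cmp <- compare_groups(m1, m1, "intensity_ratio")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$group_a$mean, cmp$group_b$mean)
})
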