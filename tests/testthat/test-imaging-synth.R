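# Synthetic two-channel field generator: determinism, mask congruence,
# geometry, experiment assembly, TIFF round-trip.

test_that("identical seeds give bit-identical fields", {
  f1 <- generate_field(tiny_field_spec(seed = 99L))
  f2 <- generate_field(tiny_field_spec(seed = 99L))
  expect_identical(f1$reporter, f2$reporter)
  expect_identical(f1$stain, f2$stain)
  expect_identical(f1$mito_mask, f2$mito_mask)
  f3 <- generate_field(tiny_field_spec(seed = 100L))
  expect_false(identical(f1$reporter, f3$reporter))
})

test_that("pixels respect the declared bit depth and masks are congruent", {
  f <- generate_field(tiny_field_spec(seed = 2L, poisson = TRUE))
  for (ch in list(f$reporter, f$stain)) {
    expect_true(is.integer(ch))
    expect_gte(min(ch), 0L)
    expect_lte(max(ch), 255L)
  }
  expect_true(all(f$mito_mask[f$mito_mask] & f$cell_mask[f$mito_mask]))
  expect_false(any(f$mito_mask & !f$cell_mask))
  expect_false(any(f$er_mask & !f$cell_mask))
})

test_that("the noiseless limit reproduces the constructed intensities", {
  # sparse puncta in a roomy field so plateaus do not overlap
  sp <- tiny_field_spec(image_size = 160L, noise_sd = 0, er_intensity = 0,
                        cytosol_intensity = 0, mito_intensity_sd = 0,
                        mito_radius_sd = 0, n_mitochondria = 3L, seed = 5L)
  f <- generate_field(sp)
  # outside the puncta everything is exactly zero
  expect_equal(sum(f$reporter[!f$cell_mask]), 0L)
  # punctum plateaus reach the specified peak
  expect_equal(max(f$reporter), as.integer(round(sp$mito_intensity)))
  # the disc mask mean is close to the plateau value (edge rolloff only)
  expect_gt(mean(f$reporter[f$mito_mask]), 0.75 * sp$mito_intensity)
  # the stain channel contains mitochondria only
  expect_equal(sum(f$stain[!f$mito_mask] > 0.5 * sp$stain_intensity), 0L)
})

test_that("mito mask area tracks n * pi * r^2 for sparse non-overlapping puncta", {
  sp <- tiny_field_spec(image_size = 256L, n_mitochondria = 8L,
                        mito_radius = 4, mito_radius_sd = 0, seed = 31L)
  f <- generate_field(sp)
  expected <- 8 * pi * 16
  expect_lt(abs(sum(f$mito_mask) - expected) / expected, 0.2)
})

test_that("experiments assemble the requested design", {
  ex <- generate_experiment(tiny_field_spec(), tiny_field_spec(),
                            cells_per_group = 1L, batches = 1L, seed = 4L)
  expect_equal(length(ex$fields), 2L)
  ex2 <- generate_experiment(tiny_field_spec(), tiny_field_spec(mito_intensity = 220),
                             cells_per_group = 6L, batches = 3L, seed = 4L)
  expect_equal(length(ex2$fields), 12L)
  expect_equal(table(ex2$manifest$group), table(rep(c("A", "B"), each = 6)),
               ignore_attr = TRUE)
  expect_equal(sort(unique(ex2$manifest$batch)), 1:3)
  # batches are balanced across groups
  expect_equal(as.integer(table(ex2$manifest$batch)), c(4L, 4L, 4L))
  # determinism at the experiment level
  ex3 <- generate_experiment(tiny_field_spec(), tiny_field_spec(mito_intensity = 220),
                             cells_per_group = 6L, batches = 3L, seed = 4L)
  expect_identical(ex2$fields[[5]]$reporter, ex3$fields[[5]]$reporter)
  expect_identical(ex2$manifest, ex3$manifest)
})

test_that("group contrast offsets propagate to the measured ratios", {
  ex <- generate_experiment(tiny_field_spec(mito_intensity = 90),
                            tiny_field_spec(mito_intensity = 200),
                            cells_per_group = 5L, batches = 1L, seed = 8L)
  cells <- measure_experiment(ex)
  expect_gt(mean(cells$intensity_ratio[cells$group == "B"]),
            mean(cells$intensity_ratio[cells$group == "A"]))
})

test_that("experiments round-trip through TIFF + manifest on disk", {
  ex <- generate_experiment(tiny_field_spec(), tiny_field_spec(),
                            cells_per_group = 1L, batches = 1L, seed = 12L)
  dir <- tempfile("expt_")
  man <- write_experiment(ex, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- read_channel_tiff(man$reporter_path[1])
  expect_identical(back, ex$fields[[1]]$reporter)
  mask <- read_channel_tiff(man$cell_mask_path[1]) > 0
  expect_identical(mask, ex$fields[[1]]$cell_mask)
})
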