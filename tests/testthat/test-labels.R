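# Air segmentation, instance splitting, and mIoU scoring.

test_that("air segmentation is exact on a noise-free two-level image", {
  u <- generate_unit(acc_spec("isotropic", 1, noise_sd = 0))
  vol <- phantom_volume(u, "expiration")
  img <- render_grayscale(vol, 0)
  mask <- segment_air(img)
  expect_identical(mask, array(vol$voxels > 0L, dim(vol$voxels)))
  # inverted contrast with the flag gives the same mask
  expect_identical(segment_air(max(img) + min(img) - img, invert = TRUE),
                   mask)
})

test_that("air segmentation tolerates realistic noise", {
  u <- generate_unit(acc_spec("isotropic", 2, noise_sd = 10))
  vol <- phantom_volume(u, "expiration")
  img <- render_grayscale(vol, 10, seed = 3)
  mask <- segment_air(img)
  agreement <- mean(mask == (vol$voxels > 0L))
  expect_gte(agreement, 0.99)
})

test_that("contrast failure is detected on structureless images", {
  flat <- array(100, c(8, 8, 8))
  expect_error(segment_air(flat), "contrast failure")
  noise <- array(rnorm(512, 100, 5), c(8, 8, 8))
  expect_error(segment_air(noise), "contrast failure")
  expect_error(segment_air(array(c(NA, 1), c(2, 1, 1))), "finite")
})

test_that("splitting separates bridged lumina and leaves isolated ones intact", {
  neck <- neck_fixture()
  labs <- split_instances(neck, spacing = 1, min_volume = 50)
  expect_length(label_counts(labs), 2L)

  s <- icosphere(10, 3)
  attr(s, "label") <- 1L
  vol <- voxelize(list(s), 1)
  one <- split_instances(vol$voxels > 0L, spacing = 1)
  expect_length(label_counts(one), 1L)
  expect_identical(one$voxels > 0L, vol$voxels > 0L)
})

test_that("splitting recovers duct plus alveoli on a phantom and is idempotent", {
  u <- generate_unit(acc_spec("isotropic", 3, noise_sd = 0))
  vol <- phantom_volume(u, "expiration")
  labs <- split_instances(vol$voxels > 0L, spacing = vol$spacing)
  expect_length(label_counts(labs), u$spec$n_alveoli + 1L)
  # label 1 is the largest instance (the duct)
  cnt <- label_counts(labs)
  expect_equal(which.max(cnt), 1L, ignore_attr = TRUE)
  expect_equal(duct_label(labs), 1L)
  # air voxels are conserved up to the logged minimum-volume filter
  removed <- attr(labs, "removed")
  expect_equal(sum(labs$voxels > 0L) + sum(removed$voxels),
               sum(vol$voxels > 0L))
  # idempotence: splitting its own output changes nothing
  again <- split_instances(labs)
  expect_identical(again$voxels, labs$voxels)
})

test_that("empty masks raise a no-structure error", {
  expect_error(split_instances(array(FALSE, c(4, 4, 4)), spacing = 1),
               "no structure")
})

test_that("mIoU matches its boundary cases and is symmetric", {
  u <- generate_unit(acc_spec("isotropic", 1, noise_sd = 0))
  vol <- phantom_volume(u, "expiration")
  expect_equal(miou(vol, vol), 1)

  a <- array(0L, c(4, 4, 4)); a[1:2, , ] <- 1L
  b <- array(0L, c(4, 4, 4)); b[3:4, , ] <- 1L
  expect_equal(miou(a, b), 0)

  # reference with two equal classes, prediction missing one entirely
  r <- array(0L, c(4, 4, 4)); r[1:2, , ] <- 1L; r[3:4, , ] <- 2L
  p <- array(0L, c(4, 4, 4)); p[1:2, , ] <- 1L
  expect_equal(miou(p, r), 0.5)
  expect_equal(miou(r, p), 0.5)              # symmetric after matching

  expect_error(miou(a, array(0L, c(3, 3, 3))), "mismatch")
})

test_that("segmentation plus splitting reproduces the reference labeling", {
  u <- generate_unit(acc_spec("alveolus_dominant", 2, noise_sd = 10))
  vol <- phantom_volume(u, "expiration")
  img <- render_grayscale(vol, 10, seed = 11)
  labs <- split_instances(segment_air(img), spacing = vol$spacing)
  expect_gte(miou(labs, vol), 0.95)
})
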