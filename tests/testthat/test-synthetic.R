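# Synthetic stimulus-response generator: structure, determinism, category
# separability, noise calibration, and ground-truth recovery hooks.

test_that("the generated image set follows the dataset structure", {
  spec <- reduced_synth_spec(seed = 1)
  expect_equal(spec$n_train, spec$n_categories * spec$images_per_category)
  imgs <- gen_images(spec)
  expect_equal(dim(imgs$train), c(32, 32, 3, 300))
  expect_equal(dim(imgs$test), c(32, 32, 3, 20))
  expect_equal(length(unique(imgs$train_categories)), 75)
  expect_true(all(table(imgs$train_categories) == 4))
  # test categories are novel
  expect_length(intersect(imgs$train_categories, imgs$test_categories), 0)
  expect_true(all(imgs$train >= 0 & imgs$train <= 1))
  # bitwise determinism per seed
  expect_identical(imgs$train, gen_images(spec)$train)
  expect_false(identical(imgs$train,
                         gen_images(reduced_synth_spec(seed = 2))$train))
})

test_that("within-category images correlate more than between-category", {
  spec <- reduced_synth_spec(seed = 3, n_categories = 10L,
                             images_per_category = 4L, n_test = 2L)
  imgs <- gen_images(spec)
  flat <- matrix(imgs$train, nrow = prod(dim(imgs$train)[1:3]))
  cm <- cor(flat)
  same <- outer(imgs$train_categories, imgs$train_categories, "==")
  diag(same) <- NA
  within <- mean(cm[which(same)], na.rm = TRUE)
  between <- mean(cm[which(!same)], na.rm = TRUE)
  expect_gt(within, between)
})

test_that("responses are linear in features at sigma zero, with 35 repeats", {
  spec <- reduced_synth_spec(noise_sd = 0, seed = 4)
  set.seed(4)
  Ftr <- matrix(rnorm(spec$n_train * 30), spec$n_train)
  Fte <- matrix(rnorm(spec$n_test * 30), spec$n_test)
  truth <- gen_ground_truth(Ftr, spec)
  expect_true(all(colSums(truth$W != 0) == spec$sparsity))
  resp <- gen_responses(Ftr, Fte, truth, spec)
  expect_equal(unname(resp$train),
               unname(sweep(Ftr %*% truth$W, 2, truth$b, "+")),
               tolerance = 1e-12)
  expect_equal(nrow(resp$test), spec$n_test * 35L)
  expect_true(all(table(resp$presentation_map) == 35))
  # noiseless repeats of the same image are identical
  first <- resp$presentation_map[1]
  rows <- which(resp$presentation_map == first)
  expect_equal(resp$test[rows[1], ], resp$test[rows[2], ])
  # signal calibration: unit SD of the noiseless training response
  expect_equal(unname(apply(resp$train, 2, sd)),
               rep(1, ncol(resp$train)), tolerance = 1e-8)
})

test_that("trial noise variance matches sigma^2 at 1750 test trials", {
  spec <- synth_spec(n_categories = 10L, images_per_category = 4L,
                     n_test = 50L, test_repeats = 35L, image_size = 16L,
                     n_voxels_per_roi = 2L, sparsity = 3L,
                     noise_sd = 0.8, seed = 5L)
  set.seed(5)
  Ftr <- matrix(rnorm(40 * 25), 40)
  Fte <- matrix(rnorm(50 * 25), 50)
  truth <- gen_ground_truth(Ftr, spec)
  resp <- gen_responses(Ftr, Fte, truth, spec)
  expect_equal(nrow(resp$test), 1750L)
  # residual around each image's per-voxel mean is pure noise
  centered <- resp$test -
    average_repeats(resp$test, resp$presentation_map)[resp$presentation_map, ]
  n <- nrow(centered)
  se <- 0.8^2 * sqrt(2 / (n - 50))
  for (j in seq_len(ncol(centered))) {
    v <- sum(centered[, j]^2) / (n - 50)
    expect_lt(abs(v - 0.64), 3 * se)
  }
})

test_that("fingerprint and width mismatches against the ground truth are rejected", {
  spec <- reduced_synth_spec(seed = 6)
  Ftr <- matrix(rnorm(spec$n_train * 20), spec$n_train)
  truth <- gen_ground_truth(Ftr, spec)
  expect_error(gen_responses(Ftr[, 1:10], Ftr[1:20, 1:10], truth, spec),
               "width")
})

test_that("the fixture bundle is complete and seed-sensitive", {
  fx <- make_fixture(reduced_synth_spec(noise_sd = 0.5, seed = 7,
                                        n_categories = 20L,
                                        images_per_category = 2L,
                                        n_test = 5L))
  expect_s3_class(fx$features_train, "feature_stack")
  expect_equal(fx$features_train$batch, 40L)
  expect_equal(nrow(fx$rois), 14L)
  expect_equal(ncol(fx$responses$train), 14L)
  expect_equal(nrow(fx$responses$test), 5L * 35L)
  fx2 <- make_fixture(reduced_synth_spec(noise_sd = 0.5, seed = 8,
                                         n_categories = 20L,
                                         images_per_category = 2L,
                                         n_test = 5L))
  expect_equal(dim(fx2$responses$train), dim(fx$responses$train))
  expect_false(identical(fx2$responses$train, fx$responses$train))
})
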