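# Synthetic stimulus-response generator. Emulates the structure of the
# image-presentation fMRI dataset the encoding analysis assumes: 1200
# training images (150 categories x 8 exemplars), 50 test images each
# presented 35 times, and voxel responses that are sparse linear functions
# of true image features plus Gaussian noise. Ground truth is retained so
# recovery is checkable end to end.

#' Synthetic dataset specification
#'
#' Defaults mirror the study conditions of the emulated dataset: 1200
#' training images over 150 categories (8 per category), 50 test images
#' presented 35 times each, and seven visual ROIs. `noise_sd` is expressed
#' in units of the per-voxel signal standard deviation (the generator scales
#' every voxel's noiseless response to unit SD).
#'
#' @param n_categories,images_per_category Training-set structure; the
#'   number of training images is their product.
#' @param n_test Number of test images (one novel category each).
#' @param test_repeats Presentations per test image.
#' @param image_size Image side in pixels.
#' @param n_voxels_per_roi Voxels simulated in each ROI.
#' @param rois Base region names.
#' @param sparsity True nonzero feature weights per voxel.
#' @param noise_sd Trial noise SD relative to unit signal SD.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_categories = 150L, images_per_category = 8L,
                       n_test = 50L, test_repeats = 35L, image_size = 224L,
                       n_voxels_per_roi = 100L,
                       rois = c("V1", "V2", "V3", "V4", "LOC", "FFA", "PPA"),
                       sparsity = 10L, noise_sd = 1, seed = 1L) {
  stopifnot(n_categories >= 1, images_per_category >= 1, n_test >= 1,
            test_repeats >= 1, image_size >= 8, n_voxels_per_roi >= 1,
            sparsity >= 1, noise_sd >= 0)
  structure(list(n_train = as.integer(n_categories * images_per_category),
                 n_categories = as.integer(n_categories),
                 images_per_category = as.integer(images_per_category),
                 n_test = as.integer(n_test),
                 test_repeats = as.integer(test_repeats),
                 image_size = as.integer(image_size),
                 n_voxels_per_roi = as.integer(n_voxels_per_roi),
                 rois = rois, sparsity = as.integer(sparsity),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Reduced desk-scale specification
#'
#' Keeps the dataset's structure (category-organized training set, 35-times
#' repeated test presentations, seven ROIs) at a size where the whole
#' pipeline runs in seconds: 300 training images (75 x 4), 20 test images,
#' 32-pixel images, 2 voxels per ROI.
#'
#' @inheritParams synth_spec
#' @return A `synth_spec`.
#' @export
reduced_synth_spec <- function(noise_sd = 0, seed = 1L,
                               n_categories = 75L, images_per_category = 4L,
                               n_test = 20L, n_voxels_per_roi = 2L) {
  synth_spec(n_categories = n_categories,
             images_per_category = images_per_category, n_test = n_test,
             test_repeats = 35L, image_size = 32L,
             n_voxels_per_roi = n_voxels_per_roi, sparsity = 5L,
             noise_sd = noise_sd, seed = seed)
}

gabor_patch <- function(size, theta, freq, phase, u0, v0, sigma) {
  x <- matrix(seq_len(size), size, size) - u0
  y <- matrix(seq_len(size), size, size, byrow = TRUE) - v0
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * freq * xr + phase)
}

draw_category_params <- function(size, n_gabors = 4L) {
  lapply(seq_len(n_gabors), function(i)
    list(theta = runif(1, 0, pi),
         freq = runif(1, 0.06, 0.25),
         phase = runif(1, 0, 2 * pi),
         u0 = runif(1, 0.25, 0.75) * size,
         v0 = runif(1, 0.25, 0.75) * size,
         sigma = runif(1, 0.10, 0.30) * size,
         amp = runif(1, 0.5, 1.5),
         chan = runif(3, 0.2, 1)))
}

render_image <- function(size, params, jitter_sd) {
  img <- array(0, dim = c(size, size, 3))
  for (p in params) {
    g <- gabor_patch(size,
                     p$theta + rnorm(1, 0, jitter_sd),
                     p$freq * exp(rnorm(1, 0, jitter_sd)),
                     p$phase + rnorm(1, 0, 4 * jitter_sd),
                     p$u0 + rnorm(1, 0, jitter_sd * size),
                     p$v0 + rnorm(1, 0, jitter_sd * size),
                     p$sigma) * p$amp
    for (ch in 1:3) img[, , ch] <- img[, , ch] + g * p$chan[ch]
  }
  img <- img + array(rnorm(length(img), 0, 0.02), dim = dim(img))
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  img
}

#' Generate the synthetic image set
#'
#' Each category is a fixed mixture of oriented Gabor textures; exemplars
#' within a category share the mixture and differ by small parameter jitter,
#' so categories are discriminable by convolutional features. Test images
#' come from novel categories. Deterministic given the spec seed; pixel
#' values lie in `[0, 1]`.
#'
#' @param spec A [synth_spec()].
#' @return List with `train`/`test` image arrays `(H, W, 3, N)` and
#'   `train_categories`/`test_categories` labels.
#' @export
gen_images <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  size <- spec$image_size
  jit <- 0.04
  train <- array(0, dim = c(size, size, 3, spec$n_train))
  train_cat <- integer(spec$n_train)
  i <- 0L
  for (cc in seq_len(spec$n_categories)) {
    params <- draw_category_params(size)
    for (j in seq_len(spec$images_per_category)) {
      i <- i + 1L
      train[, , , i] <- render_image(size, params, jit)
      train_cat[i] <- cc
    }
  }
  test <- array(0, dim = c(size, size, 3, spec$n_test))
  test_cat <- integer(spec$n_test)
  for (tt in seq_len(spec$n_test)) {
    params <- draw_category_params(size)
    test[, , , tt] <- render_image(size, params, jit)
    test_cat[tt] <- spec$n_categories + tt
  }
  list(train = train, test = test,
       train_categories = train_cat, test_categories = test_cat)
}

voxel_id_table <- function(spec) {
  regions <- lapply(setNames(spec$rois, spec$rois), function(r)
    sprintf("%s_%03d", r, seq_len(spec$n_voxels_per_roi)))
  roi_map(regions)
}

#' Generate per-voxel sparse ground-truth weights
#'
#' Each voxel gets `sparsity` nonzero weights at uniformly random feature
#' coordinates, magnitudes drawn from a two-sided uniform range, then
#' rescaled so the voxel's noiseless training response has unit standard
#' deviation (making `noise_sd` a signal-relative unit).
#'
#' @param features_train Training feature matrix or [feature_stack()].
#' @param spec A [synth_spec()].
#' @return List of class `ground_truth`: `W` (`n_features x n_voxels`), `b`,
#'   `sigma`, `voxel_ids`, and feature-space fingerprints.
#' @export
gen_ground_truth <- function(features_train, spec) {
  fp <- if (inherits(features_train, "feature_stack"))
    features_train$backbone else NULL
  F <- as_feature_mat(features_train)
  rois <- voxel_id_table(spec)
  n_vox <- nrow(rois)
  set.seed(spec$seed + 1000L)
  W <- matrix(0, ncol(F), n_vox)
  b <- runif(n_vox, -0.5, 0.5)
  for (j in seq_len(n_vox)) {
    supp <- sample.int(ncol(F), spec$sparsity)
    w <- runif(spec$sparsity, 0.5, 1.5) * sample(c(-1, 1), spec$sparsity,
                                                 replace = TRUE)
    sig <- drop(F[, supp, drop = FALSE] %*% w)
    s <- sd(sig)
    if (s > 0) w <- w / s
    W[supp, j] <- w
  }
  structure(list(W = W, b = b, sigma = spec$noise_sd,
                 voxel_ids = rois$voxel_id,
                 n_features = ncol(F),
                 feature_fingerprint = fp),
            class = "ground_truth")
}

#' Generate voxel responses from features and ground truth
#'
#' Training responses are `F W + b` plus Gaussian noise of SD `sigma`; each
#' test image is replicated `test_repeats` times in a randomized
#' presentation order with independent noise per trial.
#'
#' @param features_train,features_test Feature matrices or
#'   [feature_stack()]s over the ground truth's feature space.
#' @param truth A [gen_ground_truth()] result.
#' @param spec A [synth_spec()].
#' @return List with `train` (`m x voxels`), `test` (`trials x voxels`),
#'   `presentation_map` (image id per test trial), `image_ids`.
#' @export
gen_responses <- function(features_train, features_test, truth, spec) {
  check_fp <- function(f) {
    if (inherits(f, "feature_stack") &&
        !is.null(truth$feature_fingerprint) &&
        !identical(unname(f$backbone), unname(truth$feature_fingerprint)))
      stop("feature fingerprint does not match the ground truth's ",
           "feature space")
    as_feature_mat(f)
  }
  Ftr <- check_fp(features_train)
  Fte <- check_fp(features_test)
  if (ncol(Ftr) != truth$n_features || ncol(Fte) != truth$n_features)
    stop("feature width does not match the ground truth")
  n_vox <- length(truth$voxel_ids)
  set.seed(spec$seed + 2000L)
  train <- sweep(Ftr %*% truth$W, 2L, truth$b, "+") +
    matrix(rnorm(nrow(Ftr) * n_vox, 0, truth$sigma), nrow(Ftr))
  image_ids <- sprintf("img%03d", seq_len(spec$n_test))
  pm <- sample(rep(image_ids, each = spec$test_repeats))
  rows <- match(pm, image_ids)
  test <- sweep(Fte[rows, , drop = FALSE] %*% truth$W, 2L, truth$b, "+") +
    matrix(rnorm(length(pm) * n_vox, 0, truth$sigma), length(pm))
  colnames(train) <- truth$voxel_ids
  colnames(test) <- truth$voxel_ids
  list(train = train, test = test, presentation_map = pm,
       image_ids = image_ids)
}

#' Build a complete synthetic fixture bundle
#'
#' One call produces everything the pipeline consumes: images, reduced
#' backbones with globally pooled taps, V/R/M features for both splits,
#' ground truth, train/test responses, and the ROI map. Optionally written
#' to a directory in the package's container layout.
#'
#' @param spec A [synth_spec()] (default [reduced_synth_spec()]).
#' @param dir Optional output directory.
#' @return The bundle list (invisibly the same object that was written).
#' @export
make_fixture <- function(spec = reduced_synth_spec(), dir = NULL) {
  imgs <- gen_images(spec)
  vgg <- build_vgg16(vgg16_config("reduced", input_size = spec$image_size,
                                  seed = spec$seed, tap_pool = TRUE))
  rep <- build_replknet(replknet_config("reduced",
                                        input_size = spec$image_size,
                                        seed = spec$seed, tap_pool = TRUE))
  xtr <- normalize_images(imgs$train)
  xte <- normalize_images(imgs$test)
  M_train <- merge_features(extract_V(vgg, xtr), extract_R(rep, xtr))
  M_test <- merge_features(extract_V(vgg, xte), extract_R(rep, xte))
  truth <- gen_ground_truth(M_train, spec)
  resp <- gen_responses(M_train, M_test, truth, spec)
  rois <- voxel_id_table(spec)
  bundle <- list(spec = spec, images = imgs,
                 features_train = M_train, features_test = M_test,
                 truth = truth, responses = resp, rois = rois,
                 backbones = list(vgg16 = vgg, replknet = rep))
  if (!is.null(dir)) write_fixture(bundle, dir)
  bundle
}
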