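# Builders, convolution arithmetic, forward determinism, weight containers,
# and structural-reparameterization fusion.

test_that("VGG16-style graph has 13 convolutions and the six documented taps", {
  g <- build_vgg16()
  expect_equal(sum(vapply(g$layers, function(l) l$type == "conv",
                          logical(1))), 13L)
  sh <- graph_tap_shapes(g)
  expect_named(sh, c("blockA", "blockB", "blockC", "blockD", "blockE",
                     "blockE_pool"))
  expect_equal(sh$blockA, c(64L, 224L, 224L))
  expect_equal(sh$blockB, c(128L, 112L, 112L))
  expect_equal(sh$blockC, c(256L, 56L, 56L))
  expect_equal(sh$blockD, c(512L, 28L, 28L))
  expect_equal(sh$blockE, c(512L, 14L, 14L))
  expect_equal(sh$blockE_pool, c(512L, 7L, 7L))
})

test_that("RepLKNet-style graph taps follow the stage ladder", {
  g <- build_replknet()
  sh <- graph_tap_shapes(g)
  expect_named(sh, paste0("stage", 1:4))
  expect_equal(unname(vapply(sh, function(s) s[2], integer(1))),
               c(56L, 28L, 14L, 7L))
  expect_equal(unname(vapply(sh, function(s) s[1], integer(1))),
               c(128L, 256L, 512L, 1024L))
  # reduced variant keeps the topology at a smaller scale
  r <- build_replknet(replknet_config("reduced"))
  shr <- graph_tap_shapes(r)
  expect_equal(unname(vapply(shr, function(s) s[2], integer(1))),
               c(8L, 4L, 2L, 1L))
})

test_that("forward propagation of a zero image yields finite activations of the analytic shapes", {
  g <- build_vgg16(vgg16_config("reduced"))
  z <- array(0, dim = c(32, 32, 3))
  st <- forward_features(g, z)
  sh <- graph_tap_shapes(g)
  for (nm in names(st$layers)) {
    a <- st$layers[[nm]]
    expect_true(all(is.finite(a)))
    expect_equal(dim(a)[1:3], unname(sh[[nm]][c(2, 3, 1)]))
  }
})

test_that("graph convolution matches the direct-summation oracle", {
  set.seed(42)
  # 2-conv toy stack on a 5x5 single-channel input
  g <- conv_stack_graph(c(3L, 3L), channels = 1L, input_size = 5L, seed = 7)
  x <- array(rnorm(25), dim = c(5, 5, 1))
  got <- forward_layer(g$layers[[1]], x)
  l1 <- g$layers[[1]]
  exp1 <- oracle_conv2d(x, l1$w, l1$b, stride = 1, pad = 1)
  expect_equal(got, exp1, tolerance = 1e-12)
  l2 <- g$layers[[2]]
  expect_equal(forward_layer(l2, exp1),
               oracle_conv2d(exp1, l2$w, l2$b, stride = 1, pad = 1),
               tolerance = 1e-12)
  # randomized instances up to 8x8: strides, padding, groups
  for (i in 1:12) {
    n <- sample(3:8, 1); k <- sample(c(1, 3, 5), 1)
    groups <- sample(c(1, 2), 1)
    cin <- groups * sample(1:2, 1); cout <- groups * sample(1:2, 1)
    stride <- sample(1:2, 1); pad <- sample(0:2, 1)
    if (n + 2 * pad < k) next
    sp <- conv_spec(k, cin, cout, stride = stride, padding = pad,
                    groups = groups)
    w <- array(rnorm(k * k * (cin / groups) * cout),
               dim = c(k, k, cin / groups, cout))
    b <- rnorm(cout)
    x <- array(rnorm(n * n * cin), dim = c(n, n, cin))
    expect_equal(forward_layer(layer_conv(sp, w = w, b = b), x),
                 oracle_conv2d(x, w, b, stride, pad, groups),
                 tolerance = 1e-10)
  }
  # interior value of an all-ones 3x3 kernel on an all-ones image is 9
  sp <- conv_spec(3, 1, 1, padding = 1)
  ones <- array(1, dim = c(6, 6, 1))
  out <- forward_layer(layer_conv(sp, w = array(1, c(3, 3, 1, 1)),
                                  b = 0), ones)
  expect_equal(out[3, 3, 1], 9)
})

test_that("builds are seed-deterministic and forwards are batch-pure", {
  g1 <- build_vgg16(vgg16_config("reduced", seed = 5))
  g2 <- build_vgg16(vgg16_config("reduced", seed = 5))
  expect_identical(g1, g2)
  g3 <- build_vgg16(vgg16_config("reduced", seed = 6))
  expect_false(identical(g1$layers[[1]]$w, g3$layers[[1]]$w))

  set.seed(1)
  x <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3))
  batch <- array(c(x, x), dim = c(32, 32, 3, 2))
  st <- forward_features(g1, batch)
  for (a in st$layers)
    expect_identical(a[, , , 1], a[, , , 2])
  expect_identical(forward_features(g1, x), forward_features(g1, x))
})

test_that("image shape mismatches are rejected with both shapes named", {
  g <- build_vgg16(vgg16_config("reduced"))
  bad <- array(0, dim = c(16, 16, 3))
  expect_error(forward_features(g, bad), "expected.*3,32,32.*3,16,16")
})

test_that("identity blocks reduce the large-kernel net to stem + transitions", {
  cfg <- replknet_config("reduced", channels = c(4L, 4L, 4L, 4L))
  g <- build_replknet(cfg)
  delta <- function(k, ch) {
    w <- array(0, dim = c(k, k, 1, ch))
    w[(k + 1) / 2, (k + 1) / 2, 1, ] <- 1
    w
  }
  eye1x1 <- function(ch) {
    w <- array(0, dim = c(1, 1, ch, ch))
    for (c in seq_len(ch)) w[1, 1, c, c] <- 1
    w
  }
  stem_len <- 12L  # 4 conv-bn-relu triples
  g$layers <- lapply(seq_along(g$layers), function(i) {
    l <- g$layers[[i]]
    if (i <= stem_len) return(l)
    if (l$type == "bn") {
      l$eps <- 0
    } else if (l$type == "reparam") {
      ch <- l$large$spec$out_channels
      l$large$w <- delta(l$large$spec$kernel_size, ch)
      l$small$w[] <- 0
      l$bn_large$eps <- 0
      l$bn_small$eps <- 0
    } else if (l$type == "conv" && l$spec$kernel_size == 1L &&
               l$spec$in_channels == l$spec$out_channels &&
               l$spec$groups == 1L) {
      l$w <- eye1x1(l$spec$in_channels)
    } else if (l$type == "conv" && l$spec$groups == l$spec$in_channels) {
      l$w <- delta(l$spec$kernel_size, l$spec$out_channels)
    }
    l
  })
  set.seed(3)
  x <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3))
  st <- forward_features(g, x)
  stem_graph <- backbone_graph(g$layers[seq_len(stem_len)],
                               data.frame(name = "stem", index = stem_len,
                                          pooled = FALSE),
                               input_shape = g$input_shape)
  stem_out <- forward_features(stem_graph, x)$layers$stem
  # identity blocks: stage 1 reproduces the stem output exactly
  expect_equal(st$layers$stage1, stem_out, tolerance = 1e-12)
  # later stages only subsample (stride-2 delta kernels): values are a
  # subset of the previous stage's values
  s1 <- as.vector(st$layers$stage1)
  s2 <- as.vector(st$layers$stage2)
  expect_true(all(s2 %in% s1))
})

test_that("weight containers round-trip and reject shape mismatches by layer", {
  g <- build_replknet(replknet_config("reduced", seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_backbone_weights(g, path)
  g2 <- build_replknet(replknet_config("reduced", seed = 99,
                                       weights_path = path))
  set.seed(8)
  x <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3))
  expect_equal(forward_features(g2, x)$layers$stage4,
               forward_features(g, x)$layers$stage4)
  # corrupt one tensor: the loader names the first mismatched key
  w <- readRDS(path)
  w[["stem1_conv/weight"]] <- w[["stem1_conv/weight"]][, , , 1:2]
  saveRDS(w, path)
  expect_error(load_backbone_weights(g, path),
               "shape mismatch at 'stem1_conv/weight'")
})

test_that("reparam fusion folds BN and pads the small kernel", {
  set.seed(11)
  # zero small branch: fused kernel equals the BN-folded large kernel
  br <- random_dw_branch(ch = 3)
  br$small$w[] <- 0
  br$bn_small$scale[] <- 0
  br$bn_small$shift[] <- 0
  f <- fuse_reparam_branch(br)
  gain <- br$bn_large$scale / sqrt(br$bn_large$var + br$bn_large$eps)
  expect_equal(f$w, br$large$w * rep(gain, each = 49), tolerance = 1e-12)
  # identity BN on both branches: large kernel + center-padded small kernel
  br2 <- random_dw_branch(ch = 2)
  for (side in c("bn_large", "bn_small")) {
    br2[[side]]$scale[] <- 1; br2[[side]]$shift[] <- 0
    br2[[side]]$mean[] <- 0; br2[[side]]$var[] <- 1; br2[[side]]$eps <- 0
  }
  f2 <- fuse_reparam_branch(br2)
  pad <- array(0, dim = dim(br2$large$w))
  pad[3:5, 3:5, , ] <- br2$small$w
  expect_equal(f2$w, br2$large$w + pad, tolerance = 1e-12)
  expect_equal(f2$b, rep(0, 2))
})

test_that("fused and two-branch forwards agree within 1e-4 relative", {
  set.seed(21)
  worst <- 0
  for (i in 1:20) {
    ch <- sample(2:5, 1)
    br <- random_dw_branch(ch = ch)
    f <- fuse_reparam_branch(br)
    x <- array(rnorm(10 * 10 * ch), dim = c(10, 10, ch))
    two <- forward_layer(br, x)
    one <- forward_layer(layer_conv(f$spec, w = f$w, b = f$b), x)
    worst <- max(worst, max(abs(two - one)) / max(abs(two)))
  }
  expect_lt(worst, 1e-4)
})

test_that("malformed reparam branches are rejected", {
  mk <- function(k, stride = 1L, ch = 2L) {
    sp <- conv_spec(k, ch, ch, stride = stride,
                    padding = (k - 1L) %/% 2L, groups = ch, has_bias = FALSE)
    layer_conv(sp)
  }
  bn <- layer_bn(2L)
  expect_error(reparam_branch(mk(7), mk(4), bn, bn), "odd")
  expect_error(reparam_branch(mk(7), mk(3, stride = 2L), bn, bn),
               "stride")
  expect_error(reparam_branch(mk(3), mk(7), bn, bn), "small kernel")
})
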