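# Backbone builders: a small-kernel VGG16-style extractor and a large-kernel
# RepLKNet-style extractor, both as explicit layer graphs with named feature
# taps. Inference only: batch normalization always runs with frozen statistics.

#' Backbone feature graph
#'
#' An ordered list of layers plus named tap points. Taps are ordered shallow
#' to deep; forwarding one conforming image yields exactly one activation per
#' tap. A tap may be marked `pooled`, in which case the tapped activation is
#' globally average-pooled to a per-channel vector when features are read out
#' (the in-stream activation is unchanged).
#'
#' @param layers List of layer objects.
#' @param taps Data frame with columns `name`, `index`, `pooled`.
#' @param input_shape Integer vector `(channels, rows, cols)`.
#' @param name Backbone identifier.
#' @param variant Configuration variant label.
#' @return An object of class `backbone_graph`.
#' @export
backbone_graph <- function(layers, taps, input_shape, name = "backbone",
                           variant = "custom") {
  stopifnot(is.list(layers), length(input_shape) == 3)
  taps <- as.data.frame(taps)
  stopifnot(all(c("name", "index", "pooled") %in% names(taps)))
  if (anyDuplicated(taps$name)) stop("tap names must be unique")
  if (is.unsorted(taps$index)) stop("taps must be ordered shallow to deep")
  if (any(taps$index < 1 | taps$index > length(layers)))
    stop("tap index out of range")
  structure(list(layers = layers, taps = taps,
                 input_shape = as.integer(input_shape), name = name,
                 variant = variant),
            class = "backbone_graph")
}

#' @export
print.backbone_graph <- function(x, ...) {
  cat("<backbone_graph> ", x$name, " (", x$variant, ")\n", sep = "")
  cat("  input:", paste(x$input_shape, collapse = "x"), "\n")
  cat("  layers:", length(x$layers), " (",
      sum(vapply(x$layers, function(l) l$type == "conv", logical(1))),
      " conv, ",
      sum(vapply(x$layers, function(l) l$type == "reparam", logical(1))),
      " reparam)\n", sep = "")
  sh <- graph_tap_shapes(x)
  for (i in seq_len(nrow(x$taps)))
    cat("  tap ", x$taps$name[i], ": ",
        paste(sh[[i]], collapse = "x"),
        if (x$taps$pooled[i]) " (pooled)" else "", "\n", sep = "")
  invisible(x)
}

#' Per-tap activation shapes, computed analytically
#'
#' @param graph A [backbone_graph()].
#' @return Named list of `(channels, rows, cols)` shapes, one per tap
#'   (pooled taps report `(channels, 1, 1)`).
#' @export
graph_tap_shapes <- function(graph) {
  shape <- graph$input_shape
  shapes <- vector("list", nrow(graph$taps))
  names(shapes) <- graph$taps$name
  ti <- 1L
  for (i in seq_along(graph$layers)) {
    shape <- layer_out_shape(graph$layers[[i]], shape)
    while (ti <= nrow(graph$taps) && graph$taps$index[ti] == i) {
      shapes[[ti]] <- if (graph$taps$pooled[ti]) c(shape[1], 1L, 1L) else shape
      ti <- ti + 1L
    }
  }
  shapes
}

n_conv_layers <- function(graph)
  sum(vapply(graph$layers, function(l) l$type %in% c("conv", "reparam"),
             logical(1)))

# Cheap content fingerprint used for provenance checks between artifacts.
fingerprint <- function(x) {
  v <- unlist(x, use.names = FALSE)
  v <- v[is.finite(v)]
  sprintf("fp-%d-%.10e-%.10e", length(v), sum(v), sum(v * v))
}

graph_fingerprint <- function(graph) {
  ws <- lapply(graph$layers, function(l)
    switch(l$type, conv = list(l$w, l$b),
           reparam = list(l$large$w, l$small$w,
                          l$bn_large$scale, l$bn_small$scale),
           bn = list(l$scale, l$shift, l$mean, l$var), NULL))
  fingerprint(c(list(graph$input_shape), ws))
}

#' VGG16-style extractor configuration
#'
#' The standard variant is the 13-convolution VGG16 feature trunk: five
#' blocks of 3x3 convolutions (2x64, 2x128, 3x256, 3x512, 3x512 channels)
#' with 2x2 max-pooling between blocks; the three fully connected layers of
#' the classifier are not part of the feature graph. The reduced variant
#' keeps the topology with small channel counts for desk-scale work.
#'
#' @param variant `"standard"` or `"reduced"`.
#' @param input_size Input image side in pixels (must survive five 2x2 pools).
#' @param seed Integer seed for the He-style random initialization.
#' @param weights_path Optional RDS weight container written by
#'   [save_backbone_weights()].
#' @param tap_pool If `TRUE`, taps are globally average-pooled at read-out.
#' @param channels Per-block channel counts (length 5); defaults by variant.
#' @return A config list for [build_vgg16()].
#' @export
vgg16_config <- function(variant = c("standard", "reduced"),
                         input_size = NULL, seed = 1L, weights_path = NULL,
                         tap_pool = FALSE, channels = NULL) {
  variant <- match.arg(variant)
  if (is.null(channels))
    channels <- if (variant == "standard") c(64L, 128L, 256L, 512L, 512L)
                else c(4L, 6L, 8L, 8L, 8L)
  if (is.null(input_size))
    input_size <- if (variant == "standard") 224L else 32L
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32 (five 2x2 pools)")
  list(variant = variant, channels = as.integer(channels),
       input_size = as.integer(input_size), seed = as.integer(seed),
       weights_path = weights_path, tap_pool = isTRUE(tap_pool))
}

#' Build the VGG16-style feature extractor
#'
#' Thirteen 3x3 convolutions in five blocks with ReLU activations and 2x2
#' max-pooling between blocks. Six taps: the outputs of blocks A-E and the
#' output of block E after the final max-pool.
#'
#' @param config A [vgg16_config()].
#' @return A [backbone_graph()] with 13 convolution layers and 6 taps.
#' @export
build_vgg16 <- function(config = vgg16_config()) {
  convs_per_block <- c(2L, 2L, 3L, 3L, 3L)
  set.seed(config$seed)
  layers <- list()
  taps <- list()
  in_ch <- 3L
  for (b in seq_len(5L)) {
    out_ch <- config$channels[b]
    for (j in seq_len(convs_per_block[b])) {
      sp <- conv_spec(3L, in_ch, out_ch, stride = 1L, padding = 1L)
      layers <- c(layers, list(
        layer_conv(sp, name = sprintf("block%s_conv%d", LETTERS[b], j)),
        layer_relu(sprintf("block%s_relu%d", LETTERS[b], j))))
      in_ch <- out_ch
    }
    taps <- c(taps, list(data.frame(name = paste0("block", LETTERS[b]),
                                    index = length(layers),
                                    pooled = config$tap_pool)))
    layers <- c(layers, list(layer_maxpool(2L, 2L,
                                           sprintf("pool%s", LETTERS[b]))))
  }
  taps <- c(taps, list(data.frame(name = "blockE_pool",
                                  index = length(layers),
                                  pooled = config$tap_pool)))
  g <- backbone_graph(layers, do.call(rbind, taps),
                      input_shape = c(3L, config$input_size, config$input_size),
                      name = "vgg16", variant = config$variant)
  maybe_load_weights(g, config$weights_path)
}

#' RepLKNet-style extractor configuration
#'
#' The default variant follows the 31B-style channel ladder 128/256/512/1024
#' with per-stage depthwise kernels 31/29/27/13, each paired with a parallel
#' 5x5 reparameterization branch; two blocks per stage keep the graph
#' compact. The reduced variant shrinks channels and kernels for desk-scale
#' work.
#'
#' @inheritParams vgg16_config
#' @param variant `"31B"` or `"reduced"`.
#' @param channels Stage channel counts (length 4).
#' @param kernels Per-stage large depthwise kernel sizes (length 4, odd).
#' @param small_kernel Parallel branch kernel size (odd).
#' @param blocks_per_stage Number of blocks in each stage.
#' @return A config list for [build_replknet()].
#' @export
replknet_config <- function(variant = c("31B", "reduced"), input_size = NULL,
                            seed = 1L, weights_path = NULL, tap_pool = FALSE,
                            channels = NULL, kernels = NULL,
                            small_kernel = NULL, blocks_per_stage = NULL) {
  variant <- match.arg(variant)
  if (variant == "31B") {
    if (is.null(channels)) channels <- c(128L, 256L, 512L, 1024L)
    if (is.null(kernels)) kernels <- c(31L, 29L, 27L, 13L)
    if (is.null(small_kernel)) small_kernel <- 5L
    if (is.null(blocks_per_stage)) blocks_per_stage <- 2L
    if (is.null(input_size)) input_size <- 224L
  } else {
    if (is.null(channels)) channels <- c(6L, 8L, 12L, 16L)
    if (is.null(kernels)) kernels <- c(7L, 7L, 5L, 3L)
    if (is.null(small_kernel)) small_kernel <- 3L
    if (is.null(blocks_per_stage)) blocks_per_stage <- 1L
    if (is.null(input_size)) input_size <- 32L
  }
  if (any(kernels %% 2L == 0L) || small_kernel %% 2L == 0L)
    stop("depthwise kernels must be odd")
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32 (stem + three transitions)")
  list(variant = variant, channels = as.integer(channels),
       kernels = as.integer(kernels), small_kernel = as.integer(small_kernel),
       blocks_per_stage = as.integer(blocks_per_stage),
       input_size = as.integer(input_size), seed = as.integer(seed),
       weights_path = weights_path, tap_pool = isTRUE(tap_pool))
}

conv_bn_relu <- function(spec, name) {
  list(layer_conv(spec, name = paste0(name, "_conv")),
       layer_bn(spec$out_channels, name = paste0(name, "_bn")),
       layer_relu(paste0(name, "_relu")))
}

dw_spec <- function(ch, k, stride = 1L)
  conv_spec(k, ch, ch, stride = stride, padding = (k - 1L) %/% 2L,
            groups = ch, has_bias = FALSE)

#' Build the RepLKNet-style feature extractor
#'
#' One stem (stride-4 overall), four stages of large depthwise-kernel blocks
#' with parallel small-kernel reparameterization branches, and a
#' down-sampling transition between consecutive stages. Four taps at the
#' stage outputs; for a 224x224 input their spatial sizes are 56/28/14/7.
#'
#' @param config A [replknet_config()].
#' @return A [backbone_graph()] with taps `stage1`..`stage4`.
#' @export
build_replknet <- function(config = replknet_config()) {
  set.seed(config$seed)
  ch <- config$channels
  layers <- list()
  taps <- list()
  # stem: 3 -> ch[1], overall stride 4
  layers <- c(layers,
    conv_bn_relu(conv_spec(3L, 3L, ch[1], stride = 2L, padding = 1L,
                           has_bias = FALSE), "stem1"),
    conv_bn_relu(dw_spec(ch[1], 3L), "stem2"),
    conv_bn_relu(conv_spec(1L, ch[1], ch[1], has_bias = FALSE), "stem3"),
    conv_bn_relu(dw_spec(ch[1], 3L, stride = 2L), "stem4"))
  for (s in seq_len(4L)) {
    for (b in seq_len(config$blocks_per_stage)) {
      nm <- sprintf("stage%d_block%d", s, b)
      large <- layer_conv(dw_spec(ch[s], config$kernels[s]),
                          name = paste0(nm, "_dwlarge"))
      small <- layer_conv(dw_spec(ch[s], config$small_kernel),
                          name = paste0(nm, "_dwsmall"))
      layers <- c(layers,
        list(reparam_branch(large, small,
                            layer_bn(ch[s], name = paste0(nm, "_bnlarge")),
                            layer_bn(ch[s], name = paste0(nm, "_bnsmall")),
                            name = paste0(nm, "_reparam")),
             layer_relu(paste0(nm, "_relu1"))),
        conv_bn_relu(conv_spec(1L, ch[s], ch[s], has_bias = FALSE),
                     paste0(nm, "_pw")))
    }
    taps <- c(taps, list(data.frame(name = paste0("stage", s),
                                    index = length(layers),
                                    pooled = config$tap_pool)))
    if (s < 4L) {
      layers <- c(layers,
        conv_bn_relu(conv_spec(1L, ch[s], ch[s + 1L], has_bias = FALSE),
                     sprintf("trans%d_pw", s)),
        conv_bn_relu(dw_spec(ch[s + 1L], 3L, stride = 2L),
                     sprintf("trans%d_dw", s)))
    }
  }
  g <- backbone_graph(layers, do.call(rbind, taps),
                      input_shape = c(3L, config$input_size, config$input_size),
                      name = "replknet", variant = config$variant)
  maybe_load_weights(g, config$weights_path)
}

#' Plain stack of square convolutions
#'
#' Builds a sequential conv(-ReLU) stack through the same graph machinery as
#' the full backbones, with same-padding so spatial size is preserved. Used
#' for receptive-field analytics and as a transparent test harness for the
#' convolution arithmetic.
#'
#' @param kernels Integer vector of odd kernel sizes, one per layer.
#' @param channels Channel count used by every layer.
#' @param in_channels Input channel count.
#' @param input_size Input side in pixels.
#' @param relu If `TRUE`, a ReLU follows every convolution.
#' @param bias Constant bias given to every convolution. A small positive
#'   value keeps units responsive under ReLU in randomly initialized narrow
#'   stacks (an all-dead stack has no effective receptive field).
#' @param seed Seed for the random initialization.
#' @return A [backbone_graph()] with a single tap `"out"` at the last layer.
#' @export
conv_stack_graph <- function(kernels, channels = 1L, in_channels = channels,
                             input_size = 33L, relu = FALSE, bias = 0,
                             seed = 1L) {
  stopifnot(length(kernels) >= 1, all(kernels %% 2L == 1L))
  set.seed(seed)
  layers <- list()
  cin <- as.integer(in_channels)
  for (i in seq_along(kernels)) {
    sp <- conv_spec(kernels[i], cin, channels, stride = 1L,
                    padding = (kernels[i] - 1L) %/% 2L)
    layers <- c(layers, list(layer_conv(sp, b = rep(bias, channels),
                                        name = sprintf("conv%d", i))))
    if (relu) layers <- c(layers, list(layer_relu(sprintf("relu%d", i))))
    cin <- as.integer(channels)
  }
  backbone_graph(layers,
                 data.frame(name = "out", index = length(layers),
                            pooled = FALSE),
                 input_shape = c(as.integer(in_channels),
                                 as.integer(input_size),
                                 as.integer(input_size)),
                 name = sprintf("convstack_k%s", paste(kernels, collapse = "-")),
                 variant = "analytic")
}

# ---- forward pass ----------------------------------------------------------

check_image_batch <- function(images, input_shape) {
  if (is.list(images)) images <- simplify2array(images)
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  d <- dim(images)
  expect <- c(input_shape[2], input_shape[3], input_shape[1])
  if (!identical(as.integer(d[1:3]), as.integer(expect)))
    stop(sprintf("image shape mismatch: expected (C,H,W) = (%s), received (%s)",
                 paste(input_shape, collapse = ","),
                 paste(c(d[3], d[1], d[2]), collapse = ",")))
  images
}

forward_one <- function(graph, x, cache = FALSE) {
  nlay <- length(graph$layers)
  acts <- if (cache) vector("list", nlay)
  idxs <- if (cache) vector("list", nlay)
  taps <- vector("list", nrow(graph$taps))
  names(taps) <- graph$taps$name
  ti <- 1L
  for (i in seq_len(nlay)) {
    r <- apply_layer(graph$layers[[i]], x)
    x <- r$out
    if (cache) { acts[[i]] <- x; if (!is.null(r$idx)) idxs[[i]] <- r$idx }
    while (ti <= nrow(graph$taps) && graph$taps$index[ti] == i) {
      taps[[ti]] <- if (graph$taps$pooled[ti])
        array(apply(x, 3, mean), dim = c(1L, 1L, dim(x)[3])) else x
      ti <- ti + 1L
    }
  }
  list(taps = taps, acts = acts, idxs = idxs)
}

#' Forward images through a backbone and collect tap activations
#'
#' @param graph A [backbone_graph()].
#' @param images A `(H, W, C, N)` array, a single `(H, W, C)` array, or a
#'   list of such arrays. Values are assumed already normalized (see
#'   [normalize_images()]).
#' @param source Tag recorded on the resulting stack.
#' @return A [feature_stack()] with one activation array `(H, W, C, N)` per
#'   tap, shallow to deep.
#' @export
forward_features <- function(graph, images, source = graph$name) {
  images <- check_image_batch(images, graph$input_shape)
  n <- dim(images)[4]
  per_tap <- vector("list", nrow(graph$taps))
  for (i in seq_len(n)) {
    fw <- forward_one(graph, array(images[, , , i], dim = dim(images)[1:3]))
    for (t in seq_along(per_tap)) per_tap[[t]][[i]] <- fw$taps[[t]]
  }
  layers <- lapply(per_tap, simplify2array)
  names(layers) <- graph$taps$name
  feature_stack(layers, source = source, backbone = graph_fingerprint(graph))
}

#' Normalize images channel-wise
#'
#' Standardizes each channel with fixed constants; defaults are the ImageNet
#' mean/sd used throughout the pretrained-CNN literature.
#'
#' @param images `(H, W, C[, N])` array with values in `[0, 1]`.
#' @param mean,sd Per-channel constants.
#' @return Array of the same shape.
#' @export
normalize_images <- function(images, mean = c(0.485, 0.456, 0.406),
                             sd = c(0.229, 0.224, 0.225)) {
  d <- dim(images)
  nc <- d[3]
  stopifnot(length(mean) == nc, length(sd) == nc, all(sd > 0))
  per <- d[1] * d[2]
  reps <- if (length(d) == 4L) d[4] else 1L
  m <- rep(rep(mean, each = per), times = reps)
  s <- rep(rep(sd, each = per), times = reps)
  array((images - m) / s, dim = d)
}

# ---- structural reparameterization fusion ----------------------------------

fold_bn_into_conv <- function(w, b, bn) {
  g <- bn_gain(bn)
  nd <- dim(w)
  wf <- w * rep(g, each = prod(nd[1:3]))
  bf <- (b - bn$mean) * g + bn$shift
  list(w = wf, b = bf)
}

pad_kernel_center <- function(w, k_to) {
  nd <- dim(w)
  k <- nd[1]
  if (k == k_to) return(w)
  off <- (k_to - k) %/% 2L
  out <- array(0, dim = c(k_to, k_to, nd[3], nd[4]))
  out[off + seq_len(k), off + seq_len(k), , ] <- w
  out
}

#' Fuse a large/small reparameterization branch into one convolution
#'
#' Folds each branch's frozen batch normalization into its convolution
#' weights and bias, zero-pads the small kernel symmetrically to the large
#' kernel size, and sums the two branches. For any conforming input the
#' fused convolution reproduces the two-branch sum.
#'
#' @param branch A [reparam_branch()] layer.
#' @return A list with elements `spec` (the large branch's [conv_spec()] with
#'   bias), `w` and `b`.
#' @export
fuse_reparam_branch <- function(branch) {
  if (!identical(branch$type, "reparam")) stop("not a reparam branch")
  lf <- fold_bn_into_conv(branch$large$w, branch$large$b, branch$bn_large)
  sf <- fold_bn_into_conv(branch$small$w, branch$small$b, branch$bn_small)
  ls <- branch$large$spec
  spec <- conv_spec(ls$kernel_size, ls$in_channels, ls$out_channels,
                    stride = ls$stride, padding = ls$padding,
                    groups = ls$groups, has_bias = TRUE)
  list(spec = spec, w = lf$w + pad_kernel_center(sf$w, ls$kernel_size),
       b = lf$b + sf$b)
}

#' Replace every reparameterization branch in a graph by its fused form
#'
#' @param graph A [backbone_graph()].
#' @return The graph with each reparam layer replaced by a single
#'   convolution; all taps and other layers unchanged.
#' @export
fuse_graph <- function(graph) {
  graph$layers <- lapply(graph$layers, function(l) {
    if (l$type != "reparam") return(l)
    f <- fuse_reparam_branch(l)
    layer_conv(f$spec, w = f$w, b = f$b, name = paste0(l$name, "_fused"))
  })
  graph
}

# ---- weight container ------------------------------------------------------

graph_weight_list <- function(graph) {
  out <- list()
  for (l in graph$layers) {
    if (l$type == "conv") {
      out[[paste0(l$name, "/weight")]] <- l$w
      out[[paste0(l$name, "/bias")]] <- l$b
    } else if (l$type == "bn") {
      out[[paste0(l$name, "/bn_scale")]] <- l$scale
      out[[paste0(l$name, "/bn_shift")]] <- l$shift
      out[[paste0(l$name, "/bn_mean")]] <- l$mean
      out[[paste0(l$name, "/bn_var")]] <- l$var
    } else if (l$type == "reparam") {
      out[[paste0(l$large$name, "/weight")]] <- l$large$w
      out[[paste0(l$small$name, "/weight")]] <- l$small$w
      for (side in c("large", "small")) {
        bn <- l[[paste0("bn_", side)]]
        out[[paste0(bn$name, "/bn_scale")]] <- bn$scale
        out[[paste0(bn$name, "/bn_shift")]] <- bn$shift
        out[[paste0(bn$name, "/bn_mean")]] <- bn$mean
        out[[paste0(bn$name, "/bn_var")]] <- bn$var
      }
    }
  }
  out
}

#' Save / load backbone weights
#'
#' Weights are stored as a flat named-tensor container (keys
#' `layer/weight`, `layer/bias`, `layer/bn_*`) in an RDS file. Loading
#' validates every shape before assignment and reports the first mismatched
#' layer.
#'
#' @param graph A [backbone_graph()].
#' @param path File path.
#' @return `save_backbone_weights()` the path invisibly;
#'   `load_backbone_weights()` the graph with weights replaced.
#' @export
save_backbone_weights <- function(graph, path) {
  saveRDS(graph_weight_list(graph), path)
  invisible(path)
}

#' @rdname save_backbone_weights
#' @export
load_backbone_weights <- function(graph, path) {
  stored <- readRDS(path)
  take <- function(key, current) {
    if (!key %in% names(stored))
      stop("weight container is missing '", key, "'")
    v <- stored[[key]]
    if (!identical(dim(v), dim(current)) || length(v) != length(current))
      stop("shape mismatch at '", key, "': expected ",
           paste(if (is.null(dim(current))) length(current) else dim(current),
                 collapse = "x"),
           ", found ",
           paste(if (is.null(dim(v))) length(v) else dim(v), collapse = "x"))
    v
  }
  graph$layers <- lapply(graph$layers, function(l) {
    if (l$type == "conv") {
      l$w <- take(paste0(l$name, "/weight"), l$w)
      l$b <- take(paste0(l$name, "/bias"), l$b)
    } else if (l$type == "bn") {
      l$scale <- take(paste0(l$name, "/bn_scale"), l$scale)
      l$shift <- take(paste0(l$name, "/bn_shift"), l$shift)
      l$mean <- take(paste0(l$name, "/bn_mean"), l$mean)
      l$var <- take(paste0(l$name, "/bn_var"), l$var)
    } else if (l$type == "reparam") {
      l$large$w <- take(paste0(l$large$name, "/weight"), l$large$w)
      l$small$w <- take(paste0(l$small$name, "/weight"), l$small$w)
      for (side in c("large", "small")) {
        bn <- l[[paste0("bn_", side)]]
        bn$scale <- take(paste0(bn$name, "/bn_scale"), bn$scale)
        bn$shift <- take(paste0(bn$name, "/bn_shift"), bn$shift)
        bn$mean <- take(paste0(bn$name, "/bn_mean"), bn$mean)
        bn$var <- take(paste0(bn$name, "/bn_var"), bn$var)
        l[[paste0("bn_", side)]] <- bn
      }
    }
    l
  })
  graph
}

maybe_load_weights <- function(graph, path) {
  if (is.null(path)) graph else load_backbone_weights(graph, path)
}
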