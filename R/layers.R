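# Layer-level building blocks for the convolutional feature extractors.
# Activations are base-R arrays with layout (row, col, channel); shapes are
# reported to users as (channel, row, col).

#' Convolution specification
#'
#' Describes one 2-d convolution: square kernel, stride, zero padding and
#' channel grouping. Depthwise convolutions have
#' `groups == in_channels == out_channels`.
#'
#' @param kernel_size Positive integer, side of the square kernel.
#' @param in_channels,out_channels Positive integer channel counts.
#' @param stride Positive integer stride.
#' @param padding Non-negative integer zero padding on every side.
#' @param groups Positive integer dividing both channel counts.
#' @param has_bias Logical, whether the convolution carries a bias term.
#' @return An object of class `conv_spec`.
#' @export
conv_spec <- function(kernel_size, in_channels, out_channels, stride = 1L,
                      padding = 0L, groups = 1L, has_bias = TRUE) {
  stopifnot(kernel_size >= 1, in_channels >= 1, out_channels >= 1,
            stride >= 1, padding >= 0, groups >= 1)
  if (in_channels %% groups != 0 || out_channels %% groups != 0)
    stop("groups must divide both in_channels and out_channels")
  structure(list(kernel_size = as.integer(kernel_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride), padding = as.integer(padding),
                 groups = as.integer(groups), has_bias = isTRUE(has_bias)),
            class = "conv_spec")
}

conv_out_size <- function(size, spec) {
  out <- (size + 2L * spec$padding - spec$kernel_size) %/% spec$stride + 1L
  if (out < 1L) stop("kernel larger than padded input")
  out
}

# He fan-in initialization; draws from the current RNG stream.
he_weights <- function(spec) {
  cin_g <- spec$in_channels %/% spec$groups
  fan_in <- spec$kernel_size^2 * cin_g
  w <- rnorm(spec$kernel_size^2 * cin_g * spec$out_channels) * sqrt(2 / fan_in)
  dim(w) <- c(spec$kernel_size, spec$kernel_size, cin_g, spec$out_channels)
  w
}

#' Convolution and batch-normalization layers
#'
#' Constructors for the two parameterized layer types. `layer_conv()` pairs
#' a [conv_spec()] with weights of shape
#' `(kernel, kernel, in_channels/groups, out_channels)` (He-initialized from
#' the current RNG stream when omitted). `layer_bn()` is a frozen
#' (inference-mode) batch normalization with per-channel scale, shift,
#' running mean and running variance.
#'
#' @param spec A [conv_spec()].
#' @param w Weight array; `NULL` for He-style random initialization.
#' @param b Bias vector (ignored when the spec has `has_bias = FALSE`).
#' @param name Layer name, used in error messages and weight containers.
#' @return A layer object usable in [backbone_graph()] or
#'   [reparam_branch()].
#' @export
layer_conv <- function(spec, w = NULL, b = NULL, name = "conv") {
  if (is.null(w)) w <- he_weights(spec)
  cin_g <- spec$in_channels %/% spec$groups
  stopifnot(identical(dim(w), c(spec$kernel_size, spec$kernel_size, cin_g,
                                spec$out_channels)))
  if (is.null(b)) b <- numeric(spec$out_channels)
  stopifnot(length(b) == spec$out_channels)
  if (!spec$has_bias) b <- numeric(spec$out_channels)
  list(type = "conv", name = name, spec = spec, w = w, b = b)
}

#' @rdname layer_conv
#' @param channels Channel count the normalization acts on.
#' @param scale,shift,mean,var Per-channel parameters; defaults are the
#'   identity transform.
#' @param eps Variance-stabilizing epsilon.
#' @export
layer_bn <- function(channels, scale = NULL, shift = NULL, mean = NULL,
                     var = NULL, eps = 1e-5, name = "bn") {
  if (is.null(scale)) scale <- rep(1, channels)
  if (is.null(shift)) shift <- rep(0, channels)
  if (is.null(mean)) mean <- rep(0, channels)
  if (is.null(var)) var <- rep(1, channels)
  stopifnot(length(scale) == channels, length(shift) == channels,
            length(mean) == channels, length(var) == channels, eps >= 0)
  list(type = "bn", name = name, channels = as.integer(channels),
       scale = scale, shift = shift, mean = mean, var = var, eps = eps)
}

layer_relu <- function(name = "relu") list(type = "relu", name = name)

layer_maxpool <- function(k = 2L, stride = k, name = "maxpool")
  list(type = "maxpool", name = name, k = as.integer(k),
       stride = as.integer(stride))

#' Parallel large + small kernel branch pair
#'
#' A structural-reparameterization unit: a large-kernel convolution and a
#' smaller odd-kernel convolution (same stride and groups), each followed by
#' its own frozen batch normalization; the branch outputs are summed.
#'
#' @param large,small `layer_conv()` results; both kernels odd, the small one
#'   no larger than the large one, strides and groups equal.
#' @param bn_large,bn_small `layer_bn()` results for the two branches.
#' @param name Layer name.
#' @return A reparam layer usable inside a [backbone_graph()] and by
#'   [fuse_reparam_branch()].
#' @export
reparam_branch <- function(large, small, bn_large, bn_small, name = "reparam") {
  ls <- large$spec; ss <- small$spec
  if (ls$kernel_size %% 2L == 0L || ss$kernel_size %% 2L == 0L)
    stop("reparam kernels must be odd")
  if (ss$kernel_size > ls$kernel_size)
    stop("small kernel must not exceed the large kernel")
  if (ls$stride != ss$stride || ls$groups != ss$groups)
    stop("branches must share stride and groups")
  if (ls$in_channels != ss$in_channels || ls$out_channels != ss$out_channels)
    stop("branches must share channel counts")
  # same-padding on both branches so outputs align spatially
  if (ls$padding - (ls$kernel_size - 1L) %/% 2L !=
      ss$padding - (ss$kernel_size - 1L) %/% 2L)
    stop("branch paddings must differ by exactly the kernel-size difference/2")
  list(type = "reparam", name = name, large = large, small = small,
       bn_large = bn_large, bn_small = bn_small)
}

bn_gain <- function(bn) bn$scale / sqrt(bn$var + bn$eps)

apply_bn <- function(x, bn) {
  d <- dim(x)
  g <- bn_gain(bn)
  off <- bn$shift - bn$mean * g
  x * rep(g, each = d[1] * d[2]) + rep(off, each = d[1] * d[2])
}

apply_layer <- function(l, x) {
  switch(l$type,
    conv = list(out = .conv2d_fwd(x, l$w, l$b, l$spec$stride, l$spec$padding,
                                  l$spec$groups)),
    bn = list(out = apply_bn(x, l)),
    relu = { x[x < 0] <- 0; list(out = x) },
    maxpool = .maxpool_fwd(x, l$k, l$stride),
    reparam = {
      a <- apply_bn(.conv2d_fwd(x, l$large$w, l$large$b, l$large$spec$stride,
                                l$large$spec$padding, l$large$spec$groups),
                    l$bn_large)
      b <- apply_bn(.conv2d_fwd(x, l$small$w, l$small$b, l$small$spec$stride,
                                l$small$spec$padding, l$small$spec$groups),
                    l$bn_small)
      list(out = a + b)
    },
    stop("unknown layer type: ", l$type)
  )
}

# Backward pass of one layer w.r.t. its input (used by the ERF probe).
# `out` is the cached forward output, `idx` the maxpool argmax cache.
layer_bwd <- function(l, g, out, idx, in_dim) {
  switch(l$type,
    conv = .conv2d_bwd_input(g, l$w, l$spec$stride, l$spec$padding,
                             l$spec$groups, in_dim[1], in_dim[2]),
    bn = {
      d <- dim(g)
      g * rep(bn_gain(l), each = d[1] * d[2])
    },
    relu = g * (out > 0),
    maxpool = .maxpool_bwd(g, idx, in_dim[1], in_dim[2], in_dim[3]),
    reparam = {
      d <- dim(g)
      ga <- g * rep(bn_gain(l$bn_large), each = d[1] * d[2])
      gb <- g * rep(bn_gain(l$bn_small), each = d[1] * d[2])
      .conv2d_bwd_input(ga, l$large$w, l$large$spec$stride,
                        l$large$spec$padding, l$large$spec$groups,
                        in_dim[1], in_dim[2]) +
        .conv2d_bwd_input(gb, l$small$w, l$small$spec$stride,
                          l$small$spec$padding, l$small$spec$groups,
                          in_dim[1], in_dim[2])
    },
    stop("layer '", l$name, "' (", l$type, ") is not differentiable")
  )
}

# Shape propagation without running data through the graph.
layer_out_shape <- function(l, shape) {  # shape = c(C, H, W)
  switch(l$type,
    conv = c(l$spec$out_channels, conv_out_size(shape[2], l$spec),
             conv_out_size(shape[3], l$spec)),
    bn = shape,
    relu = shape,
    maxpool = c(shape[1], (shape[2] - l$k) %/% l$stride + 1L,
                (shape[3] - l$k) %/% l$stride + 1L),
    reparam = c(l$large$spec$out_channels,
                conv_out_size(shape[2], l$large$spec),
                conv_out_size(shape[3], l$large$spec)),
    stop("unknown layer type: ", l$type)
  )
}
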