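# Multi-layer feature stacks: R features (large-kernel backbone, 5 layers),
# V features (small-kernel backbone, 6 layers), and their merged M features.

#' Multi-layer feature stack
#'
#' An ordered, named collection of per-layer activations for a batch of
#' images, shallow to deep. Spatial stacks hold `(H, W, C, N)` arrays; a
#' merged (`M`) stack holds one flattened feature matrix (`N x width`).
#'
#' @param layers Named list of activation arrays (or one matrix for `M`).
#' @param source Tag: `"R"`, `"V"`, `"M"`, or a backbone name.
#' @param backbone Fingerprint(s) of the producing backbone weights.
#' @param meta Optional metadata list (flattening layouts, merge widths).
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(layers, source = "raw", backbone = NA_character_,
                          meta = list()) {
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  batch <- vapply(layers, function(a) {
    d <- dim(a)
    if (is.matrix(a)) nrow(a) else d[length(d)]
  }, numeric(1))
  if (length(unique(batch)) != 1L)
    stop("all layers must share the batch size")
  shapes <- lapply(layers, function(a) {
    d <- dim(a)
    if (is.matrix(a)) ncol(a) else c(d[3], d[1], d[2])  # (C, H, W)
  })
  structure(list(source = source, layers = layers, shapes = shapes,
                 batch = as.integer(batch[1]), backbone = backbone,
                 meta = meta),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat("<feature_stack> source=", x$source, ", batch=", x$batch, "\n", sep = "")
  for (nm in names(x$layers))
    cat("  ", nm, ": ", paste(x$shapes[[nm]], collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Per-image global L2 normalization of an activation
#'
#' Divides each image's activation by its Euclidean norm over all
#' channel-by-spatial elements, so nonzero inputs come out with unit norm and
#' an all-zero input stays zero. This is the parameter-free normalization
#' applied to the deepest large-kernel stage to form the fifth R-feature
#' layer.
#'
#' @param a `(H, W, C)` or `(H, W, C, N)` activation array.
#' @return Array of the same shape.
#' @export
normalize_layer <- function(a) {
  if (!all(is.finite(a))) stop("activation contains non-finite values")
  d <- dim(a)
  if (length(d) == 3L) {
    nrm <- sqrt(sum(a^2))
    if (nrm > 0) a <- a / nrm
    return(a)
  }
  stopifnot(length(d) == 4L)
  per <- prod(d[1:3])
  for (i in seq_len(d[4])) {
    v <- a[, , , i]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) a[, , , i] <- v / nrm
  }
  a
}

#' Extract the five-layer R feature stack
#'
#' Runs the large-kernel backbone and returns the four stage outputs plus a
#' fifth layer: the deepest stage after [normalize_layer()].
#'
#' @param replk_graph A graph from [build_replknet()].
#' @param images Image batch, see [forward_features()].
#' @return A [feature_stack()] with source `"R"` and 5 layers.
#' @export
extract_R <- function(replk_graph, images) {
  st <- forward_features(replk_graph, images, source = "R")
  if (length(st$layers) != 4L)
    stop("expected a 4-tap large-kernel backbone")
  deep <- st$layers[[4L]]
  st$layers[["stage4_norm"]] <- normalize_layer(deep)
  st$shapes[["stage4_norm"]] <- st$shapes[[4L]]
  st
}

#' Extract the six-layer V feature stack
#'
#' Runs the small-kernel backbone and returns the five block outputs plus the
#' final post-max-pool output.
#'
#' @param vgg_graph A graph from [build_vgg16()].
#' @param images Image batch, see [forward_features()].
#' @return A [feature_stack()] with source `"V"` and 6 layers.
#' @export
extract_V <- function(vgg_graph, images) {
  st <- forward_features(vgg_graph, images, source = "V")
  if (length(st$layers) != 6L)
    stop("expected a 6-tap small-kernel backbone")
  st
}

#' Flatten a feature stack to per-image vectors
#'
#' Concatenates all layers in their fixed shallow-to-deep order into one
#' vector per image. Within a layer, elements follow the array's native
#' (row, col, channel) column-major order; the layout is recorded so the
#' operation is invertible with [unflatten_stack()].
#'
#' @param stack A spatial [feature_stack()].
#' @return An `N x width` matrix with attribute `"layout"`.
#' @export
flatten_stack <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  mats <- lapply(stack$layers, function(a) {
    if (is.matrix(a)) return(a)
    d <- dim(a)
    t(matrix(a, nrow = prod(d[1:3]), ncol = d[4]))
  })
  out <- do.call(cbind, mats)
  attr(out, "layout") <- list(
    names = names(stack$layers),
    dims = lapply(stack$layers, function(a)
      if (is.matrix(a)) ncol(a) else dim(a)[1:3]),
    order = "within-layer (row, col, channel) column-major",
    source = stack$source, backbone = stack$backbone)
  out
}

#' @rdname flatten_stack
#' @param mat Matrix produced by `flatten_stack()`.
#' @param layout The `"layout"` attribute of that matrix.
#' @export
unflatten_stack <- function(mat, layout = attr(mat, "layout")) {
  stopifnot(is.matrix(mat), !is.null(layout))
  widths <- vapply(layout$dims, prod, numeric(1))
  stopifnot(ncol(mat) == sum(widths))
  ends <- cumsum(widths)
  starts <- c(1, head(ends, -1) + 1)
  layers <- vector("list", length(widths))
  names(layers) <- layout$names
  for (i in seq_along(widths)) {
    block <- mat[, starts[i]:ends[i], drop = FALSE]
    d <- layout$dims[[i]]
    layers[[i]] <- if (length(d) == 1L) block
      else array(t(block), dim = c(d, nrow(mat)))
  }
  feature_stack(layers, source = layout$source, backbone = layout$backbone)
}

#' Merge V and R features into the mixed M feature matrix
#'
#' Flattens both stacks and concatenates them per image, V features first,
#' with equal weighting (no rescaling of either source). The merged width is
#' the sum of the two flattened widths.
#'
#' @param V_stack A [feature_stack()] from [extract_V()].
#' @param R_stack A [feature_stack()] from [extract_R()].
#' @return A [feature_stack()] with source `"M"` holding one `N x width`
#'   matrix layer; `meta` records both layouts and widths.
#' @export
merge_features <- function(V_stack, R_stack) {
  stopifnot(inherits(V_stack, "feature_stack"),
            inherits(R_stack, "feature_stack"))
  if (V_stack$batch != R_stack$batch)
    stop("batch mismatch: V has ", V_stack$batch, " images, R has ",
         R_stack$batch)
  v <- flatten_stack(V_stack)
  r <- flatten_stack(R_stack)
  m <- cbind(v, r)
  feature_stack(list(M = m), source = "M",
                backbone = c(V = V_stack$backbone, R = R_stack$backbone),
                meta = list(v_width = ncol(v), r_width = ncol(r),
                            v_layout = attr(v, "layout"),
                            r_layout = attr(r, "layout")))
}

#' Feature matrix of a stack
#'
#' @param stack A [feature_stack()].
#' @return The `N x width` matrix (flattening spatial stacks as needed).
#' @export
feature_matrix <- function(stack) {
  if (identical(stack$source, "M")) return(unclass(stack$layers$M))
  out <- flatten_stack(stack)
  attr(out, "layout") <- NULL
  out
}
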