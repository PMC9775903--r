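# Effective receptive field (ERF) quantification: the contribution score of
# every input pixel to the central unit of a backbone's deepest feature tap,
# estimated by backward accumulation from a unit seed and aggregated over
# random probe images.

center_index <- function(n) as.integer(ceiling(n / 2))

#' Effective receptive field heatmap
#'
#' For each probe (a seeded standard-normal random image), forwards the
#' graph, places a unit gradient seed at the central spatial position of the
#' last tap (all channels), backpropagates to the input, and accumulates the
#' absolute sensitivity summed over input channels. Maps are averaged over
#' probes and normalized to peak 1.
#'
#' @param graph A [backbone_graph()] whose layers are all differentiable.
#' @param n_probes Number of random probe images (default 32).
#' @param seed RNG seed for the probe stream.
#' @param linear If `TRUE`, ReLU layers are treated as identity in both
#'   passes (used for the analytic receptive-field checks; max-pooling stays
#'   nonlinear).
#' @return An object of class `erf_map`: `scores` (`H x W`, peak 1),
#'   `backbone`, `n_probes`.
#' @export
erf_heatmap <- function(graph, n_probes = 32L, seed = 1L, linear = FALSE) {
  stopifnot(n_probes >= 1)
  ins <- graph$input_shape
  last_tap <- graph$taps$index[nrow(graph$taps)]
  set.seed(seed)
  acc <- matrix(0, ins[2], ins[3])
  for (p in seq_len(n_probes)) {
    x <- array(rnorm(prod(ins)), dim = c(ins[2], ins[3], ins[1]))
    acc <- acc + erf_probe(graph, x, last_tap, linear)
  }
  scores <- acc / n_probes
  peak <- max(scores)
  if (peak > 0) scores <- scores / peak
  structure(list(scores = scores, backbone = graph$name,
                 variant = graph$variant, n_probes = as.integer(n_probes),
                 normalized = peak > 0),
            class = "erf_map")
}

erf_probe <- function(graph, x, last_tap, linear) {
  nlay <- last_tap
  acts <- vector("list", nlay)
  idxs <- vector("list", nlay)
  in_dims <- vector("list", nlay)
  cur <- x
  for (i in seq_len(nlay)) {
    l <- graph$layers[[i]]
    in_dims[[i]] <- dim(cur)
    if (linear && l$type == "relu") {
      acts[[i]] <- cur
      next
    }
    r <- apply_layer(l, cur)
    cur <- r$out
    acts[[i]] <- cur
    if (!is.null(r$idx)) idxs[[i]] <- r$idx
  }
  d <- dim(cur)
  if (d[1] < 1 || d[2] < 1) stop("last tap has empty spatial extent")
  g <- array(0, dim = d)
  g[center_index(d[1]), center_index(d[2]), ] <- 1
  for (i in rev(seq_len(nlay))) {
    l <- graph$layers[[i]]
    if (linear && l$type == "relu") next
    g <- layer_bwd(l, g, acts[[i]], idxs[[i]], in_dims[[i]])
  }
  apply(abs(g), c(1, 2), sum)
}

#' @export
print.erf_map <- function(x, ...) {
  cat("<erf_map> ", x$backbone, " (", x$variant, "), ",
      nrow(x$scores), "x", ncol(x$scores), ", probes=", x$n_probes, "\n",
      sep = "")
  invisible(x)
}

#' Scalar ERF size
#'
#' Side length (pixels) of the smallest centered square window containing at
#' least `mass_fraction` of the total contribution-score mass.
#'
#' @param map An [erf_heatmap()] result (or a plain score matrix).
#' @param mass_fraction Fraction of mass to enclose, in `(0, 1]`.
#' @return Integer side length.
#' @export
erf_size <- function(map, mass_fraction = 0.95) {
  s <- if (inherits(map, "erf_map")) map$scores else as.matrix(map)
  stopifnot(mass_fraction > 0, mass_fraction <= 1)
  total <- sum(s)
  if (total <= 0) stop("empty ERF map")
  H <- nrow(s); W <- ncol(s)
  for (side in seq_len(max(H, W))) {
    sh <- min(side, H); sw <- min(side, W)
    r0 <- (H - sh) %/% 2L; c0 <- (W - sw) %/% 2L
    mass <- sum(s[r0 + seq_len(sh), c0 + seq_len(sw)])
    if (mass >= mass_fraction * total - 1e-12 * total) return(side)
  }
  max(H, W)
}

#' Compare ERF sizes across backbones
#'
#' Runs [erf_heatmap()] on each graph with a common probe budget and seed
#' and tabulates the scalar ERF sizes.
#'
#' @param graphs Named list of [backbone_graph()]s sharing an input size.
#' @param n_probes,seed Passed to [erf_heatmap()].
#' @param mass_fraction Passed to [erf_size()].
#' @param linear Passed to [erf_heatmap()].
#' @return A tibble with columns `backbone`, `input_size`, `erf_size`,
#'   ordered as given.
#' @export
compare_erf <- function(graphs, n_probes = 32L, seed = 1L,
                        mass_fraction = 0.95, linear = FALSE) {
  stopifnot(is.list(graphs), length(graphs) >= 1)
  nms <- names(graphs) %||%
    vapply(graphs, function(g) g$name, character(1))
  sizes <- unique(vapply(graphs, function(g) g$input_shape[2], integer(1)))
  if (length(sizes) != 1) stop("graphs must share the input size")
  purrr::map2_dfr(graphs, nms, function(g, nm) {
    m <- erf_heatmap(g, n_probes = n_probes, seed = seed, linear = linear)
    tibble::tibble(backbone = nm, input_size = sizes,
                   erf_size = erf_size(m, mass_fraction))
  })
}
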