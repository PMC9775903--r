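# Independent oracles used across the suite. These deliberately avoid the
# package's own compute paths: convolution by direct nested-loop summation,
# summaries by brute-force loops.

# Direct-summation 2-d convolution, layout (row, col, channel),
# weights (k, k, in_per_group, out).
oracle_conv2d <- function(x, w, b, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x)
  k <- dim(w)[1]; cin_g <- dim(w)[3]; cout <- dim(w)[4]
  cout_g <- cout / groups
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  out <- array(0, dim = c(Ho, Wo, cout))
  for (co in seq_len(cout)) {
    g <- (co - 1) %/% cout_g
    for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
      acc <- b[co]
      for (c in seq_len(cin_g)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        ii <- (oi - 1) * stride - pad + ki
        jj <- (oj - 1) * stride - pad + kj
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          acc <- acc + x[ii, jj, g * cin_g + c] * w[ki, kj, c, co]
      }
      out[oi, oj, co] <- acc
    }
  }
  out
}

# Random depthwise reparam branch (large + small kernel, random BN stats).
random_dw_branch <- function(ch = 4L, k_large = 7L, k_small = 3L) {
  mk_conv <- function(k) {
    sp <- conv_spec(k, ch, ch, stride = 1L, padding = (k - 1L) %/% 2L,
                    groups = ch, has_bias = FALSE)
    layer_conv(sp, w = array(rnorm(k * k * ch), dim = c(k, k, 1L, ch)),
               name = paste0("dw", k))
  }
  rand_bn <- function() layer_bn(ch, scale = runif(ch, 0.5, 1.5),
                                 shift = rnorm(ch), mean = rnorm(ch),
                                 var = runif(ch, 0.5, 2))
  reparam_branch(mk_conv(k_large), mk_conv(k_small), rand_bn(), rand_bn())
}

# Forward a single layer on one (H, W, C) activation through the public
# graph interface; returns the (H, W, C) output.
forward_layer <- function(layer, x, in_channels = dim(x)[3]) {
  g <- backbone_graph(list(layer),
                      data.frame(name = "out", index = 1L, pooled = FALSE),
                      input_shape = c(in_channels, dim(x)[1], dim(x)[2]))
  st <- forward_features(g, x)
  array(st$layers$out, dim = dim(st$layers$out)[1:3])
}

# Brute-force top-n mean of a correlation vector.
oracle_top_n_mean <- function(pcc, n) {
  pcc <- pcc[!is.na(pcc)]
  s <- sort(pcc, decreasing = TRUE)
  mean(s[seq_len(min(n, length(s)))])
}

# Minimal encoding_result for evaluation tests.
make_result <- function(pcc, ids = paste0("vox", seq_along(pcc)),
                        roi = NA_character_, model_id = "m",
                        threshold = 0.41) {
  out <- tibble::tibble(voxel_id = ids, roi = roi, pcc = pcc,
                        valid = !is.na(pcc) & pcc > threshold)
  structure(out, model_id = model_id, threshold = threshold,
            class = c("encoding_result", class(out)))
}

# Smallest centered square window holding >= frac of the mass, by
# exhaustive search over window sides.
oracle_erf_size <- function(s, frac) {
  H <- nrow(s); W <- ncol(s); total <- sum(s)
  for (side in seq_len(max(H, W))) {
    sh <- min(side, H); sw <- min(side, W)
    r0 <- (H - sh) %/% 2; c0 <- (W - sw) %/% 2
    if (sum(s[r0 + seq_len(sh), c0 + seq_len(sw)]) >=
        frac * total - 1e-12 * total) return(side)
  }
  max(H, W)
}
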