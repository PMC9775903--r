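# Feature-to-voxel linear mapping: PCA reduction of the (typically
# overcomplete, n > m) feature matrix to at most m-1 components, then
# per-voxel sparse linear regression by regularized orthogonal matching
# pursuit (ROMP). The fitted model for voxel response v is v = F w + b with a
# sparse weight vector w.

as_feature_mat <- function(F) {
  if (inherits(F, "feature_stack")) F <- feature_matrix(F)
  F <- as.matrix(F)
  if (!all(is.finite(F))) stop("feature matrix contains non-finite entries")
  F
}

#' Fit a principal component analysis model
#'
#' Centers the feature matrix and takes the thin singular value
#' decomposition. The number of retained components is
#' `k = min(m - 1, rank)`, where rank counts singular values above
#' `1e-10` times the largest - so a full-rank matrix of `m` samples keeps
#' `m - 1` components, the most a centered matrix can support. All retained
#' components are kept regardless of their variance share.
#'
#' @param F `m x n` feature matrix (or a [feature_stack()]), `m >= 2`.
#' @return An object of class `pca_model` with `mean` (length `n`),
#'   `components` (`n x k`, orthonormal columns), `variance` (length `k`),
#'   and `k`.
#' @export
pca_fit <- function(F) {
  F <- as_feature_mat(F)
  m <- nrow(F); n <- ncol(F)
  stopifnot(m >= 2, n >= 1)
  mu <- colMeans(F)
  Xc <- sweep(F, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = min(m - 1L, n))
  tol <- 1e-10 * max(sv$d[1], 0)
  rank <- sum(sv$d > tol)
  k <- min(m - 1L, rank)
  if (k == 0L) {
    warning("feature matrix is constant; PCA keeps 0 components")
    return(structure(list(mean = mu,
                          components = matrix(0, n, 0),
                          variance = numeric(0), k = 0L),
                     class = "pca_model"))
  }
  structure(list(mean = mu,
                 components = sv$v[, seq_len(k), drop = FALSE],
                 variance = sv$d[seq_len(k)]^2 / (m - 1),
                 k = k),
            class = "pca_model")
}

#' Project features onto a fitted PCA basis
#'
#' @param model A [pca_fit()] result.
#' @param F `m x n` matrix (or [feature_stack()]) with the training width.
#' @return `m x k` score matrix `(F - mean) %*% components`.
#' @export
pca_transform <- function(model, F) {
  stopifnot(inherits(model, "pca_model"))
  F <- as_feature_mat(F)
  if (ncol(F) != length(model$mean))
    stop("width mismatch: model expects ", length(model$mean),
         " features, received ", ncol(F))
  sweep(F, 2L, model$mean) %*% model$components
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_features = length(x$mean),
                 total_variance = sum(x$variance),
                 top_variance_share =
                   if (x$k > 0) x$variance[1] / sum(x$variance) else NA_real_)
}

#' Sparse-fit configuration
#'
#' Hyperparameters of the ROMP solver. Per iteration ROMP may add up to `K`
#' coordinates and it stops once the support reaches `2K`, so `K` bounds the
#' sparsity of the fitted weights.
#'
#' @param K Sparsity target per iteration (`K >= 1`).
#' @param tol Residual-norm stopping tolerance; `NULL` means
#'   `1e-6 * ||y||`.
#' @param max_iter Iteration cap.
#' @param seed Seed recorded with the fit (the solver itself is
#'   deterministic).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(K = 20L, tol = NULL, max_iter = 50L, seed = 1L) {
  stopifnot(K >= 1, is.null(tol) || tol > 0, max_iter >= 1)
  structure(list(K = as.integer(K), tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fit_config")
}

# Regularized subset selection: among the candidate coordinates (sorted by
# decreasing |u|), choose the maximal-energy contiguous run whose magnitudes
# are within a factor of 2 of each other. Scanning starts from the largest
# magnitude and ties keep the earliest run, so the tie-break favours the
# subset containing the largest coordinate.
regularized_subset <- function(u, cand) {
  mags <- abs(u[cand])
  ord <- order(mags, decreasing = TRUE)
  cand <- cand[ord]; mags <- mags[ord]
  best <- NULL; best_energy <- -Inf
  n <- length(cand)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && mags[j + 1L] * 2 >= mags[i]) j <- j + 1L
    energy <- sum(mags[i:j]^2)
    if (energy > best_energy) {
      best_energy <- energy
      best <- cand[i:j]
    }
  }
  best
}

#' Fit one sparse linear model by regularized orthogonal matching pursuit
#'
#' Implements the ROMP iteration: compute correlations `u = X' r` of the
#' columns with the current residual, take the `K` largest-magnitude
#' coordinates, keep the maximal-energy subset whose magnitudes lie within a
#' factor of 2 of each other, add it to the support, and re-solve least
#' squares on the support. Stops when the residual norm drops below `tol`,
#' the support reaches `2K`, or `max_iter` iterations have run. The
#' intercept is recovered from centering: `b = mean(y) - mean(X) . w`.
#'
#' @param X `m x k` design matrix with finite entries.
#' @param y Length-`m` response.
#' @param cfg A [fit_config()].
#' @return An object of class `sparse_linear_model` with `w` (length `k`),
#'   `b`, `support`, `residual_norm`, `residual_path`, `iterations`,
#'   `converged`.
#' @export
romp_fit <- function(X, y, cfg = fit_config()) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), all(is.finite(y)), nrow(X) == length(y))
  k <- ncol(X)
  if (cfg$K > k) stop("sparsity target K exceeds the number of predictors")
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  tol <- if (is.null(cfg$tol)) 1e-6 * sqrt(sum(yc^2)) else cfg$tol
  support <- integer(0)
  w_s <- numeric(0)
  r <- yc
  path <- sqrt(sum(r^2))
  iter <- 0L
  while (iter < cfg$max_iter && sqrt(sum(r^2)) > tol &&
         length(support) < 2L * cfg$K) {
    iter <- iter + 1L
    u <- drop(crossprod(Xc, r))
    u[support] <- 0
    if (max(abs(u)) <= 1e-12 * max(path[1], 1)) break
    cand <- order(abs(u), decreasing = TRUE)[seq_len(min(cfg$K, sum(u != 0)))]
    J <- regularized_subset(u, cand)
    if (length(J) == 0L) break
    # honor the 2K support bound: keep the largest-magnitude entries of J
    J <- J[seq_len(min(length(J), 2L * cfg$K - length(support)))]
    support <- sort(c(support, J))
    fit <- qr(Xc[, support, drop = FALSE])
    w_s <- qr.coef(fit, yc)
    w_s[is.na(w_s)] <- 0
    r <- yc - Xc[, support, drop = FALSE] %*% w_s
    path <- c(path, sqrt(sum(r^2)))
  }
  w <- numeric(k)
  w[support] <- w_s
  support <- support[w[support] != 0]
  structure(list(w = w, b = ybar - sum(xbar * w),
                 support = support,
                 residual_norm = sqrt(sum(r^2)), residual_path = path,
                 iterations = iter,
                 converged = sqrt(sum(r^2)) <= tol),
            class = "sparse_linear_model")
}

#' @export
print.sparse_linear_model <- function(x, ...) {
  cat("<sparse_linear_model> |support|=", length(x$support),
      ", residual=", format(x$residual_norm, digits = 4),
      ", iterations=", x$iterations,
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Fit independent sparse models for every voxel
#'
#' @param F_train `m x k` (reduced) feature matrix or [feature_stack()].
#' @param responses_train `m x n_voxels` response matrix.
#' @param cfg A [fit_config()].
#' @param voxel_ids Optional voxel identifiers (default column names or
#'   indices).
#' @return An object of class `voxel_models`: a list of
#'   `sparse_linear_model`s in voxel order plus the feature fingerprint.
#' @export
fit_voxelwise <- function(F_train, responses_train, cfg = fit_config(),
                          voxel_ids = NULL) {
  fp <- if (inherits(F_train, "feature_stack")) F_train$backbone else NULL
  F_train <- as_feature_mat(F_train)
  responses_train <- as.matrix(responses_train)
  stopifnot(nrow(F_train) == nrow(responses_train))
  if (is.null(voxel_ids))
    voxel_ids <- colnames(responses_train) %||%
      paste0("vox", seq_len(ncol(responses_train)))
  nz <- apply(responses_train, 2L, function(y) sd(y) > 0)
  if (any(!nz))
    warning(sum(!nz), " voxel(s) have zero response variance; fitted as ",
            "constant models")
  models <- lapply(seq_len(ncol(responses_train)), function(j) {
    y <- responses_train[, j]
    if (!nz[j])
      return(structure(list(w = numeric(ncol(F_train)), b = mean(y),
                            support = integer(0), residual_norm = 0,
                            residual_path = 0, iterations = 0L,
                            converged = TRUE),
                       class = "sparse_linear_model"))
    romp_fit(F_train, y, cfg)
  })
  structure(list(models = models, voxel_ids = voxel_ids, cfg = cfg,
                 n_features = ncol(F_train),
                 feature_fingerprint = fingerprint(F_train),
                 backbone_fingerprint = fp),
            class = "voxel_models")
}

#' @export
print.voxel_models <- function(x, ...) {
  cat("<voxel_models> ", length(x$models), " voxels, ", x$n_features,
      " predictors, K=", x$cfg$K, "\n", sep = "")
  invisible(x)
}

#' Predict voxel responses for new features
#'
#' Column `j` of the result is `F_test %*% w_j + b_j`.
#'
#' @param object A [fit_voxelwise()] result.
#' @param F_test `m x k` feature matrix or [feature_stack()].
#' @param ... Unused.
#' @return `m x n_voxels` matrix of predicted responses.
#' @export
predict.voxel_models <- function(object, F_test, ...) {
  F_test <- as_feature_mat(F_test)
  if (ncol(F_test) != object$n_features)
    stop("width mismatch: models expect ", object$n_features,
         " predictors, received ", ncol(F_test))
  W <- vapply(object$models, function(mm) mm$w, numeric(object$n_features))
  b <- vapply(object$models, function(mm) mm$b, numeric(1))
  out <- F_test %*% W
  out <- sweep(out, 2L, b, "+")
  colnames(out) <- object$voxel_ids
  out
}

#' @export
tidy.voxel_models <- function(x, ...) {
  tibble::tibble(
    voxel_id = x$voxel_ids,
    n_nonzero = vapply(x$models, function(mm) length(mm$support), integer(1)),
    intercept = vapply(x$models, function(mm) mm$b, numeric(1)),
    residual_norm = vapply(x$models, function(mm) mm$residual_norm,
                           numeric(1)),
    iterations = vapply(x$models, function(mm) mm$iterations, integer(1)),
    converged = vapply(x$models, function(mm) mm$converged, logical(1)))
}

#' @export
glance.voxel_models <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n_voxels = nrow(td), n_features = x$n_features,
                 K = x$cfg$K,
                 mean_support = mean(td$n_nonzero),
                 prop_converged = mean(td$converged))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
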