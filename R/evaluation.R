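# Scoring of encoding predictions: per-voxel Pearson correlation, the strict
# > 0.41 valid-voxel rule, per-ROI top-n summaries, and the two-model scatter
# categorization.

#' Region-of-interest map
#'
#' Maps voxel identifiers to one of the base visual regions (V1, V2, V3, V4,
#' LOC, FFA, PPA). The composite groups are derived automatically and are
#' reserved names: LVC = V1+V2+V3 (lower visual cortex), HVC = LOC+FFA+PPA
#' (higher visual cortex), and VC = LVC + V4 + HVC (whole visual cortex).
#'
#' @param regions Named list: region name -> character/integer vector of
#'   voxel ids.
#' @return An object of class `roi_map`: a tibble with columns `voxel_id`,
#'   `roi`, and an attribute `groups` naming the derived voxel sets.
#' @export
roi_map <- function(regions) {
  stopifnot(is.list(regions))
  reserved <- c("LVC", "HVC", "VC")
  if (any(names(regions) %in% reserved))
    stop("group names LVC/HVC/VC are derived, never user-supplied")
  ids <- unlist(lapply(regions, as.character), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("voxel(s) assigned to more than one base region: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tab <- tibble::tibble(
    voxel_id = ids,
    roi = rep(names(regions), lengths(regions)))
  grp <- function(nms) {
    nms <- intersect(nms, names(regions))
    as.character(unlist(regions[nms], use.names = FALSE))
  }
  groups <- list(LVC = grp(c("V1", "V2", "V3")),
                 HVC = grp(c("LOC", "FFA", "PPA")))
  groups$VC <- c(groups$LVC, grp("V4"), groups$HVC)
  structure(tab, groups = groups, class = c("roi_map", class(tab)))
}

roi_voxels <- function(rois, name) {
  groups <- attr(rois, "groups")
  if (name %in% names(groups)) return(groups[[name]])
  if (!name %in% rois$roi) stop("unknown ROI: ", name)
  rois$voxel_id[rois$roi == name]
}

#' Pearson correlation between observed and predicted responses
#'
#' `Pcc = cor(v, vhat)`; the sample Pearson correlation over test samples.
#' When either vector has zero variance the correlation is undefined and
#' `NA` is returned (downstream, undefined correlations are always treated
#' as invalid, never as 0).
#'
#' @param v,vhat Numeric vectors of equal length `m >= 2`.
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson <- function(v, vhat) {
  if (length(v) != length(vhat))
    stop("length mismatch: ", length(v), " vs ", length(vhat))
  stopifnot(length(v) >= 2)
  if (sd(v) == 0 || sd(vhat) == 0) return(NA_real_)
  cor(v, vhat)
}

#' Valid-voxel mask
#'
#' A voxel is a valid predicted voxel when its correlation is strictly
#' greater than the threshold (default 0.41); undefined (`NA`) correlations
#' are invalid.
#'
#' @param pcc Numeric vector of per-voxel correlations.
#' @param threshold Validity threshold in `(-1, 1)`.
#' @return List with `valid` (logical vector) and `n_valid`.
#' @export
valid_mask <- function(pcc, threshold = 0.41) {
  stopifnot(threshold > -1, threshold < 1)
  valid <- !is.na(pcc) & pcc > threshold
  list(valid = valid, n_valid = sum(valid))
}

#' Average repeated test-trial responses per image
#'
#' @param responses `trials x voxels` matrix.
#' @param presentation_map Vector (length = trials) assigning each trial to
#'   an image identifier.
#' @param image_ids Optional expected image identifiers; any listed image
#'   with zero trials is an error.
#' @return `images x voxels` matrix, rows ordered by sorted image
#'   identifier.
#' @export
average_repeats <- function(responses, presentation_map, image_ids = NULL) {
  responses <- as.matrix(responses)
  stopifnot(nrow(responses) == length(presentation_map))
  pm <- as.character(presentation_map)
  ids <- if (is.null(image_ids)) sort(unique(pm)) else as.character(image_ids)
  missing <- setdiff(ids, pm)
  if (length(missing) > 0)
    stop("image(s) with zero trials: ", paste(missing, collapse = ", "))
  out <- t(vapply(ids, function(im)
    colMeans(responses[pm == im, , drop = FALSE]),
    numeric(ncol(responses))))
  rownames(out) <- ids
  colnames(out) <- colnames(responses)
  out
}

#' Score predictions per voxel
#'
#' Computes each voxel's Pearson correlation between observed and predicted
#' test responses and applies the valid-voxel rule.
#'
#' @param observed,predicted `images x voxels` matrices with matching
#'   columns.
#' @param rois Optional [roi_map()]; adds a `roi` column.
#' @param threshold Validity threshold, see [valid_mask()].
#' @param model_id Label recorded on the result.
#' @return An `encoding_result`: a tibble with columns `voxel_id`, `roi`,
#'   `pcc`, `valid`.
#' @export
evaluate_predictions <- function(observed, predicted, rois = NULL,
                                 threshold = 0.41, model_id = "model") {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  stopifnot(identical(dim(observed), dim(predicted)))
  ids <- colnames(observed) %||% paste0("vox", seq_len(ncol(observed)))
  pcc <- vapply(seq_len(ncol(observed)), function(j)
    pearson(observed[, j], predicted[, j]), numeric(1))
  roi <- if (is.null(rois)) NA_character_
    else rois$roi[match(ids, rois$voxel_id)]
  out <- tibble::tibble(voxel_id = ids, roi = roi, pcc = pcc,
                        valid = valid_mask(pcc, threshold)$valid)
  structure(out, model_id = model_id, threshold = threshold,
            class = c("encoding_result", class(out)))
}

#' Mean of the top-n voxel correlations within an ROI
#'
#' The headline per-region summary: the mean of the `n` largest voxel
#' correlations inside the region (all voxels when the region holds fewer
#' than `n`). Ties are broken deterministically by voxel order; undefined
#' correlations are excluded.
#'
#' @param result An [evaluate_predictions()] result.
#' @param roi Region name (base region or derived group LVC/HVC/VC).
#' @param rois The [roi_map()] used to resolve group names; defaults to the
#'   `roi` column for base regions.
#' @param n Number of top voxels (default 100).
#' @return Scalar mean correlation.
#' @export
roi_top_n_mean <- function(result, roi, rois = NULL, n = 100L) {
  ids <- if (!is.null(rois)) roi_voxels(rois, roi)
    else {
      if (!roi %in% result$roi) stop("unknown ROI: ", roi)
      result$voxel_id[!is.na(result$roi) & result$roi == roi]
    }
  sub <- result[result$voxel_id %in% ids & !is.na(result$pcc), ]
  if (nrow(sub) == 0) stop("ROI '", roi, "' has no scored voxels")
  ord <- order(-sub$pcc, seq_len(nrow(sub)))
  mean(sub$pcc[ord][seq_len(min(n, nrow(sub)))])
}

#' Per-region summary table
#'
#' Top-n mean correlation and valid-voxel counts for every base region and
#' the derived groups, in the conventional report layout.
#'
#' @inheritParams roi_top_n_mean
#' @return A tibble with one row per region/group.
#' @export
roi_summary <- function(result, rois, n = 100L) {
  regions <- c(unique(rois$roi), names(attr(rois, "groups")))
  purrr::map_dfr(regions, function(rg) {
    ids <- roi_voxels(rois, rg)
    sub <- result[result$voxel_id %in% ids, ]
    tibble::tibble(
      roi = rg, n_voxels = nrow(sub),
      n_valid = sum(sub$valid),
      top_n_mean = roi_top_n_mean(result, rg, rois, n),
      mean_pcc = mean(sub$pcc, na.rm = TRUE))
  })
}

#' Categorize voxels by which of two models predicts them better
#'
#' Reproduces the scatter-plot reading of a two-model comparison: for each
#' voxel, `red` when model B's correlation is higher, `blue` when model A's
#' is higher, `black` when neither correlation exceeds the validity
#' threshold, and `tie` for exact equality with at least one model valid.
#' Undefined correlations compare lower than any defined value.
#'
#' @param result_A,result_B [evaluate_predictions()] results over the same
#'   voxels.
#' @param threshold Validity threshold.
#' @return A `scatter_compare` tibble with columns `voxel_id`, `roi`,
#'   `pcc_A`, `pcc_B`, `category`; attribute `counts` holds the per-category
#'   tally.
#' @export
scatter_compare <- function(result_A, result_B, threshold = 0.41) {
  if (!setequal(result_A$voxel_id, result_B$voxel_id) ||
      nrow(result_A) != nrow(result_B))
    stop("the two results must cover the same voxel set")
  b <- result_B[match(result_A$voxel_id, result_B$voxel_id), ]
  pa <- result_A$pcc; pb <- b$pcc
  cmp_a <- ifelse(is.na(pa), -Inf, pa)
  cmp_b <- ifelse(is.na(pb), -Inf, pb)
  any_valid <- pmax(cmp_a, cmp_b) > threshold
  category <- dplyr::case_when(
    !any_valid ~ "black",
    cmp_b > cmp_a ~ "red",
    cmp_a > cmp_b ~ "blue",
    TRUE ~ "tie")
  out <- tibble::tibble(voxel_id = result_A$voxel_id, roi = result_A$roi,
                        pcc_A = pa, pcc_B = pb, category = category)
  counts <- c(red = sum(category == "red"), blue = sum(category == "blue"),
              black = sum(category == "black"), tie = sum(category == "tie"))
  structure(out, counts = counts, threshold = threshold,
            model_A = attr(result_A, "model_id"),
            model_B = attr(result_B, "model_id"),
            class = c("scatter_compare", class(out)))
}

#' @export
glance.encoding_result <- function(x, ...) {
  tibble::tibble(model_id = attr(x, "model_id"),
                 n_voxels = nrow(x),
                 n_valid = sum(x$valid),
                 mean_pcc = mean(x$pcc, na.rm = TRUE),
                 max_pcc = if (all(is.na(x$pcc))) NA_real_
                           else max(x$pcc, na.rm = TRUE))
}
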