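# Artifact containers and configuration. Large dense arrays travel as RDS
# containers with named groups; specs and ROI maps are JSON sidecars. Every
# artifact carries a fingerprint so the pipeline can refuse mixed-provenance
# inputs.

#' Write / read a voxel-response container
#'
#' The container holds a `trials x voxels` matrix, unique voxel identifiers,
#' and (for test-split files) the trial-to-image presentation map.
#'
#' @param responses `trials x voxels` finite matrix.
#' @param path File path (`.rds`).
#' @param voxel_ids Voxel identifiers, one per column.
#' @param presentation_map Optional image id per trial.
#' @return `write_responses()` the path invisibly; `read_responses()` a list
#'   with `responses`, `voxel_ids`, `presentation_map`.
#' @export
write_responses <- function(responses, path, voxel_ids = colnames(responses),
                            presentation_map = NULL) {
  responses <- as.matrix(responses)
  stopifnot(!is.null(voxel_ids), length(voxel_ids) == ncol(responses))
  if (!is.null(presentation_map))
    stopifnot(length(presentation_map) == nrow(responses))
  saveRDS(list(responses = unname(responses),
               voxel_ids = as.character(voxel_ids),
               presentation_map = presentation_map,
               fingerprint = fingerprint(responses)),
          path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  x <- readRDS(path)
  for (need in c("responses", "voxel_ids"))
    if (is.null(x[[need]])) stop("response container is missing '", need, "'")
  if (!all(is.finite(x$responses)))
    stop("response matrix contains non-finite entries")
  if (anyDuplicated(x$voxel_ids))
    stop("duplicated voxel ids: ",
         paste(unique(x$voxel_ids[duplicated(x$voxel_ids)]), collapse = ", "))
  if (length(x$voxel_ids) != ncol(x$responses))
    stop("voxel id count does not match the response matrix")
  colnames(x$responses) <- x$voxel_ids
  x[c("responses", "voxel_ids", "presentation_map")]
}

#' Read / write an ROI map as JSON
#'
#' The file maps base region names to voxel-id lists, e.g.
#' `{"V1": ["V1_001", ...], ...}`. The composite groups LVC/HVC/VC are
#' reserved and derived automatically, never stored.
#'
#' @param path JSON file path.
#' @return `read_roi_map()` a [roi_map()]; `write_roi_map()` the path
#'   invisibly.
#' @export
read_roi_map <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(x) == 0) return(roi_map(stats::setNames(list(), character(0))))
  roi_map(as.list(x))
}

#' @rdname read_roi_map
#' @param rois A [roi_map()].
#' @export
write_roi_map <- function(rois, path) {
  regions <- split(rois$voxel_id, rois$roi)
  jsonlite::write_json(regions, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Write / read a feature-stack container
#'
#' @param stack A [feature_stack()].
#' @param path File path (`.rds`).
#' @return The path invisibly / the stack.
#' @export
write_features <- function(stack, path) {
  stopifnot(inherits(stack, "feature_stack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "feature_stack")) stop("not a feature-stack container")
  x
}

write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  jsonlite::write_json(unclass(bundle$spec), p("spec.json"),
                       auto_unbox = TRUE, digits = NA)
  write_roi_map(bundle$rois, p("rois.json"))
  write_features(bundle$features_train, p("features_train.rds"))
  write_features(bundle$features_test, p("features_test.rds"))
  write_responses(bundle$responses$train, p("responses_train.rds"))
  write_responses(bundle$responses$test, p("responses_test.rds"),
                  presentation_map = bundle$responses$presentation_map)
  saveRDS(bundle$truth, p("truth.rds"))
  jsonlite::write_json(
    list(seed = bundle$spec$seed,
         n_train = bundle$spec$n_train, n_test = bundle$spec$n_test,
         feature_width = ncol(feature_matrix(bundle$features_train)),
         backbones = as.list(bundle$features_train$backbone)),
    p("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  spec <- do.call(synth_spec, jsonlite::fromJSON(p("spec.json"))[
    c("n_categories", "images_per_category", "n_test", "test_repeats",
      "image_size", "n_voxels_per_roi", "rois", "sparsity", "noise_sd",
      "seed")])
  te <- readRDS(p("responses_test.rds"))
  list(spec = spec,
       features_train = read_features(p("features_train.rds")),
       features_test = read_features(p("features_test.rds")),
       responses_train = read_responses(p("responses_train.rds")),
       responses_test = read_responses(p("responses_test.rds")),
       truth = readRDS(p("truth.rds")),
       rois = read_roi_map(p("rois.json")))
}
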