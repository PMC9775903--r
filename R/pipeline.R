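# End-to-end orchestration: PCA of the training features, per-voxel sparse
# fits, prediction of the held-out responses, repeat averaging and
# per-region summaries.

#' Pipeline run configuration
#'
#' @param fixture_dir Directory holding a fixture bundle written by
#'   [make_fixture()] (features, responses, ROIs).
#' @param out_dir Optional directory for results, summary and manifest.
#' @param sparsity ROMP sparsity target `K`; `"auto"` sets `K` to half the
#'   PCA dimension (rounded up) so the solver may expand to the full reduced
#'   space - the right budget when validating noiseless recovery. Pass a
#'   number (e.g. 20) for genuinely sparse fits.
#' @param threshold Valid-voxel correlation threshold.
#' @param top_n Top-n used in the per-region summary.
#' @param average_repeats Average repeated test presentations per image
#'   before correlating (the standard protocol for repeated test designs).
#' @param seed Seed recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fixture_dir, out_dir = NULL, sparsity = "auto",
                       threshold = 0.41, top_n = 100L,
                       average_repeats = TRUE, seed = 1L) {
  if (!dir.exists(fixture_dir)) stop("fixture_dir does not exist: ",
                                     fixture_dir)
  structure(list(fixture_dir = fixture_dir, out_dir = out_dir,
                 sparsity = sparsity, threshold = threshold,
                 top_n = as.integer(top_n),
                 average_repeats = isTRUE(average_repeats),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the encoding pipeline on a fixture bundle
#'
#' Executes the full analysis: load features and responses, fit PCA on the
#' training features only, transform both splits with the training model,
#' fit one sparse linear model per voxel, predict the test responses,
#' average repeated presentations, score by Pearson correlation, and
#' summarize per region. Refuses feature files whose backbone fingerprints
#' disagree between splits.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `result` (an `encoding_result`),
#'   `summary` (per-ROI tibble), `models`, `pca`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  stage_times <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_times[[name]] <<- round(proc.time()[3] - t0, 3)
    message(sprintf("[voxkern] %-10s %7.2fs", name, stage_times[[name]]))
    out
  }

  fx <- stage("load", read_fixture(config$fixture_dir))
  if (!identical(unname(fx$features_train$backbone),
                 unname(fx$features_test$backbone)))
    stop("pipeline stage 'load' failed: test features come from a ",
         "different backbone than the training features", call. = FALSE)

  pca <- stage("pca", pca_fit(fx$features_train))
  Ztr <- pca_transform(pca, fx$features_train)
  Zte <- pca_transform(pca, fx$features_test)

  K <- if (identical(config$sparsity, "auto")) max(1L, ceiling(pca$k / 2))
       else as.integer(config$sparsity)
  cfg <- fit_config(K = K, seed = config$seed)
  models <- stage("fit", fit_voxelwise(Ztr, fx$responses_train$responses,
                                       cfg))

  pred <- stage("predict", predict(models, Zte))
  obs <- fx$responses_test$responses
  if (config$average_repeats) {
    if (is.null(fx$responses_test$presentation_map))
      stop("pipeline stage 'average' failed: repeat averaging requested ",
           "but the test container has no presentation map", call. = FALSE)
    obs <- stage("average",
                 average_repeats(obs, fx$responses_test$presentation_map))
  }
  result <- stage("evaluate",
                  evaluate_predictions(obs, pred, rois = fx$rois,
                                       threshold = config$threshold,
                                       model_id = "mixed"))
  summary <- roi_summary(result, fx$rois, n = config$top_n)

  manifest <- list(seed = config$seed, sparsity_K = K,
                   threshold = config$threshold,
                   pca_k = pca$k,
                   n_voxels = nrow(result),
                   backbones = as.list(fx$features_train$backbone),
                   config_hash = fingerprint(list(config$threshold,
                                                  config$top_n, K,
                                                  config$seed)),
                   stage_seconds = as.list(stage_times),
                   total_seconds = round(proc.time()[3] - t_all, 3))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(result),
                     file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(summary),
                     file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(result = result, summary = summary, models = models,
                 pca = pca, manifest = manifest))
}
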