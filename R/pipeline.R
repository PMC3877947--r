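#' End-to-end analysis of one scan
#'
#' Runs the full quantification chain on a scintigram pair: atlas
#' registration, adaptive hot-spot detection in both views, feature
#' extraction, per-region classification, skeletal involvement and the bone
#' scan index.
#'
#' @param pair a `scintigram_pair`.
#' @param registry a `classifier_registry` covering `pair$sex`.
#' @param atlas optional preloaded `skeletal_atlas` (loaded from `pair$sex`
#'   when omitted).
#' @param segmentation optional precomputed `segmentation_result` (skips
#'   registration; used when the true segmentation is known).
#' @param detect a [detect_control()].
#' @param register a [register_control()].
#' @param metastasis_threshold probability cutoff for counting a hot spot into
#'   the BSI.
#' @return a `patient_result` (see [compute_bsi()]) with the segmentation
#'   quality attached.
#' @export
run_pipeline <- function(pair, registry, atlas = NULL, segmentation = NULL,
                         detect = detect_control(),
                         register = register_control(),
                         metastasis_threshold = 0.5) {
  stopifnot(inherits(pair, "scintigram_pair"))
  if (is.null(atlas)) atlas <- load_atlas(pair$sex)
  if (is.null(segmentation)) segmentation <- register_atlas(atlas, pair, register)
  hs <- detect_scan(pair, segmentation, atlas, detect)
  hs <- classify_hotspots(hs, registry, pair$sex)
  hs <- skeletal_involvement(hs, segmentation, atlas)
  result <- compute_bsi(hs, segmentation, metastasis_threshold)
  result$registration_quality <- segmentation$quality
  result$sex <- pair$sex
  result
}

#' Batch analysis with a failure manifest
#'
#' Applies [run_pipeline()] to a list of scans, continuing past per-scan
#' failures.
#'
#' @param pairs named list of `scintigram_pair`s (names become patient ids).
#' @param registry a `classifier_registry`.
#' @param ... passed to [run_pipeline()].
#' @return list with `results` (named list of `patient_result`s), `manifest`
#'   (tibble of failures: `patient`, `error`), and `n_failed`.
#' @export
run_pipeline_batch <- function(pairs, registry, ...) {
  ids <- names(pairs)
  if (is.null(ids)) ids <- paste0("patient_", seq_along(pairs))
  results <- list()
  failures <- list()
  atlases <- list()
  for (i in seq_along(pairs)) {
    res <- tryCatch({
      sx <- pairs[[i]]$sex
      if (is.null(atlases[[sx]])) atlases[[sx]] <- load_atlas(sx)
      run_pipeline(pairs[[i]], registry, atlas = atlases[[sx]], ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(patient = ids[i], error = conditionMessage(res))
    } else {
      results[[ids[i]]] <- res
    }
  }
  list(results = results,
       manifest = if (length(failures)) dplyr::bind_rows(failures) else
         tibble::tibble(patient = character(), error = character()),
       n_failed = length(failures))
}
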