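#' Read a pipeline configuration from YAML
#'
#' The config carries two blocks, `segmentation` (fields of
#' [canny_params()]) and `threshold` (fields of [threshold_spec()]); fields
#' left out take the package defaults. Per-image overrides can be applied by
#' editing the returned objects before calling [quantify_batch()].
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` (a `wq_canny_params`) and `spec`
#'   (a `wq_threshold_spec`).
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  params <- do.call(canny_params, cfg$segmentation %||% list())
  if (is.null(cfg$threshold$threshold))
    stop("config must set threshold: threshold (the uniform brightness cutoff)")
  spec <- do.call(threshold_spec, cfg$threshold)
  list(params = params, spec = spec)
}
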