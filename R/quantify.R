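#' Proliferation index of one disc
#'
#' The ratio of GFP-positive area to total wing disc area, the measure used
#' to compare proliferation across genotypes while compensating for
#' developmental asynchrony. Dimensionless ("AU"); exact pixel-count
#' arithmetic.
#'
#' @param gfp_mask,disc_mask Region masks (see [region_mask()]).
#' @return `area_px(gfp_mask) / area_px(disc_mask)`.
#' @examples
#' d <- matrix(TRUE, 100, 100)
#' g <- matrix(FALSE, 100, 100); g[1:25, ] <- TRUE
#' proliferation_index(region_mask(g), region_mask(d))  # 0.25
#' @export
proliferation_index <- function(gfp_mask, disc_mask) {
  da <- area_px(disc_mask)
  if (da == 0L) stop("disc area is zero: cannot normalize the GFP area")
  area_px(gfp_mask) / da
}

# Fingerprint of every parameter that affects segmentation, recorded per
# image so results are auditable.
params_fingerprint <- function(params, spec) {
  rlang::hash(list(unclass(params), unclass(spec)))
}

# Segment one image and compute its index; shared by quantify_batch and the
# phantom-based simulations.
quantify_image <- function(image, params, spec) {
  disc <- segment_disc(image$junction_channel, params)
  gfp <- segment_gfp(image$reporter_channel, spec, disc_mask = disc)
  gfp_unres <- segment_gfp(image$reporter_channel,
                           threshold_spec(spec$threshold, spec$scope,
                                          restrict_to_disc = FALSE))
  list(disc = disc, gfp = gfp,
       record = data.frame(
         image_id = image$image_id,
         genotype = image$genotype,
         disc_area_px = area_px(disc),
         gfp_area_px = area_px(gfp),
         gfp_area_unrestricted_px = area_px(gfp_unres),
         proliferation_index = proliferation_index(gfp, disc),
         threshold_used = spec$threshold,
         params_fingerprint = params_fingerprint(params, spec),
         status = "ok", reason = "",
         stringsAsFactors = FALSE))
}

#' Recover the proliferation index from one image
#'
#' Runs the full per-image pipeline (disc segmentation, GFP thresholding,
#' index) on an in-memory [disc_image()]; used heavily on phantoms.
#'
#' @param image A `wq_disc_image`.
#' @param params A [canny_params()].
#' @param spec A [threshold_spec()].
#' @return The proliferation index (numeric scalar).
#' @export
recover_index <- function(image, params = canny_params(), spec) {
  quantify_image(image, params, spec)$record$proliferation_index
}

#' Quantify a whole batch of images
#'
#' Runs the segmentation pipeline over every manifest row, in manifest
#' order. Images that fail (unreadable file, "no disc found", ...) yield an
#' explicit failure row carrying the reason — they are never silently
#' dropped, so per-condition n stays auditable.
#'
#' @param manifest A [load_manifest()] data frame (or one shaped like it).
#' @param params A [canny_params()].
#' @param spec A [threshold_spec()]; with scope `"per_image"` the records
#'   are marked non-uniform.
#' @param output_dir If non-`NULL`, `results.csv` and one S1-style overlay
#'   PNG per image are written there.
#' @param verbose Print a one-line run log (parameters, failure count).
#' @return A data frame of per-image records (class `wq_quant`), one row per
#'   manifest row, with a `status`/`reason` pair ("ok" or "failed").
#' @export
quantify_batch <- function(manifest, params = canny_params(), spec,
                           output_dir = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(manifest), inherits(spec, "wq_threshold_spec"))
  if (!is.null(output_dir)) dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    rows[[i]] <- tryCatch({
      img <- load_disc_image(c(junction = r$junction_path, reporter = r$reporter_path),
                             image_id = r$image_id, genotype = r$genotype)
      q <- quantify_image(img, params, spec)
      if (!is.null(output_dir))
        write_overlay_png(img, q$disc, q$gfp,
                          file.path(output_dir, paste0(r$image_id, "_overlay.png")))
      q$record
    }, error = function(e) {
      data.frame(image_id = r$image_id, genotype = r$genotype,
                 disc_area_px = NA_integer_, gfp_area_px = NA_integer_,
                 gfp_area_unrestricted_px = NA_integer_,
                 proliferation_index = NA_real_,
                 threshold_used = spec$threshold,
                 params_fingerprint = params_fingerprint(params, spec),
                 status = "failed", reason = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  n_fail <- sum(out$status == "failed")
  if (n_fail == nrow(out)) stop("all ", n_fail, " images in the batch failed")
  if (verbose)
    message(sprintf(
      "quantify_batch: %d image(s), %d failed; sigma=%.2f closing=%d threshold=%.4f scope=%s",
      nrow(out), n_fail, params$smoothing_sigma, params$closing_radius,
      spec$threshold, spec$scope))
  attr(out, "uniform_threshold") <- spec$scope == "batch"
  class(out) <- c("wq_quant", "data.frame")
  if (!is.null(output_dir))
    write_results_csv(out, file.path(output_dir, "results.csv"))
  out
}

#' Write the batch results table
#'
#' Deterministic CSV (no timestamps): identical inputs and configuration
#' give byte-identical files. The index is stored at full precision; round
#' only for display.
#'
#' @param records Output of [quantify_batch()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
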