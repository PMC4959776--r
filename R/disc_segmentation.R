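#' Parameters for disc outline detection
#'
#' Controls the Canny edge detector and the outline-closing/filling steps
#' that turn a junction-marker (DE-cadherin) channel into a whole-disc mask.
#'
#' By default the hysteresis thresholds adapt to the image: the high
#' threshold is the `high_quantile` quantile of the non-zero gradient
#' magnitude and the low threshold is `low_high_ratio` times the high one.
#' Quantile thresholds track staining intensity across batches; absolute
#' thresholds (on the \[0, 1\] gradient-magnitude scale, where a unit
#' intensity step gives magnitude about 1) can be supplied instead via
#' `low_threshold`/`high_threshold`.
#'
#' @param smoothing_sigma Gaussian smoothing bandwidth in pixels.
#' @param low_threshold,high_threshold Optional absolute hysteresis
#'   thresholds in \[0, 1\] with `low < high`; both must be given together.
#' @param high_quantile Quantile of non-zero gradient magnitude used for the
#'   high threshold when absolute thresholds are not given.
#' @param low_high_ratio Low threshold as a fraction of the high one.
#' @param closing_radius Disk radius (px) for morphological closing of the
#'   edge map before filling; bridges small gaps in the junctional outline.
#' @param min_area_fraction Minimum disc size as a fraction of the image
#'   area; smaller filled components are ignored by [select_disc()].
#' @return An object of class `wq_canny_params`.
#' @export
canny_params <- function(smoothing_sigma = 2, low_threshold = NULL,
                         high_threshold = NULL, high_quantile = 0.9,
                         low_high_ratio = 0.5, closing_radius = 3L,
                         min_area_fraction = 0.05) {
  stopifnot(smoothing_sigma > 0, closing_radius >= 0,
            min_area_fraction > 0, min_area_fraction < 1,
            high_quantile > 0, high_quantile < 1,
            low_high_ratio > 0, low_high_ratio <= 1)
  if (xor(is.null(low_threshold), is.null(high_threshold)))
    stop("give both low_threshold and high_threshold, or neither")
  if (!is.null(low_threshold)) {
    stopifnot(low_threshold >= 0, high_threshold <= 1)
    if (low_threshold >= high_threshold)
      stop("low_threshold must be < high_threshold")
  }
  structure(list(smoothing_sigma = smoothing_sigma,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 high_quantile = high_quantile,
                 low_high_ratio = low_high_ratio,
                 closing_radius = as.integer(closing_radius),
                 min_area_fraction = min_area_fraction),
            class = "wq_canny_params")
}

#' Canny edge detection on the junction channel
#'
#' Gaussian smoothing at `smoothing_sigma`, Sobel gradients, non-maximum
#' suppression and hysteresis thresholding. A constant image yields an empty
#' edge map (downstream disc selection then reports "no disc found").
#'
#' @param channel Numeric matrix, intensities in \[0, 1\].
#' @param params A [canny_params()] object.
#' @return A [region_mask()] of edge pixels (thin, 1-2 px wide).
#' @export
detect_edges <- function(channel, params = canny_params()) {
  stopifnot(is.matrix(channel), inherits(params, "wq_canny_params"))
  if (is.null(params$high_threshold)) {
    g <- cpp_gradients(channel, params$smoothing_sigma)
    pos <- g$mag[g$mag > 1e-12]
    if (length(pos) == 0L)
      return(region_mask(matrix(FALSE, nrow(channel), ncol(channel))))
    high <- as.numeric(quantile(pos, params$high_quantile, names = FALSE))
    low <- params$low_high_ratio * high
    region_mask(cpp_nms_hysteresis(g$gx, g$gy, g$mag, low, high))
  } else {
    region_mask(cpp_canny(channel, params$smoothing_sigma,
                          params$low_threshold, params$high_threshold))
  }
}

#' Close edge gaps and fill the outline interior
#'
#' Fills the interior of the detected outline: a pixel is interior iff it is
#' not 4-connected-reachable from the image border through non-edge pixels.
#' With `closing_radius > 0` the edge map is first dilated with a disk of
#' that radius (bridging gaps in the junctional outline), the dilated
#' outline is filled, and the filled region is eroded with the same disk so
#' the boundary returns to its detected position. The dilate-fill-erode
#' order is what makes gap bridging effective: closing a thin outline alone
#' re-erodes the bridge before the fill can use it. The result always
#' contains the input edges, so the disc mask includes the outline itself;
#' if no enclosed interior exists the edges come back unchanged.
#'
#' @param edge_mask A [region_mask()] or logical matrix of edge pixels.
#' @param params A [canny_params()] (only `closing_radius` is used).
#' @return A [region_mask()] of the filled outline(s).
#' @export
close_and_fill <- function(edge_mask, params = canny_params()) {
  m <- as_mask_matrix(edge_mask)
  r <- params$closing_radius
  if (r > 0L) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    d <- as.matrix(EBImage::dilate(m * 1.0, brush)) > 0.5
    filled <- !cpp_flood_outside(d)
    e <- as.matrix(EBImage::erode(filled * 1.0, brush)) > 0.5
    region_mask(e | m)
  } else {
    region_mask(!cpp_flood_outside(m))
  }
}

#' Select the wing disc component from a filled mask
#'
#' Returns the largest 8-connected component; components smaller than
#' `min_area_fraction` of the image area are ignored (the boundary case is
#' retained: the comparison is `>=`).
#'
#' @param filled_mask A [region_mask()] or logical matrix from
#'   [close_and_fill()].
#' @param params A [canny_params()] (only `min_area_fraction` is used).
#' @return A [region_mask()] containing the single disc component.
#' @export
select_disc <- function(filled_mask, params = canny_params()) {
  m <- as_mask_matrix(filled_mask)
  lab <- cpp_label(m, 8L)
  sizes <- tabulate(lab[lab > 0L])
  npix <- length(m)
  largest_frac <- if (length(sizes)) max(sizes) / npix else 0
  keep <- which(sizes >= params$min_area_fraction * npix)
  if (!length(keep))
    stop(structure(class = c("wq_no_disc_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("no disc found: largest filled component covers ",
                            "%.4f of the image (min_area_fraction = %.4f)"),
                     largest_frac, params$min_area_fraction),
                     call = sys.call(-1))))
  best <- keep[which.max(sizes[keep])]
  region_mask(lab == best)
}

#' Segment the whole wing disc from the junction channel
#'
#' Composition [detect_edges()] -> [close_and_fill()] -> [select_disc()]:
#' Canny edge detection on the DE-cadherin (junction) channel, closing and
#' filling of the resulting outline, and selection of the largest filled
#' component as the disc.
#'
#' @inheritParams detect_edges
#' @return A [region_mask()] of the whole disc (outline + interior).
#' @export
segment_disc <- function(channel, params = canny_params()) {
  edges <- detect_edges(channel, params)
  filled <- close_and_fill(edges, params)
  select_disc(filled, params)
}
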