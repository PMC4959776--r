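#' Uniform brightness threshold specification
#'
#' Holds the manually determined threshold applied to the reporter (GFP)
#' channel, on the normalized \[0, 1\] intensity scale. The default scope is
#' `"batch"`: one threshold for the whole experiment, matching a uniform
#' threshold across conditions; `"per_image"` is available for exploration
#' and is flagged as non-uniform in batch output.
#'
#' @param threshold Intensity cutoff in \[0, 1\]; pixels with intensity
#'   `>= threshold` (inclusive) are GFP-positive.
#' @param scope `"batch"` or `"per_image"`.
#' @param restrict_to_disc If `TRUE` (default) the GFP mask is intersected
#'   with the disc mask, so the proliferation index is bounded by 1. Both the
#'   restricted and unrestricted areas are recorded by [quantify_batch()].
#' @return An object of class `wq_threshold_spec`.
#' @export
threshold_spec <- function(threshold, scope = c("batch", "per_image"),
                           restrict_to_disc = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  scope <- match.arg(scope)
  structure(list(threshold = threshold, scope = scope,
                 restrict_to_disc = isTRUE(restrict_to_disc)),
            class = "wq_threshold_spec")
}

#' Segment the GFP-positive region by uniform thresholding
#'
#' A pixel is GFP-positive iff its normalized reporter intensity is greater
#' than or equal to the threshold. With `restrict_to_disc` the mask is
#' intersected with the disc mask.
#'
#' @param reporter_channel Numeric matrix, intensities in \[0, 1\].
#' @param spec A [threshold_spec()].
#' @param disc_mask Disc [region_mask()]; required when
#'   `spec$restrict_to_disc` is `TRUE`.
#' @return A [region_mask()] of GFP-positive pixels.
#' @export
segment_gfp <- function(reporter_channel, spec, disc_mask = NULL) {
  stopifnot(is.matrix(reporter_channel), inherits(spec, "wq_threshold_spec"))
  m <- reporter_channel >= spec$threshold
  if (spec$restrict_to_disc) {
    if (is.null(disc_mask))
      stop("restrict_to_disc = TRUE requires a disc_mask")
    dm <- as_mask_matrix(disc_mask)
    if (!identical(dim(dm), dim(reporter_channel)))
      stop("disc_mask shape does not match the reporter channel")
    m <- m & dm
  }
  region_mask(m)
}

#' Suggest a batch threshold by Otsu's method
#'
#' Pools the intensity histogram (256 bins on \[0, 1\]) of one or more
#' reporter channels and returns the cutpoint maximizing the between-class
#' variance. This is offered as a reproducible starting point for the
#' manually determined threshold only; the recorded analysis threshold is
#' always the one in the [threshold_spec()].
#'
#' @param reporter_channels A numeric matrix or a list of them.
#' @param bins Number of histogram bins.
#' @return A single threshold value in (0, 1): pixels `>=` it are foreground.
#' @export
suggest_threshold <- function(reporter_channels, bins = 256L) {
  if (is.matrix(reporter_channels)) reporter_channels <- list(reporter_channels)
  x <- unlist(lapply(reporter_channels, as.numeric), use.names = FALSE)
  stopifnot(all(x >= 0), all(x <= 1))
  bin <- pmin(floor(x * bins), bins - 1L)        # bin k covers [k/bins, (k+1)/bins)
  counts <- tabulate(bin + 1L, nbins = bins)
  if (sum(counts > 0L) < 2L)
    stop("no bimodality: pooled intensities are constant")
  mids <- (seq_len(bins) - 0.5) / bins
  w <- cumsum(counts)                            # class sizes below each cut
  mu <- cumsum(counts * mids)
  n <- w[bins]; mu_tot <- mu[bins]
  # between-class variance for cut after bin k (foreground = bins > k)
  k <- seq_len(bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (n * mu[k][valid] - mu_tot * w0[valid])^2 /
    (w0[valid] * w1[valid])
  best <- which.max(bcv)                         # first maximum breaks ties
  best / bins                                    # lower edge of first foreground bin
}
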