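#' Binary region mask
#'
#' A 2D boolean mask with a cached pixel-area count, used for both the
#' whole-disc region and the GFP-positive region.
#'
#' @param mask Logical matrix (`TRUE` = inside the region).
#' @return An object of class `wq_region_mask` with elements `mask`
#'   (logical matrix) and `area_px` (integer count of `TRUE` pixels).
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
#' region_mask(m)
#' @export
region_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0.5
  stopifnot(is.logical(mask), is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, area_px = sum(mask)), class = "wq_region_mask")
}

#' Pixel area of a region mask
#'
#' @param x A [region_mask()] or a logical matrix.
#' @return Integer number of pixels in the region.
#' @export
area_px <- function(x) {
  if (inherits(x, "wq_region_mask")) x$area_px else sum(as_mask_matrix(x))
}

# Coerce region_mask / logical matrix / numeric matrix to a logical matrix.
as_mask_matrix <- function(x) {
  if (inherits(x, "wq_region_mask")) return(x$mask)
  if (is.numeric(x) && is.matrix(x)) return(x > 0.5)
  stopifnot(is.logical(x), is.matrix(x))
  x
}

#' @export
print.wq_region_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<wq_region_mask> %d x %d, area %d px (%.1f%% of image)\n",
              d[1], d[2], x$area_px, 100 * x$area_px / prod(d)))
  invisible(x)
}
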