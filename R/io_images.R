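#' Construct a two-channel wing disc image record
#'
#' Bundles the junction-marker (DE-cadherin) channel and the GFP reporter
#' channel of one imaged disc with its identity metadata. Channels are stored
#' as floating-point intensities on \[0, 1\]; all downstream thresholds are
#' expressed on this normalized scale so a "uniform brightness threshold" is
#' portable across bit depths.
#'
#' @param junction_channel,reporter_channel Numeric matrices of identical
#'   dimensions with intensities in \[0, 1\] (rows = image rows, origin at
#'   the top-left).
#' @param image_id Character scalar identifying the image.
#' @param genotype Free-text condition label (e.g. `"ptc>Cdc42-RNAi+P35"`).
#' @param bit_depth Original bit depth of the source data (8 or 16).
#' @param pixel_size_um Optional microns-per-pixel; areas are reported in
#'   pixels and converted to um^2 only when this is provided.
#' @return An object of class `wq_disc_image`.
#' @export
disc_image <- function(junction_channel, reporter_channel, image_id,
                       genotype = "unknown", bit_depth = 16L,
                       pixel_size_um = NULL) {
  stopifnot(is.matrix(junction_channel), is.matrix(reporter_channel))
  if (!identical(dim(junction_channel), dim(reporter_channel)))
    stop("channel shape mismatch: junction is ", paste(dim(junction_channel), collapse = "x"),
         " but reporter is ", paste(dim(reporter_channel), collapse = "x"))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  rng <- range(junction_channel, reporter_channel)
  if (rng[1] < 0 || rng[2] > 1)
    stop("channel intensities must lie in [0, 1] after normalization")
  if (!is.null(pixel_size_um)) stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  structure(list(junction_channel = junction_channel,
                 reporter_channel = reporter_channel,
                 image_id = as.character(image_id),
                 genotype = as.character(genotype),
                 bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um),
            class = "wq_disc_image")
}

#' @export
print.wq_disc_image <- function(x, ...) {
  cat(sprintf("<wq_disc_image> %s [%s], %d x %d px, %d-bit source\n",
              x$image_id, x$genotype, nrow(x$junction_channel),
              ncol(x$junction_channel), x$bit_depth))
  invisible(x)
}

# Read one grayscale or multichannel image file; returns list(planes, bits).
# Planes are matrices normalized to [0,1] by 2^bits - 1.
read_image_file <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # libtiff warns about ExtraSamples on plain 2-sample grayscale stacks
    raw <- tryCatch(suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE)),
                    error = function(e) stop("unreadable TIFF ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
    bits <- attr(raw[[1]], "bits.per.sample") %||% 16L
    planes <- list()
    for (pl in raw) {
      a <- unclass(pl)
      if (length(dim(a)) == 3L) {
        planes <- c(planes, lapply(seq_len(dim(a)[3]), function(k) a[, , k]))
      } else if (length(dim(a)) == 2L) {
        planes <- c(planes, list(a))
      } else {
        stop("image in ", path, " has more than 2 spatial dimensions; ",
             "project z-stacks to 2D before loading")
      }
    }
    list(planes = planes, bits = as.integer(bits))
  } else if (ext == "png") {
    a <- tryCatch(png::readPNG(path),
                  error = function(e) stop("unreadable PNG ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    if (length(dim(a)) == 3L)
      planes <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
    else planes <- list(a)
    list(planes = planes, bits = 8L)
  } else stop("unsupported image format '", ext, "' for ", path,
              " (TIFF or PNG expected)")
}

#' Load a two-channel disc image from file(s)
#'
#' Reads the junction and reporter channels either from two single-channel
#' files or from one multichannel file, rescales intensities to \[0, 1\] by
#' `2^bit_depth - 1`, and validates shapes. Channel identity always comes
#' from `channel_map`, never from file metadata.
#'
#' @param paths Character vector of one (multichannel) or two file paths.
#'   With two paths, name them `junction` and `reporter`.
#' @param channel_map For a single multichannel file, a named integer vector
#'   `c(junction = i, reporter = j)` giving plane indices.
#' @param image_id,genotype,pixel_size_um Passed to [disc_image()].
#' @return A `wq_disc_image`.
#' @export
load_disc_image <- function(paths, channel_map = c(junction = 1L, reporter = 2L),
                            image_id, genotype = "unknown", pixel_size_um = NULL) {
  stopifnot(all(c("junction", "reporter") %in% names(channel_map)))
  if (length(paths) == 2L) {
    if (!all(c("junction", "reporter") %in% names(paths)))
      stop("with two paths, name them 'junction' and 'reporter'")
    jf <- read_image_file(paths[["junction"]])
    rf <- read_image_file(paths[["reporter"]])
    if (length(jf$planes) != 1L || length(rf$planes) != 1L)
      stop("per-channel files must be single-plane grayscale images; ",
           "project z-stacks to 2D before loading")
    junction <- jf$planes[[1]]; reporter <- rf$planes[[1]]
    bits <- max(jf$bits, rf$bits)
  } else if (length(paths) == 1L) {
    f <- read_image_file(paths[[1]])
    idx <- channel_map[c("junction", "reporter")]
    if (any(idx > length(f$planes)))
      stop("channel_map indexes plane ", max(idx), " but ", paths[[1]],
           " has only ", length(f$planes), " plane(s)")
    junction <- f$planes[[idx[["junction"]]]]
    reporter <- f$planes[[idx[["reporter"]]]]
    bits <- f$bits
  } else stop("paths must have length 1 or 2")
  disc_image(junction, reporter, image_id = image_id, genotype = genotype,
             bit_depth = bits, pixel_size_um = pixel_size_um)
}

#' Load and validate a batch manifest
#'
#' The manifest is a UTF-8 CSV with a header row and required columns
#' `image_id`, `genotype`, `junction_path`, `reporter_path`; relative paths
#' are resolved against the manifest's directory. Row order is preserved.
#'
#' @param path Path to the manifest CSV.
#' @param check_files Verify that every referenced image file exists.
#' @return A data frame of class `wq_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "genotype", "junction_path", "reporter_path")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  dup <- unique(m$image_id[duplicated(m$image_id)])
  if (length(dup))
    stop("duplicate image_id in manifest: ", paste(dup, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  m$junction_path <- resolve(m$junction_path)
  m$reporter_path <- resolve(m$reporter_path)
  if (check_files) {
    for (i in seq_len(nrow(m))) {
      for (col in c("junction_path", "reporter_path")) {
        if (!file.exists(m[[col]][i]))
          stop("manifest row ", i, " (image_id ", m$image_id[i],
               "): file not found: ", m[[col]][i])
      }
    }
  }
  class(m) <- c("wq_manifest", "data.frame")
  m
}

#' Write a single channel as a 16-bit grayscale TIFF
#'
#' @param channel Numeric matrix with values in \[0, 1\].
#' @param path Output path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(channel, path, bits_per_sample = 16L) {
  stopifnot(is.matrix(channel), all(channel >= 0), all(channel <= 1))
  tiff::writeTIFF(channel, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' Write / read a binary mask as an 8-bit PNG (0/255)
#'
#' The pair is a bit-exact round trip for any logical matrix.
#'
#' @param mask A [region_mask()] or logical matrix.
#' @param path File path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a [region_mask()].
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  region_mask(a >= 0.5)
}

# One-pixel-wide outline of a mask: pixels whose 4-neighbourhood leaves the
# region (image border counts as outside).
mask_outline <- function(mask) {
  m <- as_mask_matrix(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  m & !interior
}

#' Write an overlay rendering of the segmented regions
#'
#' Renders the junction channel in grayscale with the whole-disc outline in
#' red and the GFP-region outline in green, as an RGB PNG.
#'
#' @param image A `wq_disc_image`.
#' @param disc_mask,gfp_mask Region masks (the GFP mask may be `NULL`).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, disc_mask, gfp_mask, path) {
  base <- image$junction_channel
  rgb <- array(rep(base, 3L), dim = c(dim(base), 3L))
  dout <- mask_outline(disc_mask)
  rgb[, , 1][dout] <- 1; rgb[, , 2][dout] <- 0; rgb[, , 3][dout] <- 0
  if (!is.null(gfp_mask)) {
    gout <- mask_outline(gfp_mask)
    rgb[, , 1][gout] <- 0; rgb[, , 2][gout] <- 1; rgb[, , 3][gout] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
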