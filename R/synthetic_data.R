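#' Specification of a synthetic wing-disc phantom
#'
#' A phantom emulates the structure the segmentation pipeline assumes: one
#' closed, star-convex disc outline (a bright junctional band, as with
#' DE-cadherin staining, over a faint interior mesh texture) and a uniformly
#' bright vertical reporter stripe through the disc (the GAL4-driver
#' region), with Poisson photon noise and Gaussian read noise on the
#' normalized intensity scale. The boundary is a low-order harmonic
#' perturbation of a circle so closing/filling is exercised on non-circular
#' shapes; its amplitude is capped at 0.2 of the radius to keep the outline
#' closed.
#'
#' @param image_size `(rows, cols)` of the image.
#' @param disc_center `(row, col)` of the disc centre; default image centre.
#' @param disc_radius Mean boundary radius in pixels.
#' @param boundary_irregularity Amplitude of the radial perturbation as a
#'   fraction of the radius, in \[0, 0.2\].
#' @param stripe_fraction Target GFP area / disc area, in \[0, 1\].
#' @param junction_contrast Peak junctional band intensity in (0, 1\].
#' @param gfp_contrast Reporter stripe intensity in (0, 1\].
#' @param noise_sd Gaussian read-noise s.d. on the \[0, 1\] scale.
#' @param photon_scale Photons at unit intensity for the Poisson component;
#'   0 disables photon noise.
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @return An object of class `wq_phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L), disc_center = NULL,
                         disc_radius = 80, boundary_irregularity = 0.08,
                         stripe_fraction = 0.25, junction_contrast = 0.8,
                         gfp_contrast = 0.8, noise_sd = 0.02,
                         photon_scale = 400, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16L),
            disc_radius > 0,
            boundary_irregularity >= 0, boundary_irregularity <= 0.2,
            stripe_fraction >= 0, stripe_fraction <= 1,
            junction_contrast > 0, junction_contrast <= 1,
            gfp_contrast > 0, gfp_contrast <= 1,
            noise_sd >= 0, photon_scale >= 0)
  if (is.null(disc_center)) disc_center <- (image_size + 1) / 2
  r_max <- disc_radius * (1 + boundary_irregularity)
  margin <- min(disc_center[1] - 1, image_size[1] - disc_center[1],
                disc_center[2] - 1, image_size[2] - disc_center[2])
  if (r_max + 5 > margin)
    stop("disc does not fit in the image with a 5 px margin")
  structure(list(image_size = as.integer(image_size),
                 disc_center = as.numeric(disc_center),
                 disc_radius = disc_radius,
                 boundary_irregularity = boundary_irregularity,
                 stripe_fraction = stripe_fraction,
                 junction_contrast = junction_contrast,
                 gfp_contrast = gfp_contrast,
                 noise_sd = noise_sd, photon_scale = photon_scale,
                 seed = as.integer(seed)),
            class = "wq_phantom_spec")
}

#' Generate one phantom disc image with ground truth
#'
#' The disc region is bounded by `r(theta) = disc_radius * (1 + sum of
#' seeded order-2..4 harmonics)`; the junction channel carries the boundary
#' band plus interior mesh, the reporter channel carries the stripe (exactly
#' zero outside it before noise). The stripe width is found by bisection on
#' the discrete masks so that stripe-in-disc area / disc area hits
#' `stripe_fraction` to within 0.02. Ground-truth masks are the noise-free
#' geometric sets; the true index is their exact pixel-count ratio.
#'
#' @param spec A [phantom_spec()].
#' @param image_id,genotype Metadata for the returned [disc_image()].
#' @return A list with elements `image` (a `wq_disc_image`) and `truth`
#'   (list of `disc_mask`, `gfp_mask` as [region_mask()]s, and `true_index`).
#' @export
generate_phantom <- function(spec, image_id = "phantom", genotype = "synthetic") {
  stopifnot(inherits(spec, "wq_phantom_spec"))
  local_seed(spec$seed, {
    nr <- spec$image_size[1]; nc <- spec$image_size[2]
    cy <- spec$disc_center[1]; cx <- spec$disc_center[2]
    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dy <- row - cy; dx <- col - cx
    rho <- sqrt(dy^2 + dx^2)
    theta <- atan2(dy, dx)

    # star-convex boundary: seeded order-2..4 harmonics, total amplitude
    # equal to boundary_irregularity
    k <- 2:4
    w <- runif(3); phase <- runif(3, 0, 2 * pi)
    amp <- if (spec$boundary_irregularity > 0) {
      spec$boundary_irregularity * w / sum(w)
    } else rep(0, 3)
    perturb <- matrix(0, nr, nc)
    for (h in seq_along(k))
      perturb <- perturb + amp[h] * cos(k[h] * theta + phase[h])
    r_theta <- spec$disc_radius * (1 + perturb)

    disc <- rho <= r_theta

    # junction channel: bright band just inside the boundary over a faint
    # interior mesh; dark background
    band_w <- 3
    band <- disc & (rho >= r_theta - band_w)
    mesh_period <- 8
    mesh_phase <- runif(2, 0, 2 * pi)
    mesh <- sin(2 * pi * col / mesh_period + mesh_phase[1]) *
      sin(2 * pi * row / mesh_period + mesh_phase[2])
    junction <- matrix(0.02, nr, nc)
    junction[disc] <- 0.35 * spec$junction_contrast +
      0.1 * spec$junction_contrast * mesh[disc]
    junction[band] <- spec$junction_contrast

    # reporter channel: vertical stripe through the disc centre, width found
    # by bisection on the discrete stripe-in-disc fraction
    disc_area <- sum(disc)
    gfp <- matrix(FALSE, nr, nc)
    if (spec$stripe_fraction > 0) {
      # quarter-pixel centre offset: the stripe's two edges then cross
      # integer columns at different widths, so bisection resolves the
      # discrete fraction one column at a time
      sx <- cx + 0.25
      frac_at <- function(w) sum(disc & abs(col - sx) <= w / 2) / disc_area
      lo <- 0; hi <- 2 * nc
      for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (frac_at(mid) < spec$stripe_fraction) lo <- mid else hi <- mid
      }
      w <- if (abs(frac_at(lo) - spec$stripe_fraction) <
               abs(frac_at(hi) - spec$stripe_fraction)) lo else hi
      gfp <- disc & abs(col - sx) <= w / 2
      if (abs(sum(gfp) / disc_area - spec$stripe_fraction) > 0.02)
        stop("stripe_fraction ", spec$stripe_fraction,
             " is unreachable for this geometry")
    }
    reporter <- matrix(0, nr, nc)
    reporter[gfp] <- spec$gfp_contrast

    add_noise <- function(x) {
      if (spec$photon_scale > 0)
        x <- matrix(rpois(length(x), x * spec$photon_scale) / spec$photon_scale,
                    nrow(x), ncol(x))
      if (spec$noise_sd > 0)
        x <- x + matrix(rnorm(length(x), sd = spec$noise_sd), nrow(x), ncol(x))
      pmin(pmax(x, 0), 1)
    }
    junction <- add_noise(junction)
    reporter <- add_noise(reporter)

    list(image = disc_image(junction, reporter, image_id = image_id,
                            genotype = genotype, bit_depth = 16L),
         truth = list(disc_mask = region_mask(disc),
                      gfp_mask = region_mask(gfp),
                      true_index = sum(gfp) / disc_area))
  })
}

# Derive a per-image RNG seed from (experiment seed, image index); keeps
# every image individually regenerable and all seeds below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 100003 + as.double(index) * 7919) %% 2147483629)
}

# Truncated-normal draw on [0, 1] by rejection.
rtrunc01 <- function(mean, sd) {
  if (sd == 0) return(min(max(mean, 0), 1))
  for (i in 1:10000) {
    z <- rnorm(1, mean, sd)
    if (z >= 0 && z <= 1) return(z)
  }
  stop("truncated-normal rejection failed: mean ", mean, ", sd ", sd)
}

#' Simulate a multi-genotype phantom experiment in memory
#'
#' Draws each image's stripe fraction from a normal distribution truncated
#' to \[0, 1\] (per-group mean and s.d.) and generates one phantom per
#' image. Each phantom's RNG stream is derived from `(seed, image index)`.
#'
#' @param groups Data frame with columns `genotype`, `mean_fraction`,
#'   `sd_fraction` (one row per condition).
#' @param n_per_group Images per condition; at least 2 (a t test needs
#'   at least 2 per group).
#' @param seed Experiment master seed.
#' @param base_spec A [phantom_spec()] providing all non-stripe parameters.
#' @return A list with `images` (list of `wq_disc_image`) and `truth`
#'   (data frame: image_id, genotype, stripe_fraction, true_index, seed).
#' @export
simulate_experiment <- function(groups, n_per_group, seed,
                                base_spec = phantom_spec()) {
  stopifnot(is.data.frame(groups),
            all(c("genotype", "mean_fraction", "sd_fraction") %in% names(groups)))
  if (n_per_group < 2L)
    stop("n_per_group must be at least 2 (a t test needs >= 2 per group)")
  images <- list(); rows <- list(); idx <- 0L
  for (g in seq_len(nrow(groups))) {
    for (j in seq_len(n_per_group)) {
      idx <- idx + 1L
      s <- derive_seed(seed, idx)
      frac <- local_seed(s + 1L,
                         rtrunc01(groups$mean_fraction[g], groups$sd_fraction[g]))
      sp <- base_spec
      sp$stripe_fraction <- frac
      sp$seed <- s
      id <- sprintf("img%03d", idx)
      ph <- generate_phantom(sp, image_id = id, genotype = groups$genotype[g])
      images[[idx]] <- ph$image
      rows[[idx]] <- data.frame(image_id = id, genotype = groups$genotype[g],
                                stripe_fraction = frac,
                                true_index = ph$truth$true_index,
                                seed = s, stringsAsFactors = FALSE)
    }
  }
  list(images = images, truth = do.call(rbind, rows))
}

#' Write a phantom experiment to disk as a loadable batch
#'
#' Runs [simulate_experiment()] and writes one 16-bit junction and reporter
#' TIFF per image plus `manifest.csv` (loadable with [load_manifest()]) and
#' `truth.csv` into `dir`.
#'
#' @inheritParams simulate_experiment
#' @param dir Output directory (created if needed).
#' @return A list with `manifest_path`, `truth_path`, and the `manifest`
#'   and `truth` data frames.
#' @export
generate_experiment <- function(groups, n_per_group, dir, seed,
                                base_spec = phantom_spec()) {
  sim <- simulate_experiment(groups, n_per_group, seed, base_spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mrows <- lapply(sim$images, function(img) {
    jp <- file.path(dir, paste0(img$image_id, "_junction.tif"))
    rp <- file.path(dir, paste0(img$image_id, "_reporter.tif"))
    write_channel_tiff(img$junction_channel, jp)
    write_channel_tiff(img$reporter_channel, rp)
    data.frame(image_id = img$image_id, genotype = img$genotype,
               junction_path = basename(jp), reporter_path = basename(rp),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, mrows)
  manifest_path <- file.path(dir, "manifest.csv")
  truth_path <- file.path(dir, "truth.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  write.csv(sim$truth, truth_path, row.names = FALSE)
  list(manifest_path = manifest_path, truth_path = truth_path,
       manifest = manifest, truth = sim$truth)
}
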