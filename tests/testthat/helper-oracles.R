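# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the flood fill is an iterative-dilation fixpoint,
# the t test is the textbook closed form, Otsu is an explicit loop over
# cutpoints.

# Pixels 4-connected-reachable from the image border through non-blocked
# pixels, by repeated one-step dilation until fixpoint.
flood_outside_oracle <- function(blocked) {
  nr <- nrow(blocked); nc <- ncol(blocked)
  reached <- matrix(FALSE, nr, nc)
  reached[1, ] <- TRUE; reached[nr, ] <- TRUE
  reached[, 1] <- TRUE; reached[, nc] <- TRUE
  reached <- reached & !blocked
  repeat {
    grown <- reached
    grown[-1, ] <- grown[-1, ] | reached[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reached[-1, ]
    grown[, -1] <- grown[, -1] | reached[, -nc]
    grown[, -nc] <- grown[, -nc] | reached[, -1]
    grown <- grown & !blocked
    if (identical(grown, reached)) return(reached)
    reached <- grown
  }
}

# Textbook pooled-variance two-sided t test.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Welch t with Satterthwaite degrees of freedom.
welch_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive between-class-variance maximization over all 256-bin cutpoints.
otsu_oracle <- function(x, bins = 256L) {
  bin <- pmin(floor(x * bins), bins - 1L)
  counts <- tabulate(bin + 1L, nbins = bins)
  mids <- (seq_len(bins) - 0.5) / bins
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(bins - 1L)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):bins] * mids[(k + 1):bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  best_k / bins
}

random_edge_mask <- function(nr, nc, p = 0.3) {
  matrix(runif(nr * nc) < p, nr, nc)
}

rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Phantom conditions used by the recovery checks: radius 60-100 px,
# irregularity up to 0.15, read noise up to 0.05, stripe fractions cycling
# through 0.1 / 0.2 / 0.3.
recovery_phantom_specs <- function(n, seed_base = 400L) {
  lapply(seq_len(n), function(i) {
    local_pars <- withr::with_seed(seed_base + i, list(
      radius = runif(1, 60, 100),
      irregularity = runif(1, 0, 0.15),
      noise_sd = runif(1, 0, 0.05)))
    phantom_spec(disc_radius = local_pars$radius,
                 boundary_irregularity = local_pars$irregularity,
                 noise_sd = local_pars$noise_sd,
                 stripe_fraction = c(0.1, 0.2, 0.3)[(i - 1L) %% 3L + 1L],
                 seed = seed_base + i)
  })
}

# Small fast phantom geometry for the pipeline-level simulation checks.
sim_base_spec <- function() {
  phantom_spec(image_size = c(128L, 128L), disc_radius = 45)
}

# Phantom -> segmentation -> index for a whole simulated experiment.
pipeline_group_indices <- function(groups, n_per_group, seed,
                                   params = canny_params(),
                                   spec = threshold_spec(0.4)) {
  sim <- simulate_experiment(groups, n_per_group, seed, base_spec = sim_base_spec())
  idx <- vapply(sim$images, recover_index, numeric(1), params = params, spec = spec)
  split(idx, sim$truth$genotype)
}
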