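#' @title Synthetic map-pair generator
#' @description Fully synthetic stand-ins for (experimental map, tightly
#' masked sharp target) training pairs. A pseudo-atomic model (self-avoiding
#' random walk with protein-backbone-like 3.8 A steps) is rendered as a sum
#' of Gaussians ("sharp" reference); contrast loss is simulated by Fourier
#' amplitude attenuation `exp(-B s^2 / 4)` (crystallographic B-factor
#' convention on amplitudes, s in 1/A), optionally with a smooth spatially
#' varying blend between two B values to emulate heterogeneous local
#' quality; two half maps receive independent noise and the full map is
#' their average; the target is the sharp map under a tight mask obtained
#' by thresholding and dilating the sharp map itself.
#' @name synthetic_data
NULL

#' Random pseudo-atomic model
#'
#' Atoms are placed by a self-avoiding random walk with fixed 3.8 A steps
#' (backbone-like spacing), restarted from a random previously placed atom
#' when blocked, and constrained to the box interior margin.
#'
#' @param n_atoms number of atoms (>= 1).
#' @param box_size box edge(s) in Angstrom (scalar or length 3).
#' @param seed integer seed; the model is deterministic per seed.
#' @param margin distance (A) kept between atoms and the box faces.
#' @return A `pseudo_model`: data.frame `atoms` (x, y, z, amplitude,
#'   bfactor) plus `box_size`.
#' @export
random_pseudo_model <- function(n_atoms, box_size, seed = 1L, margin = 12) {
  stopifnot(n_atoms >= 1)
  box <- rep_len(as.numeric(box_size), 3L)
  lo <- rep(margin, 3)
  hi <- box - margin
  if (any(hi - lo < 7.6) && n_atoms > 1)
    stop("box too small for a 3.8 A-step walk with this margin")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  step <- 3.8
  min_sep <- 3.0
  pos <- matrix(NA_real_, n_atoms, 3)
  pos[1, ] <- box / 2 + stats::runif(3, -2, 2)
  for (i in seq_len(n_atoms)[-1]) {
    anchor <- pos[i - 1L, ]
    best <- NULL
    best_d2 <- -Inf
    placed <- FALSE
    for (try in 1:200) {
      dir <- stats::rnorm(3)
      cand <- anchor + step * dir / sqrt(sum(dir^2))
      if (any(cand < lo) || any(cand > hi)) next
      d2 <- min(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 3, byrow = TRUE))^2))
      if (d2 >= min_sep^2) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (d2 > best_d2) {
        best_d2 <- d2
        best <- cand
      }
    }
    if (!placed) {
      # keep the exact 3.8 A consecutive spacing; accept the least-crowded
      # in-box direction when full self-avoidance is blocked
      if (is.null(best))
        stop("box too small: could not place ", n_atoms, " atoms")
      pos[i, ] <- best
    }
  }
  atoms <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      amplitude = stats::runif(n_atoms, 0.8, 1.2),
                      bfactor = stats::runif(n_atoms, 20, 60))
  structure(list(atoms = atoms, box_size = box), class = "pseudo_model")
}

#' Render a pseudo-model as a sharp density map
#'
#' Each atom contributes an isotropic Gaussian with peak height equal to
#' its amplitude and width `sigma^2 = B / (8 pi^2) + sigma0^2`, evaluated
#' on a local neighborhood of +/- 4 sigma.
#'
#' @param model a `pseudo_model`.
#' @param voxel_size sampling in A/voxel.
#' @param grid_shape grid dimensions; default covers the model's box.
#' @param sigma0 base atom width in A (default 0.8).
#' @return A nonnegative [density_map].
#' @export
simulate_sharp_map <- function(model, voxel_size = 1,
                               grid_shape = NULL, sigma0 = 0.8) {
  stopifnot(inherits(model, "pseudo_model"))
  if (is.null(grid_shape))
    grid_shape <- as.integer(round(model$box_size / voxel_size))
  d <- as.integer(rep_len(grid_shape, 3L))
  arr <- array(0, dim = d)
  a <- model$atoms
  # voxel i covers physical coordinate (i - 1) * voxel_size
  for (k in seq_len(nrow(a))) {
    p <- c(a$x[k], a$y[k], a$z[k]) / voxel_size + 1
    if (any(p < 1) || any(p > d))
      stop("atom ", k, " lies outside the grid")
    sigma <- sqrt(a$bfactor[k] / (8 * pi^2) + sigma0^2) / voxel_size
    r <- ceiling(4 * sigma)
    ix <- max(1, floor(p[1] - r)):min(d[1], ceiling(p[1] + r))
    iy <- max(1, floor(p[2] - r)):min(d[2], ceiling(p[2] + r))
    iz <- max(1, floor(p[3] - r)):min(d[3], ceiling(p[3] + r))
    gx <- exp(-(ix - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(iy - p[2])^2 / (2 * sigma^2))
    gz <- exp(-(iz - p[3])^2 / (2 * sigma^2))
    arr[ix, iy, iz] <- arr[ix, iy, iz] +
      a$amplitude[k] * outer(outer(gx, gy), gz)
  }
  density_map(arr, voxel_size = voxel_size)
}

#' Contrast-degradation specification
#'
#' @param global_B global B-factor in A^2 (amplitude attenuation
#'   `exp(-B s^2 / 4)`).
#' @param noise_sigma standard deviation of the per-half-map noise.
#' @param noise_type `"white"` or `"bandlimited"` (Gaussian-filtered white
#'   noise re-scaled to `noise_sigma`).
#' @param local_B_range optional `c(Bmin, Bmax)`: the map is a smooth
#'   position-wise blend of the two globally attenuated versions,
#'   emulating heterogeneous local quality.
#' @param seed seed for the noise (and blend field) draws.
#' @return A `degrade_spec` object.
#' @export
degrade_spec <- function(global_B, noise_sigma, noise_type = "white",
                         local_B_range = NULL, seed = 1L) {
  stopifnot(global_B >= 0, noise_sigma >= 0)
  if (!noise_type %in% c("white", "bandlimited"))
    stop("noise_type must be 'white' or 'bandlimited'")
  if (!is.null(local_B_range)) {
    stopifnot(length(local_B_range) == 2L, all(local_B_range >= 0))
    local_B_range <- sort(local_B_range)
  }
  structure(list(global_B = global_B, noise_sigma = noise_sigma,
                 noise_type = noise_type, local_B_range = local_B_range,
                 seed = as.integer(seed)),
            class = "degrade_spec")
}

# |s|^2 grid in (1/A)^2 for a map of shape d at given voxel size
freq_sq_grid <- function(d, voxel_size) {
  fr <- lapply(d, function(n) {
    k <- seq_len(n) - 1
    k <- ifelse(k <= n / 2, k, k - n)
    (k / (n * voxel_size))^2
  })
  outer(outer(fr[[1]], fr[[2]], "+"), fr[[3]], "+")
}

apply_bfactor <- function(arr, voxel_size, B) {
  if (B == 0) return(arr)
  s2 <- freq_sq_grid(dim(arr), voxel_size)
  Re(stats::fft(stats::fft(arr) * exp(-B * s2 / 4), inverse = TRUE)) /
    prod(dim(arr))
}

#' Degrade a sharp map into experimental-like half maps
#'
#' Applies B-factor amplitude attenuation (global, or a smooth blend of
#' `local_B_range` when set), then adds independent noise to each half
#' map; the full map is exactly the half-map average.
#'
#' @param sharp a [density_map] (the sharp reference).
#' @param spec a [degrade_spec].
#' @return List with [density_map]s `full`, `half1`, `half2` and `signal`
#'   (the noise-free degraded map).
#' @export
degrade_map <- function(sharp, spec) {
  stopifnot(is_density_map(sharp), inherits(spec, "degrade_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  d <- dim(sharp$data)
  v <- sharp$voxel_size
  if (is.null(spec$local_B_range)) {
    signal <- apply_bfactor(sharp$data, v, spec$global_B)
  } else {
    lo <- apply_bfactor(sharp$data, v, spec$local_B_range[1])
    hi <- apply_bfactor(sharp$data, v, spec$local_B_range[2])
    w <- gaussian_blur_cube(array(stats::rnorm(prod(d)), dim = d),
                            sigma = min(d) / 6)
    w <- (w - min(w)) / (max(w) - min(w))
    signal <- (1 - w) * lo + w * hi
  }
  draw_noise <- function() {
    n <- array(stats::rnorm(prod(d)), dim = d)
    if (spec$noise_type == "bandlimited") {
      n <- gaussian_blur_cube(n, sigma = 1.5)
      n <- n / stats::sd(n)
    }
    n * spec$noise_sigma
  }
  h1 <- signal + draw_noise()
  h2 <- signal + draw_noise()
  mk <- function(a) density_map(a, voxel_size = v, origin = sharp$origin)
  list(full = mk((h1 + h2) / 2), half1 = mk(h1), half2 = mk(h2),
       signal = mk(signal))
}

#' Tight mask from a sharp map
#'
#' Thresholds the sharp map at a fraction of its maximum and dilates the
#' support by a Euclidean ball.
#'
#' @param sharp a [density_map].
#' @param threshold_fraction threshold as a fraction of the map maximum,
#'   in (0, 1).
#' @param dilation_radius ball radius in voxels (0 = no dilation).
#' @return A binary [mask_volume].
#' @export
make_mask <- function(sharp, threshold_fraction = 0.05, dilation_radius = 2) {
  stopifnot(is_density_map(sharp))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  if (max(sharp$data) <= 0) stop("mask has empty support (non-positive map)")
  m <- sharp$data >= threshold_fraction * max(sharp$data)
  if (!any(m)) stop("mask has empty support")
  if (dilation_radius > 0) {
    d2 <- cpp_edt_sq(!m)  # squared distance to the nearest in-mask voxel
    m <- d2 <= dilation_radius^2
  }
  mask_volume(m, voxel_size = sharp$voxel_size)
}

#' Masked sharp target
#'
#' @param sharp a [density_map].
#' @param mask a [mask_volume] of the same shape.
#' @return The voxel-wise product as a [density_map]; out-of-mask voxels
#'   are exactly zero.
#' @export
make_target <- function(sharp, mask) {
  stopifnot(is_density_map(sharp), inherits(mask, "mask_volume"))
  if (!identical(dim(sharp$data), dim(mask$data))) stop("shape mismatch")
  density_map(sharp$data * mask$data, voxel_size = sharp$voxel_size,
              origin = sharp$origin)
}

#' Generate a collection of synthetic map pairs
#'
#' Draws per-map parameters from the stated ranges with independent
#' per-map seeds derived from the master seed. Defaults define the study
#' conditions: 96^3 boxes at 1 A/voxel, 60-200 atoms, global B in
#' [50, 200] A^2, white noise with peak signal-to-noise drawn in [2, 6],
#' mask threshold 5\% of maximum with 2-voxel dilation.
#'
#' @param n_maps number of map pairs.
#' @param seed master seed.
#' @param box_size box edge in A (grid at 1 A/voxel).
#' @param n_atoms_range,global_B_range,snr_range sampling ranges.
#' @param threshold_fraction,dilation_radius mask parameters.
#' @param noise_type noise model for [degrade_spec()].
#' @param keep which per-map volumes to retain (memory control).
#' @param out_dir optional directory: writes `<id>_{full,half1,half2,
#'   target,mask}.mrc` plus `manifest.csv`.
#' @return List with `records` (per-map lists of kept volumes and the
#'   drawn `spec`) and `manifest` (data.frame of all parameters).
#' @export
generate_dataset <- function(n_maps, seed = 1L, box_size = 96,
                             n_atoms_range = c(60L, 200L),
                             global_B_range = c(50, 200),
                             snr_range = c(2, 6),
                             threshold_fraction = 0.05,
                             dilation_radius = 2,
                             noise_type = "white",
                             keep = c("full", "half1", "half2", "target",
                                      "mask", "sharp"),
                             out_dir = NULL) {
  stopifnot(n_maps >= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  map_seeds <- sample.int(2147483646L, n_maps)
  n_atoms <- sample(seq(n_atoms_range[1], n_atoms_range[2]), n_maps,
                    replace = TRUE)
  bfac <- stats::runif(n_maps, global_B_range[1], global_B_range[2])
  snr <- stats::runif(n_maps, snr_range[1], snr_range[2])
  records <- vector("list", n_maps)
  rows <- vector("list", n_maps)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n_maps)) {
    id <- sprintf("syn%03d", i)
    model <- random_pseudo_model(n_atoms[i], box_size, seed = map_seeds[i])
    sharp <- simulate_sharp_map(model, voxel_size = 1)
    # set the noise level from the degraded (not sharp) peak so SNR is the
    # peak signal-to-noise actually present in the input map
    peak <- max(apply_bfactor(sharp$data, 1, bfac[i]))
    sigma <- peak / snr[i]
    spec <- degrade_spec(global_B = bfac[i], noise_sigma = sigma,
                         noise_type = noise_type, seed = map_seeds[i])
    deg <- degrade_map(sharp, spec)
    mask <- make_mask(sharp, threshold_fraction, dilation_radius)
    target <- make_target(sharp, mask)
    rec <- list(id = id, seed = map_seeds[i], spec = spec,
                n_atoms = n_atoms[i], snr = snr[i])
    vols <- list(full = deg$full, half1 = deg$half1, half2 = deg$half2,
                 target = target, mask = mask, sharp = sharp)
    rec <- c(rec, vols[intersect(keep, names(vols))])
    records[[i]] <- rec
    rows[[i]] <- data.frame(id = id, seed = map_seeds[i],
                            n_atoms = n_atoms[i], global_B = bfac[i],
                            snr = snr[i], noise_sigma = sigma,
                            box_size = box_size,
                            threshold_fraction = threshold_fraction,
                            dilation_radius = dilation_radius,
                            noise_type = noise_type)
    if (!is.null(out_dir)) {
      write_map(deg$full, file.path(out_dir, paste0(id, "_full.mrc")))
      write_map(deg$half1, file.path(out_dir, paste0(id, "_half1.mrc")))
      write_map(deg$half2, file.path(out_dir, paste0(id, "_half2.mrc")))
      write_map(target, file.path(out_dir, paste0(id, "_target.mrc")))
      write_map(density_map(mask$data, voxel_size = 1),
                file.path(out_dir, paste0(id, "_mask.mrc")))
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  list(records = records, manifest = manifest)
}
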