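#' @title Noise-statistics normalization
#' @description Before chunking, every map is linearly rescaled so its noise
#' region adopts a fixed mean of 0 and standard deviation of 0.1 (the
#' classical cryo-EM intensity convention). The noise region defaults to the
#' corners/edges of the box: voxels outside the centered sphere of radius
#' `0.9 * min(dim) / 2` that also lie in the outer 15\% shell of the box.
#' Deposited maps are boxed with a solvent margin around a centered
#' particle, so this set is overwhelmingly noise. An explicit noise mask
#' always overrides the heuristic.
#' @name normalization
NULL

default_noise_region <- function(d) {
  ctr <- (d + 1) / 2
  cx <- abs(seq_len(d[1]) - ctr[1])
  cy <- abs(seq_len(d[2]) - ctr[2])
  cz <- abs(seq_len(d[3]) - ctr[3])
  r2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  outside_sphere <- r2 > (0.45 * min(d))^2
  shell <- outer(outer(cx > 0.35 * d[1], cy > 0.35 * d[2], "|"),
                 cz > 0.35 * d[3], "|")
  outside_sphere & shell
}

#' Construct normalization statistics directly
#'
#' Mostly useful for tests and for replaying recorded statistics; ordinary
#' pipelines obtain stats from [estimate_noise_stats()].
#'
#' @param noise_mean,noise_std estimated noise moments (`noise_std > 0`).
#' @param target_mean,target_std the fixed scale the noise is mapped to.
#' @return A `normalization_stats` object.
#' @export
normalization_stats <- function(noise_mean, noise_std, target_mean = 0,
                                target_std = 0.1) {
  if (noise_std <= 0 || target_std <= 0)
    stop("standard deviations must be positive")
  structure(list(noise_mean = noise_mean, noise_std = noise_std,
                 target_mean = target_mean, target_std = target_std,
                 noise_region = "explicit", n_voxels = NA_integer_),
            class = "normalization_stats")
}

#' Estimate the noise statistics of a map
#'
#' Computes mean and standard deviation over the noise region, after
#' discarding values more than 4 MADs from the noise median so stray signal
#' in the shell does not bias the scale.
#'
#' @param map a [density_map].
#' @param noise_mask optional [mask_volume] (or logical array) selecting the
#'   noise voxels explicitly; must have the map's shape.
#' @return A `normalization_stats` object with fields `noise_mean`,
#'   `noise_std`, `target_mean` (0), `target_std` (0.1) and `noise_region`.
#' @export
estimate_noise_stats <- function(map, noise_mask = NULL) {
  stopifnot(is_density_map(map))
  d <- dim(map$data)
  if (is.null(noise_mask)) {
    sel <- default_noise_region(d)
    region <- "outer-shell"
  } else {
    m <- if (inherits(noise_mask, "mask_volume")) noise_mask$data else noise_mask
    if (!identical(dim(m), d)) stop("noise mask shape does not match map")
    sel <- m > 0
    region <- "explicit-mask"
  }
  v <- map$data[sel]
  if (length(v) < 2L) stop("noise region is empty")
  med <- stats::median(v)
  madv <- stats::mad(v)
  if (madv > 0) v <- v[abs(v - med) <= 4 * madv]
  noise_mean <- mean(v)
  noise_std <- stats::sd(v)
  rng <- diff(range(map$data))
  if (!is.finite(noise_std) || noise_std <= 1e-12 * max(rng, 1e-300))
    stop("flat noise region: cannot estimate noise statistics")
  structure(list(noise_mean = noise_mean, noise_std = noise_std,
                 target_mean = 0, target_std = 0.1,
                 noise_region = region, n_voxels = length(v)),
            class = "normalization_stats")
}

#' @export
print.normalization_stats <- function(x, ...) {
  cat(sprintf(
    "<normalization_stats> noise mean %.4g, sd %.4g (%s, %d voxels) -> (%g, %g)\n",
    x$noise_mean, x$noise_std, x$noise_region, x$n_voxels,
    x$target_mean, x$target_std))
  invisible(x)
}

#' Normalize a map to the fixed noise scale
#'
#' Affine, rank-preserving transform
#' `(map - noise_mean) * target_std / noise_std + target_mean`.
#'
#' @param map a [density_map].
#' @param stats a `normalization_stats` object from [estimate_noise_stats()].
#' @return The normalized [density_map].
#' @export
normalize_map <- function(map, stats) {
  stopifnot(is_density_map(map), inherits(stats, "normalization_stats"))
  arr <- (map$data - stats$noise_mean) * (stats$target_std / stats$noise_std) +
    stats$target_mean
  density_map(arr, voxel_size = map$voxel_size, origin = map$origin)
}

#' Invert [normalize_map()]
#'
#' @inheritParams normalize_map
#' @return The map on its original intensity scale.
#' @export
denormalize_map <- function(map, stats) {
  stopifnot(is_density_map(map), inherits(stats, "normalization_stats"))
  arr <- (map$data - stats$target_mean) * (stats$noise_std / stats$target_std) +
    stats$noise_mean
  density_map(arr, voxel_size = map$voxel_size, origin = map$origin)
}

#' Normalize a tightly masked target map
#'
#' Target maps are masked, so their noise region is identically zero and
#' noise-statistics normalization is undefined. Instead the map is scaled so
#' the 95th percentile of in-mask values equals 1; out-of-mask voxels (which
#' are already zero) are unaffected by the global scale.
#'
#' @param map a [density_map] (masked target).
#' @param mask the [mask_volume] defining the molecular support.
#' @return The rescaled [density_map], with the scale factor attached as
#'   attribute `"target_scale"`.
#' @export
normalize_target <- function(map, mask) {
  stopifnot(is_density_map(map), inherits(mask, "mask_volume"))
  if (!identical(dim(map$data), dim(mask$data)))
    stop("mask shape does not match map")
  v <- map$data[mask$data > 0]
  if (length(v) == 0L) stop("mask has empty support")
  q <- as.numeric(stats::quantile(v, 0.95, names = FALSE))
  if (q <= 0) stop("non-positive 95th percentile inside mask")
  out <- density_map(map$data / q, voxel_size = map$voxel_size,
                     origin = map$origin)
  attr(out, "target_scale") <- 1 / q
  out
}
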