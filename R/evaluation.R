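#' @title Map similarity and resolution measures
#' @description The measurement apparatus of the pipeline: Fourier shell
#' correlation (FSC) curves, threshold resolutions (0.5 against an external
#' reference; 0.143 between half maps), FSC under a softened tight mask,
#' and real-space Pearson correlation. Shells are one Fourier voxel wide,
#' binned by rounded integer Fourier radius (per-axis normalized frequency
#' norm for anisotropic boxes); the threshold search excludes the DC shell
#' and linearly interpolates the first crossing.
#' @name evaluation
NULL

shell_index <- function(d, nref) {
  fr <- lapply(seq_along(d), function(ax) {
    n <- d[ax]
    k <- seq_len(n) - 1
    k <- ifelse(k <= n / 2, k, k - n)
    k / n
  })
  rnorm2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  as.integer(round(sqrt(rnorm2) * nref))
}

#' Fourier shell correlation between two maps
#'
#' @param map1,map2 [density_map]s (or 3-d arrays) on identical grids.
#' @param voxel_size required if bare arrays are given.
#' @return An `fsc_curve`: `shell_freq` (1/A, shell centers, strictly
#'   increasing up to Nyquist), `fsc`, `n_voxels` (Fourier voxels per
#'   shell) and `voxel_size`. The DC shell is included but flagged by
#'   `shell_freq == 0`.
#' @export
fsc <- function(map1, map2, voxel_size = NULL) {
  a <- as_map_array(map1)
  b <- as_map_array(map2)
  if (!identical(dim(a), dim(b))) stop("maps have different shapes")
  if (is_density_map(map1)) {
    if (is_density_map(map2)) check_same_grid(map1, map2)
    voxel_size <- map1$voxel_size
  }
  if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
  if (all(a == 0) || all(b == 0)) stop("all-zero map: FSC undefined")
  d <- dim(a)
  nref <- min(d)
  idx <- shell_index(d, nref)
  keep <- idx <= nref %/% 2
  idx <- idx[keep]
  F1 <- stats::fft(a)[keep]
  F2 <- stats::fft(b)[keep]
  num <- rowsum(Re(F1 * Conj(F2)), idx)
  d1 <- rowsum(Mod(F1)^2, idx)
  d2 <- rowsum(Mod(F2)^2, idx)
  nv <- as.vector(rowsum(rep(1, length(idx)), idx))
  shells <- as.integer(rownames(num))
  denom <- sqrt(as.vector(d1) * as.vector(d2))
  val <- ifelse(denom > 0, as.vector(num) / denom, 0)
  structure(list(shell_freq = shells / (nref * voxel_size),
                 fsc = val, n_voxels = nv, voxel_size = voxel_size),
            class = "fsc_curve")
}

#' @export
as.data.frame.fsc_curve <- function(x, ...) {
  data.frame(shell_freq = x$shell_freq, fsc = x$fsc, n_voxels = x$n_voxels)
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to %.3g 1/A (Nyquist %.3g)\n",
              length(x$fsc), max(x$shell_freq), 1 / (2 * x$voxel_size)))
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Finds the first shell pair (excluding DC) where the curve falls from at
#' or above the threshold to below it, linearly interpolates the crossing
#' frequency, and returns its reciprocal in Angstrom. If the curve never
#' drops below the threshold the Nyquist resolution `2 * voxel_size` is
#' returned with attribute `flag = "nyquist"`; a curve that never reaches
#' the threshold returns `Inf` with `flag = "below"`. Curves that start
#' below the threshold and re-cross (typically a noisy near-DC shell) are
#' flagged `"crossed-recrossing"`.
#'
#' @param curve an `fsc_curve`.
#' @param threshold correlation threshold in (0, 1); 0.5 for comparison
#'   against an external reference, 0.143 between half maps.
#' @return Resolution in Angstrom (possibly flagged).
#' @export
resolution_at_threshold <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  use <- which(curve$shell_freq > 0)
  if (length(use) < 2L) stop("malformed curve")
  f <- curve$shell_freq[use]
  v <- curve$fsc[use]
  recross <- v[1] < threshold   # pathological start below threshold: flagged
  for (k in seq_len(length(v) - 1L)) {
    if (v[k] >= threshold && v[k + 1] < threshold) {
      fc <- f[k] + (v[k] - threshold) / (v[k] - v[k + 1]) * (f[k + 1] - f[k])
      return(structure(1 / fc,
                       flag = if (recross) "crossed-recrossing" else "crossed"))
    }
  }
  if (all(v < threshold)) return(structure(Inf, flag = "below"))
  structure(2 * curve$voxel_size, flag = "nyquist")
}

#' Soften a binary mask with a cosine edge
#'
#' In-mask voxels at Euclidean distance `d` from the mask boundary get
#' weight `0.5 - 0.5 * cos(pi * min(d, width) / width)`; outside voxels
#' stay 0. `width = 0` returns the hard mask.
#'
#' @param mask a [mask_volume].
#' @param width edge width in voxels.
#' @return A soft [mask_volume].
#' @export
soften_mask <- function(mask, width = 3) {
  stopifnot(inherits(mask, "mask_volume"))
  m <- mask$data > 0
  if (width <= 0)
    return(mask_volume(m, voxel_size = mask$voxel_size, binary = TRUE))
  dist <- sqrt(cpp_edt_sq(m))
  w <- ifelse(m, 0.5 - 0.5 * cos(pi * pmin(dist, width) / width), 0)
  mask_volume(w, voxel_size = mask$voxel_size, binary = FALSE)
}

#' FSC after masking both maps
#'
#' @inheritParams fsc
#' @param mask a [mask_volume].
#' @param soften_width cosine-edge width in voxels (0 = hard mask).
#' @return An `fsc_curve`.
#' @export
masked_fsc <- function(map1, map2, mask, soften_width = 3,
                       voxel_size = NULL) {
  stopifnot(inherits(mask, "mask_volume"))
  a <- as_map_array(map1)
  b <- as_map_array(map2)
  if (!identical(dim(a), dim(mask$data))) stop("mask shape mismatch")
  if (is.null(voxel_size))
    voxel_size <- if (is_density_map(map1)) map1$voxel_size else mask$voxel_size
  soft <- soften_mask(mask, soften_width)$data
  fsc(a * soft, b * soft, voxel_size = voxel_size)
}

#' Real-space Pearson correlation between maps
#'
#' @param map1,map2 [density_map]s or arrays of identical shape.
#' @param mask optional [mask_volume]: correlate in-mask voxels only.
#' @return Correlation coefficient in [-1, 1].
#' @export
real_space_cc <- function(map1, map2, mask = NULL) {
  a <- as_map_array(map1)
  b <- as_map_array(map2)
  if (!identical(dim(a), dim(b))) stop("maps have different shapes")
  if (!is.null(mask)) {
    sel <- (if (inherits(mask, "mask_volume")) mask$data else mask) > 0
    a <- a[sel]
    b <- b[sel]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(as.vector(a), as.vector(b))
}

#' Radially averaged power spectrum
#'
#' @param map a [density_map] or array.
#' @param voxel_size required for bare arrays.
#' @return data.frame with `shell_freq` (1/A) and mean `power` per shell.
#' @export
radial_power <- function(map, voxel_size = NULL) {
  a <- as_map_array(map)
  if (is_density_map(map)) voxel_size <- map$voxel_size
  if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
  d <- dim(a)
  nref <- min(d)
  idx <- shell_index(d, nref)
  keep <- idx <= nref %/% 2
  p <- Mod(stats::fft(a)[keep])^2
  idx <- idx[keep]
  pw <- rowsum(p, idx) / as.vector(rowsum(rep(1, length(idx)), idx))
  data.frame(shell_freq = as.integer(rownames(pw)) / (nref * voxel_size),
             power = as.vector(pw))
}

#' Guinier-style B-factor estimate from a map pair
#'
#' Regresses `log(P_degraded / P_reference)` on squared spatial frequency
#' over the informative shells; under `exp(-B s^2 / 4)` amplitude
#' attenuation the slope is `-B / 2`.
#'
#' @param reference the sharp reference [density_map].
#' @param degraded the attenuated [density_map].
#' @param min_power_frac shells with reference power below this fraction
#'   of the maximum are excluded from the fit.
#' @return Estimated B-factor in A^2.
#' @export
estimate_bfactor <- function(reference, degraded, min_power_frac = 1e-6) {
  pr <- radial_power(reference)
  pd <- radial_power(degraded)
  use <- pr$shell_freq > 0 & pr$power > min_power_frac * max(pr$power) &
    pd$power > 0
  if (sum(use) < 3L) stop("too few informative shells for a Guinier fit")
  y <- log(pd$power[use] / pr$power[use])
  s2 <- pr$shell_freq[use]^2
  fit <- stats::lm(y ~ s2)
  -2 * unname(stats::coef(fit)[2])
}

#' Evaluate a processed collection against its targets
#'
#' Per map: real-space CC of input and prediction against the target, and
#' FSC\code{@}0.5 resolutions of input-vs-target and prediction-vs-target,
#' unmasked and under the softened tight mask.
#'
#' @param inputs,predictions,targets aligned lists of [density_map]s.
#' @param masks aligned list of [mask_volume]s.
#' @param out_csv optional path to write the per-map table as CSV.
#' @return data.frame with one row per map; the column medians are
#'   attached as attribute `"summary"`.
#' @export
evaluate_run <- function(inputs, predictions, targets, masks,
                         out_csv = NULL) {
  n <- length(targets)
  stopifnot(length(inputs) == n, length(predictions) == n,
            length(masks) == n)
  rows <- lapply(seq_len(n), function(i) {
    tg <- targets[[i]]
    res <- function(m) as.numeric(resolution_at_threshold(fsc(m, tg), 0.5))
    resm <- function(m) as.numeric(resolution_at_threshold(
      masked_fsc(m, tg, masks[[i]]), 0.5))
    data.frame(
      map = i,
      cc_input = real_space_cc(inputs[[i]], tg),
      cc_pred = real_space_cc(predictions[[i]], tg),
      res_input = res(inputs[[i]]),
      res_pred = res(predictions[[i]]),
      res_input_masked = resm(inputs[[i]]),
      res_pred_masked = resm(predictions[[i]]))
  })
  out <- do.call(rbind, rows)
  summ <- vapply(out[-1], stats::median, numeric(1))
  attr(out, "summary") <- summ
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
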