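#' @title Resampling between the native grid and the 1 A/voxel working grid
#' @description The pipeline operates on a fixed working grid of 1 A/voxel;
#' maps are resampled on the way in and the processed volume is resized back
#' to the original grid on the way out. The default resampling is a
#' Fourier-space resize (zero-pad / crop of the DFT): it is exactly
#' band-limited, linear, and deterministic. A real-space cubic-spline
#' alternative is available via `method = "spline"`.
#' @name resampling
NULL

# frequency-domain transfer matrix for resizing one axis from N to M samples.
# Even-size Nyquist bins are split (pad) or summed (crop) so that real input
# stays real and the crop is the exact adjoint of the pad.
axis_transfer <- function(N, M) {
  Tm <- matrix(0, M, N)
  if (M == N) {
    diag(Tm) <- 1
    return(Tm)
  }
  if (M < N) {
    for (m in 0:(M - 1)) {
      fm <- if (m < M / 2) m else m - M
      if (abs(fm) < M / 2) {
        Tm[m + 1, (fm %% N) + 1] <- 1
      } else {  # fm == -M/2, even M: fold both input half-Nyquist bins
        Tm[m + 1, ((M / 2) %% N) + 1] <- Tm[m + 1, ((M / 2) %% N) + 1] + 1
        Tm[m + 1, ((-M / 2) %% N) + 1] <- Tm[m + 1, ((-M / 2) %% N) + 1] + 1
      }
    }
  } else {
    for (n in 0:(N - 1)) {
      fn <- if (n < N / 2) n else n - N
      if (abs(fn) < N / 2) {
        Tm[(fn %% M) + 1, n + 1] <- 1
      } else {  # fn == -N/2, even N: split across the two output bins
        Tm[((N / 2) %% M) + 1, n + 1] <- 0.5
        Tm[((-N / 2) %% M) + 1, n + 1] <- 0.5
      }
    }
  }
  Tm
}

apply_axis <- function(arr, ax, Tm) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[ax])
  out <- Tm %*% m
  d2 <- d
  d2[ax] <- nrow(Tm)
  a2 <- array(out, dim = d2[perm])
  aperm(a2, order(perm))
}

fourier_resize <- function(arr, out_dim) {
  d <- dim(arr)
  if (all(d == out_dim)) return(arr)
  F <- stats::fft(arr)
  for (ax in 1:3) {
    if (d[ax] != out_dim[ax]) F <- apply_axis(F, ax, axis_transfer(d[ax], out_dim[ax]))
  }
  Re(stats::fft(F, inverse = TRUE)) / prod(d)
}

spline_resize <- function(arr, out_dim) {
  for (ax in 1:3) {
    d <- dim(arr)
    if (d[ax] == out_dim[ax]) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- matrix(aperm(arr, perm), nrow = d[ax])
    xin <- seq(0, 1, length.out = d[ax])
    xout <- seq(0, 1, length.out = out_dim[ax])
    a2 <- apply(a, 2, function(col) stats::spline(xin, col, xout = xout)$y)
    d2 <- d
    d2[ax] <- out_dim[ax]
    arr <- aperm(array(a2, dim = d2[perm]), order(perm))
  }
  arr
}

#' Resample a map to the working voxel size
#'
#' @param map a [density_map].
#' @param target_voxel working sampling in A/voxel (default 1.0).
#' @param method `"fourier"` (default, band-limited DFT pad/crop) or
#'   `"spline"` (real-space cubic spline).
#' @return A list with elements `map` (the resampled [density_map]) and
#'   `record` (a `resample_record` storing everything needed to invert with
#'   [resize_to_original()]).
#' @export
resample_to_working_grid <- function(map, target_voxel = 1.0,
                                     method = c("fourier", "spline")) {
  stopifnot(is_density_map(map), target_voxel > 0)
  method <- match.arg(method)
  d <- dim(map$data)
  out_dim <- as.integer(floor(d * map$voxel_size / target_voxel + 0.5))
  if (any(out_dim < 4L))
    stop("resampled shape degenerate (dimension < 4); check voxel sizes")
  record <- structure(list(original_shape = d,
                           original_voxel_size = map$voxel_size,
                           working_voxel_size = target_voxel,
                           method = method),
                      class = "resample_record")
  if (all(out_dim == d) && abs(map$voxel_size - target_voxel) < 1e-9) {
    return(list(map = map, record = record))
  }
  arr <- if (method == "fourier") fourier_resize(map$data, out_dim)
         else spline_resize(map$data, out_dim)
  list(map = density_map(arr, voxel_size = target_voxel, origin = map$origin),
       record = record)
}

#' Resize a processed map back to its original grid
#'
#' Inverts [resample_to_working_grid()] so the output shows the original
#' shape and sampling rate.
#'
#' @param map a [density_map] on the working grid.
#' @param record the `resample_record` returned by
#'   [resample_to_working_grid()].
#' @return A [density_map] with the original shape and voxel size.
#' @export
resize_to_original <- function(map, record) {
  stopifnot(is_density_map(map), inherits(record, "resample_record"))
  d0 <- record$original_shape
  if (length(d0) != 3L || any(d0 < 1L) || record$original_voxel_size <= 0)
    stop("inconsistent resample record")
  arr <- if (identical(record$method, "spline")) spline_resize(map$data, d0)
         else fourier_resize(map$data, d0)
  density_map(arr, voxel_size = record$original_voxel_size,
              origin = map$origin)
}
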