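#' @title Cube chunking and overlap-averaged reassembly
#' @description Maps are processed by the network in cubes of 64^3 voxels.
#' Inference uses overlapping cubes with a stride of 16 voxels whose
#' predictions are re-assembled by averaging the overlapping parts; training
#' extraction typically uses stride 32. Per axis of length `N` (padded to at
#' least the cube size) the cube origins are `0, stride, 2*stride, ...`,
#' with the final origin clamped to exactly `N - cube_size` so every voxel
#' is covered with at most one irregular step.
#' @name chunking
NULL

axis_origins <- function(n, cube_size, stride) {
  last <- n - cube_size
  o <- seq(0L, last, by = stride)
  if (o[length(o)] != last) o <- c(o, last)
  as.integer(o)
}

#' Plan a chunk grid
#'
#' @param shape integer length-3 map shape (x, y, z voxels).
#' @param cube_size cube edge in voxels (default 64).
#' @param stride stride between cube origins in voxels; `1 <= stride <=
#'   cube_size`.
#' @return A `chunk_grid` object: `origins` is an n x 3 matrix of 0-based
#'   cube corners (sorted, x varying fastest), `padded_shape` is the shape
#'   after padding small axes up to `cube_size`.
#' @export
plan_chunks <- function(shape, cube_size = 64L, stride = 16L) {
  shape <- as.integer(shape)
  cube_size <- as.integer(cube_size)
  stride <- as.integer(stride)
  if (length(shape) != 3L || any(shape < 1L)) stop("invalid shape")
  if (cube_size < 1L) stop("cube_size must be >= 1")
  if (stride < 1L || stride > cube_size)
    stop("stride must satisfy 1 <= stride <= cube_size")
  padded <- pmax(shape, cube_size)
  ax <- lapply(padded, axis_origins, cube_size = cube_size, stride = stride)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  structure(list(cube_size = cube_size, stride = stride,
                 origins = as.matrix(g), padded_shape = padded,
                 out_shape = shape,
                 pad_value_policy = "constant-from-noise-mean"),
            class = "chunk_grid")
}

#' @export
print.chunk_grid <- function(x, ...) {
  cat(sprintf("<chunk_grid> %d cubes of %d^3, stride %d, padded shape %s\n",
              nrow(x$origins), x$cube_size, x$stride,
              paste(x$padded_shape, collapse = "x")))
  invisible(x)
}

#' Extract cubes from a map
#'
#' Cubes are returned in origin order. If the map is smaller than the cube
#' on some axis it is corner-placed and the remainder padded with
#' `pad_value` (by default the map's estimated noise mean, which is ~0 after
#' normalization).
#'
#' @param map a [density_map] or 3-d array.
#' @param grid a `chunk_grid` planned for this map's shape.
#' @param pad_value value used for padding; `NULL` means the map's noise
#'   mean (falling back to the global mean if the noise region is flat).
#' @return A list of `cube_size^3` arrays.
#' @export
extract_chunks <- function(map, grid, pad_value = NULL) {
  arr <- as_map_array(map)
  if (!identical(as.integer(dim(arr)), as.integer(grid$out_shape)))
    stop("grid was planned for a different shape")
  if (any(dim(arr) < grid$padded_shape)) {
    if (is.null(pad_value)) {
      pad_value <- tryCatch(
        estimate_noise_stats(density_map(arr))$noise_mean,
        error = function(e) mean(arr))
    }
    big <- array(pad_value, dim = grid$padded_shape)
    big[seq_len(dim(arr)[1]), seq_len(dim(arr)[2]), seq_len(dim(arr)[3])] <- arr
    arr <- big
  }
  cs <- grid$cube_size
  lapply(seq_len(nrow(grid$origins)), function(i) {
    o <- grid$origins[i, ]
    arr[o[1] + seq_len(cs), o[2] + seq_len(cs), o[3] + seq_len(cs)]
  })
}

#' Reassemble cubes into a map by overlap averaging
#'
#' Every voxel of the padded volume is the arithmetic mean of all cube
#' values covering it; padding introduced at extraction is cropped away.
#'
#' @param cubes list of cubes, in the grid's origin order.
#' @param grid the `chunk_grid` used for extraction.
#' @param out_shape shape of the returned array (default: the grid's
#'   original shape).
#' @return A 3-d array of shape `out_shape`.
#' @export
assemble_chunks <- function(cubes, grid, out_shape = grid$out_shape) {
  if (length(cubes) != nrow(grid$origins))
    stop("number of cubes does not match the grid")
  cs <- grid$cube_size
  acc <- array(0, dim = grid$padded_shape)
  cnt <- array(0L, dim = grid$padded_shape)
  for (i in seq_along(cubes)) {
    o <- grid$origins[i, ]
    ix <- o[1] + seq_len(cs); iy <- o[2] + seq_len(cs); iz <- o[3] + seq_len(cs)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + cubes[[i]]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  if (any(cnt == 0L)) stop("internal: grid left voxels uncovered")
  out <- acc / cnt
  out[seq_len(out_shape[1]), seq_len(out_shape[2]), seq_len(out_shape[3]),
      drop = FALSE]
}

#' Per-voxel coverage counts of a chunk grid
#'
#' @param grid a `chunk_grid`.
#' @return Integer array over the padded shape counting how many cubes
#'   cover each voxel.
#' @export
coverage_counts <- function(grid) {
  cs <- grid$cube_size
  cnt <- array(0L, dim = grid$padded_shape)
  for (i in seq_len(nrow(grid$origins))) {
    o <- grid$origins[i, ]
    ix <- o[1] + seq_len(cs); iy <- o[2] + seq_len(cs); iz <- o[3] + seq_len(cs)
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  cnt
}

# fraction of in-mask voxels per chunk; used to separate signal cubes from
# noise-only cubes when building training sets
chunk_signal_fraction <- function(mask, grid) {
  m <- if (inherits(mask, "mask_volume")) mask$data else mask
  cubes <- extract_chunks(m > 0, grid, pad_value = 0)
  vapply(cubes, mean, numeric(1))
}
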