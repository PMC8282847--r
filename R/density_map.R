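#' Cryo-EM density map container
#'
#' A `density_map` is the package's universal currency: a 3-d real-valued
#' grid together with its physical sampling. Internally the array is always
#' indexed `data[x, y, z]` (first index fastest, R's column-major layout);
#' MRC files with permuted axis conventions are canonicalized on read.
#'
#' @param data 3-d numeric array of map intensities (arbitrary units).
#' @param voxel_size isotropic sampling in Angstrom per voxel.
#' @param origin physical position (Angstrom, length 3) of grid index
#'   `[1, 1, 1]`.
#' @return An object of class `density_map` with fields `data`,
#'   `voxel_size` and `origin`.
#' @export
density_map <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array")
  if (any(dim(data) < 1L)) stop("all map dimensions must be >= 1")
  if (!all(is.finite(data))) stop("map contains non-finite values")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 vector")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  origin (A): %.3g %.3g %.3g | range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

is_density_map <- function(x) inherits(x, "density_map")

#' Binary or soft mask volume
#'
#' @param data 3-d array with values in `[0, 1]`.
#' @param voxel_size Angstrom per voxel.
#' @param binary if `TRUE`, values must be exactly 0 or 1.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, voxel_size = 1, binary = TRUE) {
  if (is.logical(data)) {
    storage.mode(data) <- "double"
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array")
  if (any(data < 0) || any(data > 1)) stop("mask values must lie in [0, 1]")
  if (binary && !all(data %in% c(0, 1)))
    stop("binary mask must contain only 0/1 values")
  if (!any(data > 0)) stop("mask has empty support")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 binary = isTRUE(binary)),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, %s, support %.1f%%\n",
              d[1], d[2], d[3], if (x$binary) "binary" else "soft",
              100 * mean(x$data > 0)))
  invisible(x)
}

# internal: accept a density_map or bare array, return the array
as_map_array <- function(x) {
  if (is_density_map(x)) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a density_map or 3-d array")
}

check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("maps have different shapes")
  if (abs(a$voxel_size - b$voxel_size) > tol * max(a$voxel_size, b$voxel_size))
    stop("maps have different voxel sizes")
  invisible(TRUE)
}
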