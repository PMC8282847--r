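#' Read an MRC/CCP4 density map
#'
#' Parses the MRC2014 header, canonicalizes any `MAPC/MAPR/MAPS` axis
#' permutation so the returned array is always indexed `[x, y, z]`, and
#' takes the voxel size from the cell dimensions divided by the grid
#' sampling. Data modes 0 (int8), 1 (int16), 2 (float32) and 12 (float16)
#' are accepted. The origin is taken from the `ORIGIN` record, falling back
#' to `NXSTART/NYSTART/NZSTART` when the record is all zero.
#'
#' @param path path to an `.mrc`/`.map` file.
#' @param allow_anisotropic accept per-axis voxel sizes differing by more
#'   than 1\%; the returned `voxel_size` is then their mean and the per-axis
#'   values are attached as attribute `"voxel_size_xyz"`.
#' @return A [density_map].
#' @export
read_map <- function(path, allow_anisotropic = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nxyz <- ints[1:3]
  mode <- ints[4]
  nstart <- ints[5:7]
  mxyz <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # cell angles
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/dmax/dmean
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # ispg
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "raw", n = 100)                                 # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "raw", n = 1024 - 208)                          # map/machst/rms/labels

  if (any(nxyz < 1)) stop("invalid grid dimensions in header")
  if (!mode %in% c(0L, 1L, 2L, 12L))
    stop("unsupported MRC mode ", mode, " (not a real-valued map mode)")
  if (any(mxyz < 1) || any(cella <= 0))
    stop("zero or negative voxel size in header")
  if (!setequal(mapcrs, 1:3))
    stop("invalid MAPC/MAPR/MAPS axis correspondence")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)

  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.double(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.double(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                            endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "12" = decode_half(readBin(con, "integer", n = n, size = 2,
                               signed = FALSE, endian = "little")))
  if (length(vals) != n) stop("truncated map data")
  if (!all(is.finite(vals))) stop("map contains non-finite values")

  raw_arr <- array(vals, dim = nxyz)
  # file dim j runs along crystal axis mapcrs[j]; permute to [x, y, z]
  perm <- match(1:3, mapcrs)
  arr <- aperm(raw_arr, perm)

  vox_xyz <- cella / mxyz
  spread <- (max(vox_xyz) - min(vox_xyz)) / mean(vox_xyz)
  if (spread > 0.01 && !allow_anisotropic)
    stop(sprintf(paste0("anisotropic voxel size (%.4g/%.4g/%.4g A); pass ",
                        "allow_anisotropic = TRUE to accept"),
                 vox_xyz[1], vox_xyz[2], vox_xyz[3]))
  if (all(orig == 0) && any(nstart != 0)) {
    orig <- nstart[perm] * vox_xyz
  }
  m <- density_map(arr, voxel_size = mean(vox_xyz), origin = orig)
  if (spread > 0.01) attr(m, "voxel_size_xyz") <- vox_xyz
  m
}

#' Write a density map as MRC2014
#'
#' Always writes mode 2 (float32) with `MAPC/MAPR/MAPS = 1,2,3`, header
#' statistics recomputed from the data, and the map origin in the `ORIGIN`
#' record.
#'
#' @param map a [density_map].
#' @param path output file path; the parent directory must exist.
#' @export
write_map <- function(map, path) {
  stopifnot(is_density_map(map))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  vals <- as.numeric(map$data)
  wi(d)                      # nx ny nz
  wi(2L)                     # mode float32
  wi(c(0L, 0L, 0L))          # nstart
  wi(d)                      # mx my mz
  wf(d * map$voxel_size)     # cella
  wf(c(90, 90, 90))          # cellb
  wi(1:3)                    # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(0L)                     # ispg
  wi(0L)                     # nsymbt
  writeBin(raw(100), con)    # extra (word 27-49)
  wf(map$origin)             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(vals) * sqrt((length(vals) - 1) / length(vals)))  # rms
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # labels
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

# IEEE 754 half-precision decode from unsigned 16-bit integers
decode_half <- function(u) {
  s <- ifelse(bitwAnd(u, 0x8000L) != 0L, -1, 1)
  e <- bitwAnd(bitwShiftR(u, 10L), 0x1FL)
  f <- bitwAnd(u, 0x3FFL)
  out <- numeric(length(u))
  norm <- e > 0L & e < 31L
  out[norm] <- s[norm] * 2^(e[norm] - 15) * (1 + f[norm] / 1024)
  sub <- e == 0L
  out[sub] <- s[sub] * 2^(-14) * (f[sub] / 1024)
  if (any(e == 31L & f == 0L)) stop("map contains infinite values")
  if (any(e == 31L & f != 0L)) stop("map contains NaN values")
  out
}

#' Average two half maps
#'
#' Full maps are obtained as the voxel-wise arithmetic mean of the two
#' half-set reconstructions; metadata is copied from the first half map.
#'
#' @param half1,half2 [density_map]s on the same grid (shape and voxel
#'   size within `1e-4` relative tolerance).
#' @return A [density_map] containing `(half1 + half2) / 2`.
#' @export
average_half_maps <- function(half1, half2) {
  stopifnot(is_density_map(half1), is_density_map(half2))
  check_same_grid(half1, half2)
  density_map((half1$data + half2$data) / 2,
              voxel_size = half1$voxel_size, origin = half1$origin)
}
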