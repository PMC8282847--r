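test_that("MRC write/read round-trip is bit-exact with full metadata", {
  arr <- as_f32(array(rnorm(4 * 5 * 6), dim = c(4, 5, 6)))
  m <- density_map(arr, voxel_size = 1.5, origin = c(10, 20, 30))
  p1 <- tempfile(fileext = ".mrc")
  p2 <- tempfile(fileext = ".mrc")
  write_map(m, p1)
  r1 <- read_map(p1)
  expect_identical(r1$data, arr)          # float32 data survives exactly
  expect_equal(r1$voxel_size, 1.5)
  expect_equal(r1$origin, c(10, 20, 30))
  write_map(r1, p2)                        # full round trip
  expect_identical(read_map(p2)$data, r1$data)
  unlink(c(p1, p2))
})

test_that("header statistics match the data within float32 rounding", {
  m <- noise_map(8, seed = 3)
  p <- tempfile(fileext = ".mrc")
  write_map(m, p)
  con <- file(p, "rb")
  readBin(con, "raw", n = 76)
  st <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  close(con)
  expect_equal(st[1], min(m$data), tolerance = 1e-6)
  expect_equal(st[2], max(m$data), tolerance = 1e-6)
  expect_equal(st[3], mean(m$data), tolerance = 1e-6)
  unlink(p)
})

test_that("permuted MAPC/MAPR/MAPS axis orders canonicalize to the same array", {
  arr <- as_f32(array(rnorm(3 * 4 * 5), dim = c(3, 4, 5)))
  ref <- tempfile(fileext = ".mrc")
  write_mrc_raw(arr, ref, voxel = 1.2, axis_order = 1:3)
  base <- read_map(ref)
  for (ao in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1), c(1, 3, 2))) {
    p <- tempfile(fileext = ".mrc")
    write_mrc_raw(arr, p, voxel = 1.2, axis_order = ao)
    r <- read_map(p)
    expect_identical(r$data, base$data)
    unlink(p)
  }
  unlink(ref)
})

test_that("integer map modes 0 and 1 read correctly", {
  arr <- array(sample(-100:100, 4^3, replace = TRUE), dim = c(4, 4, 4))
  p <- tempfile(fileext = ".mrc")
  write_mrc_raw(arr, p, mode = 1L)
  expect_equal(read_map(p)$data, arr + 0)
  small <- array(sample(-100:100, 4^3, replace = TRUE), dim = c(4, 4, 4))
  write_mrc_raw(small, p, mode = 0L)
  expect_equal(read_map(p)$data, small + 0)
  unlink(p)
})

test_that("read_map rejects bad files and anisotropy without the override", {
  expect_error(read_map(tempfile()), "not found")
  arr <- array(rnorm(4^3), dim = c(4, 4, 4))
  p <- tempfile(fileext = ".mrc")
  write_mrc_raw(arr, p, mode = 2L)
  # corrupt the mode field to an unsupported complex mode (4)
  con <- file(p, "r+b")
  seek(con, 12, rw = "write")
  writeBin(4L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_map(p), "mode")
  # anisotropic cell: stretch CELLA x
  write_mrc_raw(arr, p, mode = 2L)
  con <- file(p, "r+b")
  seek(con, 40, rw = "write")
  writeBin(8.0, con, size = 4, endian = "little")  # cella x: 8 A over 4 voxels
  close(con)
  expect_error(read_map(p), "anisotropic")
  r <- read_map(p, allow_anisotropic = TRUE)
  expect_equal(attr(r, "voxel_size_xyz"), c(2, 1, 1))
  unlink(p)
})

test_that("half-precision (mode 12) values decode exactly", {
  # representable half values round-trip through the decoder
  u <- c(0x3C00L, 0xBC00L, 0x4000L, 0x3800L, 0x0000L, 0x0001L)
  expect_equal(emrestore:::decode_half(u),
               c(1, -1, 2, 0.5, 0, 2^-24))
})

test_that("average_half_maps averages and halves the noise variance", {
  v <- blob_map(16)
  expect_equal(average_half_maps(v, v)$data, v$data)
  up <- density_map(v$data + 1, v$voxel_size)
  dn <- density_map(v$data - 1, v$voxel_size)
  expect_equal(average_half_maps(up, dn)$data, v$data)
  set.seed(42)
  n <- 64
  sigma <- 0.7
  h1 <- density_map(v2 <- array(rnorm(n^3, 0, sigma), dim = c(n, n, n)))
  h2 <- density_map(array(rnorm(n^3, 0, sigma), dim = c(n, n, n)))
  avg <- average_half_maps(h1, h2)
  expect_equal(stats::var(as.vector(avg$data)), sigma^2 / 2, tolerance = 0.05)
  expect_error(average_half_maps(v, blob_map(8)), "shapes")
})

test_that("resampling to the working grid follows the shape arithmetic", {
  m <- density_map(blob_map(32)$data, voxel_size = 2)
  rs <- resample_to_working_grid(m)
  expect_equal(dim(rs$map$data), c(64L, 64L, 64L))
  expect_equal(rs$map$voxel_size, 1.0)
  # no-op when already on the working grid
  m1 <- blob_map(24, voxel = 1)
  rs1 <- resample_to_working_grid(m1)
  expect_equal(rs1$map$data, m1$data, tolerance = 1e-6)
  # degenerate output shape
  expect_error(resample_to_working_grid(density_map(array(1:27 + 0,
    dim = c(3, 3, 3)), voxel_size = 1), target_voxel = 2), "degenerate")
})

test_that("band-limited maps survive the resample round trip", {
  m <- density_map(blob_map(32, sigma = 4)$data, voxel_size = 2)
  rs <- resample_to_working_grid(m)
  back <- resize_to_original(rs$map, rs$record)
  expect_equal(dim(back$data), dim(m$data))
  expect_equal(back$voxel_size, m$voxel_size)
  expect_gt(cor(as.vector(back$data), as.vector(m$data)), 0.999)
})

test_that("fourier resampling is linear", {
  a <- blob_map(20, seed = 1)$data
  b <- blob_map(20, seed = 2)$data
  f <- function(x) emrestore:::fourier_resize(x, c(30L, 30L, 30L))
  lhs <- f(2 * a + 3 * b)
  rhs <- 2 * f(a) + 3 * f(b)
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("inconsistent resample records are rejected", {
  m <- blob_map(16)
  rec <- structure(list(original_shape = c(0L, 0L, 0L),
                        original_voxel_size = 1, working_voxel_size = 1,
                        method = "fourier"), class = "resample_record")
  expect_error(resize_to_original(m, rec), "inconsistent")
})

test_that("an independent MRC implementation reads our files identically", {
  # gemmi (Python) as an external oracle for the writer
  arr <- as_f32(array(rnorm(5 * 6 * 7), dim = c(5, 6, 7)))
  m <- density_map(arr, voxel_size = 1.3, origin = c(1, 2, 3))
  p <- tempfile(fileext = ".mrc")
  write_map(m, p)
  py <- sprintf(paste0(
    "import gemmi, json; g = gemmi.read_ccp4_map('%s');",
    "import numpy as np; a = np.array(g.grid, copy=False);",
    "print(json.dumps({'shape': list(a.shape),",
    " 'sum': float(np.float64(a).sum()),",
    " 'corner': float(a[0,0,0]), 'vox': round(g.grid.spacing[0], 6)}))"), p)
  out <- suppressWarnings(system2("python", c("-c", shQuote(py)),
                                  stdout = TRUE, stderr = TRUE))
  ok <- length(out) > 0 && any(grepl("shape", out))
  expect_true(ok)
  info <- jsonlite::fromJSON(out[grepl("shape", out)][1])
  expect_equal(sort(info$shape), sort(dim(arr)))
  expect_equal(info$sum, sum(arr), tolerance = 1e-6)
  expect_equal(info$corner, arr[1, 1, 1], tolerance = 1e-6)
  expect_equal(info$vox, 1.3, tolerance = 1e-4)
  unlink(p)
})
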