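# shared fixtures and independent oracles, built in code at test time

# small band-limited blob map: sum of a few broad Gaussians
blob_map <- function(n = 24, voxel = 1, seed = 1, k = 4, sigma = 3) {
  set.seed(seed)
  arr <- array(0, dim = c(n, n, n))
  ctr <- matrix(runif(3 * k, n * 0.3, n * 0.7), ncol = 3)
  idx <- seq_len(n)
  for (j in seq_len(k)) {
    gx <- exp(-(idx - ctr[j, 1])^2 / (2 * sigma^2))
    gy <- exp(-(idx - ctr[j, 2])^2 / (2 * sigma^2))
    gz <- exp(-(idx - ctr[j, 3])^2 / (2 * sigma^2))
    arr <- arr + outer(outer(gx, gy), gz)
  }
  density_map(arr, voxel_size = voxel)
}

noise_map <- function(n = 24, mean = 0, sd = 1, voxel = 1, seed = 1) {
  set.seed(seed)
  density_map(array(rnorm(n^3, mean, sd), dim = c(n, n, n)),
              voxel_size = voxel)
}

# round doubles to float32 so bit-exact map round-trip comparisons are valid
as_f32 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  close(con)
  con <- file(tf, "rb")
  v <- readBin(con, "numeric", n = length(x), size = 4, endian = "little")
  close(con)
  array(v, dim = dim(x))
}

# independent minimal MRC writer (separate from the package's write_map):
# writes data in an arbitrary MAPC/MAPR/MAPS axis order and arbitrary mode
write_mrc_raw <- function(arr_xyz, path, voxel = 1, axis_order = 1:3,
                          mode = 2L, origin = c(0, 0, 0)) {
  # file dim j runs along crystal axis axis_order[j]
  perm <- axis_order            # file array = aperm(canonical, axis_order)
  fa <- aperm(arr_xyz, perm)
  d <- dim(fa)
  dxyz <- dim(arr_xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(mode); wi(c(0L, 0L, 0L)); wi(dxyz)
  wf(dxyz * voxel); wf(c(90, 90, 90))
  wi(axis_order)
  wf(c(min(fa), max(fa), mean(fa)))
  wi(0L); wi(0L)
  writeBin(raw(100), con)
  wf(origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0L)
  writeBin(raw(800), con)
  v <- as.numeric(fa)
  if (mode == 2L) writeBin(v, con, size = 4, endian = "little")
  else if (mode == 0L) writeBin(as.integer(round(v)), con, size = 1)
  else if (mode == 1L) writeBin(as.integer(round(v)), con, size = 2,
                                endian = "little")
  else stop("unsupported mode in helper")
  invisible(path)
}

# brute-force FSC by direct DFT sums (no fft), for tiny grids
fsc_bruteforce <- function(a, b, voxel = 1) {
  d <- dim(a)
  stopifnot(all(d == d[1]))
  n <- d[1]
  dft <- function(x) {
    out <- array(0i, dim = d)
    for (k1 in 0:(n - 1)) for (k2 in 0:(n - 1)) for (k3 in 0:(n - 1)) {
      ph <- outer(outer(exp(-2i * pi * k1 * (0:(n - 1)) / n),
                        exp(-2i * pi * k2 * (0:(n - 1)) / n)),
                  exp(-2i * pi * k3 * (0:(n - 1)) / n))
      out[k1 + 1, k2 + 1, k3 + 1] <- sum(x * ph)
    }
    out
  }
  F1 <- dft(a)
  F2 <- dft(b)
  ks <- 0:(n - 1)
  ks <- ifelse(ks <= n / 2, ks, ks - n)
  r <- sqrt(outer(outer(ks^2, ks^2, "+"), ks^2, "+"))
  shell <- as.integer(round(r))
  keep <- shell <= n %/% 2
  num <- tapply(Re(F1 * Conj(F2))[keep], shell[keep], sum)
  d1 <- tapply(Mod(F1)[keep]^2, shell[keep], sum)
  d2 <- tapply(Mod(F2)[keep]^2, shell[keep], sum)
  list(shell = as.integer(names(num)),
       fsc = as.numeric(num / sqrt(d1 * d2)))
}

# hand-built fsc_curve for threshold/interpolation tests
make_curve <- function(freq, val, voxel = 1) {
  structure(list(shell_freq = freq, fsc = val,
                 n_voxels = rep(10L, length(freq)), voxel_size = voxel),
            class = "fsc_curve")
}

# tiny U-net configuration that exercises every code path quickly
tiny_config <- function() {
  unet_config(n_levels = 2L, convs_per_block = 2L, base_filters = c(4L, 6L),
              norm_groups = 2L)
}
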