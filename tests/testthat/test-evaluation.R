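test_that("FSC self- and anti-correlation are exact per shell", {
  v <- blob_map(24, seed = 6)
  cv <- fsc(v, v)
  expect_true(all(abs(cv$fsc - 1) < 1e-9))
  neg <- density_map(-v$data, v$voxel_size)
  expect_true(all(abs(fsc(v, neg)$fsc + 1) < 1e-9))
  expect_true(all(diff(cv$shell_freq) > 0))
  expect_lte(max(cv$shell_freq), 1 / (2 * v$voxel_size) + 1e-12)
  expect_true(all(cv$n_voxels >= 1))
})

test_that("FFT shell sums match a direct-DFT brute force on 8^3 maps", {
  set.seed(7)
  a <- array(rnorm(8^3), dim = c(8, 8, 8))
  b <- array(rnorm(8^3), dim = c(8, 8, 8))
  ours <- fsc(a, b, voxel_size = 1)
  brute <- fsc_bruteforce(a, b)
  expect_equal(ours$fsc, brute$fsc, tolerance = 1e-6)
})

test_that("independent noise maps decorrelate within the counting bound", {
  set.seed(8)
  n <- 64
  a <- array(rnorm(n^3), dim = c(n, n, n))
  b <- array(rnorm(n^3), dim = c(n, n, n))
  cv <- fsc(a, b, voxel_size = 1)
  use <- cv$shell_freq > 0
  ok <- abs(cv$fsc[use]) <= 3 / sqrt(cv$n_voxels[use])
  expect_gte(mean(ok), 0.95)
})

test_that("FSC is symmetric and invariant to positive scaling", {
  a <- blob_map(16, seed = 1)$data
  b <- blob_map(16, seed = 2)$data
  expect_identical(fsc(a, b, voxel_size = 1)$fsc,
                   fsc(b, a, voxel_size = 1)$fsc)
  expect_equal(fsc(5 * a, 0.2 * b, voxel_size = 1)$fsc,
               fsc(a, b, voxel_size = 1)$fsc, tolerance = 1e-12)
  expect_error(fsc(array(0, dim = c(8, 8, 8)), a[1:8, 1:8, 1:8],
                   voxel_size = 1), "all-zero")
})

test_that("threshold resolution interpolates the worked example", {
  curve <- make_curve(c(0.1, 0.2, 0.3), c(0.9, 0.6, 0.2))
  res <- resolution_at_threshold(curve, 0.5)
  expect_equal(as.numeric(res), 1 / 0.225, tolerance = 1e-3)   # 4.444 A
  expect_identical(attr(res, "flag"), "crossed")
})

test_that("non-crossing curves return flagged boundary resolutions", {
  v <- blob_map(16)
  res <- resolution_at_threshold(fsc(v, v), 0.5)
  expect_identical(attr(res, "flag"), "nyquist")
  expect_equal(as.numeric(res), 2 * v$voxel_size)
  low <- make_curve(c(0.1, 0.2, 0.3), c(0.2, 0.1, 0.05))
  res2 <- resolution_at_threshold(low, 0.5)
  expect_identical(attr(res2, "flag"), "below")
  expect_identical(as.numeric(res2), Inf)
  expect_error(resolution_at_threshold(make_curve(0.1, 0.5), 1.5),
               "threshold")
})

test_that("resolution is monotone in pointwise-raised curves", {
  f <- seq(0.05, 0.5, by = 0.05)
  lo <- make_curve(f, seq(0.95, 0.1, length.out = length(f)))
  hi <- make_curve(f, pmin(1, lo$fsc + 0.2))
  expect_lte(as.numeric(resolution_at_threshold(hi, 0.5)),
             as.numeric(resolution_at_threshold(lo, 0.5)))
})

test_that("soft mask edges are cosine-shaped and bounded", {
  m <- array(FALSE, dim = c(24, 24, 24))
  m[6:19, 6:19, 6:19] <- TRUE
  soft <- soften_mask(mask_volume(m), width = 3)
  expect_true(all(soft$data >= 0 & soft$data <= 1))
  expect_true(all(soft$data[!m] == 0))
  expect_equal(soft$data[12, 12, 12], 1)     # deep interior saturates
  expect_lt(soft$data[6, 12, 12], 1)         # boundary voxels are tapered
  hard <- soften_mask(mask_volume(m), width = 0)
  expect_identical(hard$data, m + 0)
})

test_that("masked FSC reduces to plain FSC for the all-ones mask", {
  a <- blob_map(16, seed = 3)
  b <- blob_map(16, seed = 4)
  ones <- mask_volume(array(1, dim = dim(a$data)))
  expect_equal(masked_fsc(a, b, ones)$fsc, fsc(a, b)$fsc, tolerance = 1e-9)
  msk <- make_mask(a, 0.2, 2)
  expect_true(all(abs(masked_fsc(a, a, msk)$fsc - 1) < 1e-9))
})

test_that("masking away out-of-mask noise raises mid-frequency FSC", {
  set.seed(10)
  sharp <- blob_map(32, k = 2, sigma = 2.5)
  msk <- make_mask(sharp, 0.1, 3)
  noise <- array(rnorm(32^3, 0, 0.3), dim = c(32, 32, 32))
  noise[msk$data > 0] <- 0                   # noise confined outside mask
  noisy <- density_map(sharp$data + noise)
  plain <- fsc(noisy, sharp)
  masked <- masked_fsc(noisy, sharp, msk)
  mid <- which(plain$shell_freq > 0.1 & plain$shell_freq < 0.35)
  expect_gt(mean(masked$fsc[mid]), mean(plain$fsc[mid]))
})

test_that("real-space correlation is affine-invariant and noise-monotone", {
  v <- blob_map(24, seed = 5)
  expect_equal(real_space_cc(v, v), 1)
  aff <- density_map(3 * v$data + 2)
  expect_equal(real_space_cc(v, aff), 1)
  expect_equal(real_space_cc(v, density_map(-2 * v$data + 1)), -1)
  set.seed(11)
  ccs <- vapply(c(0.05, 0.15, 0.4, 1), function(s)
    real_space_cc(v, density_map(v$data +
      array(rnorm(24^3, 0, s), dim = c(24, 24, 24)))), numeric(1))
  expect_true(all(diff(ccs) < 0))
  expect_error(real_space_cc(v, density_map(array(1, dim = dim(v$data)) +
                                              0 * v$data)), "variance")
})

test_that("evaluation reports satisfy the identity baselines", {
  sharp <- lapply(1:2, function(i) blob_map(24, seed = i))
  masks <- lapply(sharp, make_mask, threshold_fraction = 0.2,
                  dilation_radius = 1)
  targets <- mapply(make_target, sharp, masks, SIMPLIFY = FALSE)
  set.seed(3)
  inputs <- lapply(targets, function(t)
    density_map(t$data + array(rnorm(24^3, 0, 0.2), dim = dim(t$data))))
  # predictions identical to targets: perfect scores
  rep1 <- evaluate_run(inputs, targets, targets, masks)
  expect_equal(rep1$cc_pred, rep(1, 2))
  expect_true(all(rep1$res_pred == 2 * targets[[1]]$voxel_size))
  # predictions identical to inputs: the improvement columns collapse
  rep2 <- evaluate_run(inputs, inputs, targets, masks)
  expect_equal(rep2$cc_pred, rep2$cc_input)
  expect_equal(rep2$res_pred, rep2$res_input)
  expect_named(attr(rep1, "summary"),
               c("cc_input", "cc_pred", "res_input", "res_pred",
                 "res_input_masked", "res_pred_masked"))
  p <- tempfile(fileext = ".csv")
  evaluate_run(inputs, targets, targets, masks, out_csv = p)
  expect_equal(nrow(utils::read.csv(p)), 2L)
  unlink(p)
})
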