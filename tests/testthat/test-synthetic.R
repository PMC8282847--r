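test_that("pseudo-models are reproducible chains with 3.8 A spacing", {
  m1 <- random_pseudo_model(40, 96, seed = 3)
  m2 <- random_pseudo_model(40, 96, seed = 3)
  expect_identical(m1, m2)
  pos <- as.matrix(m1$atoms[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(pos)^2))
  expect_true(all(abs(steps - 3.8) < 1e-6))
  expect_true(all(pos >= 12 - 1e-9 & pos <= 96 - 12 + 1e-9))
  # degenerate single-atom model
  m0 <- random_pseudo_model(1, 48, seed = 1)
  expect_equal(nrow(m0$atoms), 1L)
  expect_error(random_pseudo_model(10, 10, seed = 1), "too small")
})

test_that("gaussian rendering peaks at the amplitude and superposes", {
  one <- structure(list(atoms = data.frame(x = 16, y = 16, z = 16,
                                           amplitude = 2.5, bfactor = 30),
                        box_size = rep(32, 3)), class = "pseudo_model")
  m <- simulate_sharp_map(one, voxel_size = 1)
  # atom sits exactly on voxel (17, 17, 17): x/voxel + 1
  expect_equal(max(m$data), 2.5, tolerance = 1e-9)
  expect_equal(which.max(m$data),
               17 + 32 * (16 + 32 * 16))
  expect_true(all(m$data >= 0))
  # symmetry of the profile around the peak
  expect_equal(m$data[16, 17, 17], m$data[18, 17, 17])
  # superposition and homogeneity
  two <- one
  two$atoms <- rbind(two$atoms,
                     data.frame(x = 6, y = 6, z = 6, amplitude = 1,
                                bfactor = 10))
  msum <- simulate_sharp_map(two, voxel_size = 1)
  single2 <- two
  single2$atoms <- two$atoms[2, ]
  expect_equal(msum$data,
               m$data + simulate_sharp_map(single2, voxel_size = 1)$data,
               tolerance = 1e-12)
  dbl <- one
  dbl$atoms$amplitude <- 5
  expect_equal(simulate_sharp_map(dbl, 1)$data, 2 * m$data,
               tolerance = 1e-12)
  out <- one
  out$atoms$x <- 40
  expect_error(simulate_sharp_map(out, 1), "outside")
})

test_that("degradation is exact at B = 0 and halves average to the full map", {
  sharp <- blob_map(32)
  d0 <- degrade_map(sharp, degrade_spec(0, 0, seed = 1))
  expect_equal(d0$full$data, sharp$data, tolerance = 1e-6)
  dn <- degrade_map(sharp, degrade_spec(80, 0.05, seed = 2))
  expect_equal((dn$half1$data + dn$half2$data) / 2, dn$full$data,
               tolerance = 1e-12)
  # reruns with the same seed are identical
  dn2 <- degrade_map(sharp, degrade_spec(80, 0.05, seed = 2))
  expect_identical(dn$full$data, dn2$full$data)
})

test_that("the Guinier slope of the attenuated map recovers the B-factor", {
  model <- random_pseudo_model(60, 64, seed = 5)
  sharp <- simulate_sharp_map(model)
  for (B in c(50, 100, 200)) {
    deg <- degrade_map(sharp, degrade_spec(B, 0, seed = 1))
    expect_equal(estimate_bfactor(sharp, deg$signal), B, tolerance = 0.1)
  }
})

test_that("spatially varying B blends between the two attenuation levels", {
  sharp <- blob_map(32)
  lo <- degrade_map(sharp, degrade_spec(50, 0, seed = 3))$signal$data
  hi <- degrade_map(sharp, degrade_spec(150, 0, seed = 3))$signal$data
  mix <- degrade_map(sharp, degrade_spec(100, 0, local_B_range = c(50, 150),
                                         seed = 3))$signal$data
  expect_true(all(mix >= pmin(lo, hi) - 1e-6 & mix <= pmax(lo, hi) + 1e-6))
})

test_that("band-limited noise has the requested scale", {
  sharp <- blob_map(32)
  d <- degrade_map(sharp, degrade_spec(0, 0.2, noise_type = "bandlimited",
                                       seed = 4))
  expect_equal(stats::sd(d$half1$data - d$signal$data), 0.2,
               tolerance = 0.02)
})

test_that("mask support shrinks with threshold and grows with dilation", {
  sharp <- blob_map(32, k = 1)
  sup <- vapply(c(0.1, 0.3, 0.6, 0.9), function(tf)
    sum(make_mask(sharp, tf, 0)$data), numeric(1))
  expect_true(all(diff(sup) < 0))
  m0 <- make_mask(sharp, 0.3, 0)$data
  m2 <- make_mask(sharp, 0.3, 2)$data
  expect_true(all(m2[m0 > 0] == 1))
  expect_gt(sum(m2), sum(m0))
  expect_error(make_mask(density_map(array(0, dim = c(8, 8, 8))), 0.5, 0),
               "empty support")
})

test_that("targets vanish exactly outside the mask", {
  sharp <- blob_map(24)
  msk <- make_mask(sharp, 0.2, 1)
  tg <- make_target(sharp, msk)
  expect_true(all(tg$data[msk$data == 0] == 0))
  expect_identical(tg$data > 0, sharp$data > 0 & msk$data > 0)
  expect_lte(sum(tg$data), sum(sharp$data))
  ones <- mask_volume(array(1, dim = dim(sharp$data)))
  expect_equal(make_target(sharp, ones)$data, sharp$data)
})

test_that("generated datasets are reproducible and obey their own spec", {
  ds1 <- generate_dataset(3, seed = 21, box_size = 64,
                          n_atoms_range = c(20L, 40L),
                          keep = c("full", "half1", "mask"))
  ds2 <- generate_dataset(3, seed = 21, box_size = 64,
                          n_atoms_range = c(20L, 40L), keep = character())
  expect_identical(ds1$manifest, ds2$manifest)
  for (i in seq_len(3)) {
    rec <- ds1$records[[i]]
    # each half map carries noise of the drawn sigma; the full map
    # (average of two halves) carries sigma / sqrt(2)
    st <- estimate_noise_stats(rec$half1)
    expect_equal(st$noise_std, ds1$manifest$noise_sigma[i], tolerance = 0.05)
    stf <- estimate_noise_stats(rec$full)
    expect_equal(stf$noise_std, ds1$manifest$noise_sigma[i] / sqrt(2),
                 tolerance = 0.05)
    expect_lt(mean(rec$mask$data), 0.5)   # tight targets
  }
})
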