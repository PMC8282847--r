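test_that("augmentation is a no-op when every probability is zero", {
  set.seed(1)
  a <- array(rnorm(8^3), dim = c(8, 8, 8))
  b <- array(rnorm(8^3), dim = c(8, 8, 8))
  cfg <- augment_config(rotation_prob = 0, blur_prob = 0, corrupt_prob = 0)
  out <- augment_pair(a, b, cfg)
  expect_identical(out$input, a)
  expect_identical(out$target, b)
})

test_that("the orientation set has 24 proper rotations incl. order-4 ones", {
  set.seed(2)
  a <- array(rnorm(6^3), dim = c(6, 6, 6))
  outs <- lapply(1:24, function(id) rotate_cube(a, id))
  # identity is orientation 1; all orientations are distinct
  expect_identical(outs[[1]], a)
  expect_equal(length(unique(lapply(outs, as.vector))), 24L)
  # single-axis 90-degree rotations return after four applications
  order4 <- vapply(1:24, function(id) {
    r <- a
    for (k in 1:4) r <- rotate_cube(r, id)
    identical(r, a) && !identical(rotate_cube(a, id), a)
  }, logical(1))
  expect_gte(sum(order4), 6L)
})

test_that("rotation transforms input and target identically", {
  set.seed(3)
  a <- array(rnorm(8^3), dim = c(8, 8, 8))
  cfg <- augment_config(rotation_prob = 1, blur_prob = 0, corrupt_prob = 0)
  out <- augment_pair(a, a, cfg)
  expect_identical(out$input, out$target)
  expect_equal(sort(as.vector(out$input)), sort(as.vector(a)))
})

test_that("corruption touches one sub-box of the input and never the target", {
  set.seed(4)
  a <- array(rnorm(16^3), dim = c(16, 16, 16))
  b <- array(rnorm(16^3), dim = c(16, 16, 16))
  cfg <- augment_config(rotation_prob = 0, blur_prob = 0, corrupt_prob = 1,
                        corrupt_patch_size = 4L)
  out <- augment_pair(a, b, cfg)
  expect_identical(out$target, b)
  changed <- which(out$input != a, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  spans <- apply(changed, 2, function(ix) diff(range(ix)))
  expect_true(all(spans <= 3))           # confined to a 4^3 box
  expect_lte(nrow(changed), 64)
})

test_that("blurring affects the input only and reduces roughness", {
  set.seed(5)
  a <- array(rnorm(16^3), dim = c(16, 16, 16))
  b <- array(rnorm(16^3), dim = c(16, 16, 16))
  cfg <- augment_config(rotation_prob = 0, blur_prob = 1, corrupt_prob = 0)
  out <- augment_pair(a, b, cfg)
  expect_identical(out$target, b)
  expect_false(identical(out$input, a))
  expect_lt(stats::sd(out$input), stats::sd(a))
})

test_that("rotation-only augmentation leaves the identity predictor's loss unchanged", {
  set.seed(6)
  a <- array(rnorm(8^3), dim = c(8, 8, 8))
  b <- array(rnorm(8^3), dim = c(8, 8, 8))
  for (id in c(2, 7, 13, 24))
    expect_equal(mae_loss(rotate_cube(a, id), rotate_cube(b, id)),
                 mae_loss(a, b))
})

test_that("mae_loss computes hand-checkable values", {
  t <- array(rnorm(4^3), dim = c(4, 4, 4))
  expect_equal(mae_loss(t, t), 0)
  expect_equal(mae_loss(t + 0.2, t), 0.2)
  p <- t
  p[1:32] <- t[1:32] + 0.6
  p[33:64] <- t[33:64] - 0.6
  expect_equal(mae_loss(p, t), 0.6)
  expect_error(mae_loss(array(0, dim = c(2, 2, 2)), t), "mismatch")
})

test_that("plateau schedule halves exactly once for the canonical sequence", {
  losses <- c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)
  st <- emrestore:::plateau_new(patience = 5L)
  decays <- logical(length(losses))
  for (i in seq_along(losses)) {
    st <- emrestore:::plateau_step(st, losses[i])
    decays[i] <- st$decay
  }
  expect_identical(which(decays), 7L)
  # counter was reset by the decay: no second decay until 5 more flat epochs
  for (i in 1:4) {
    st <- emrestore:::plateau_step(st, 0.9)
    expect_false(st$decay)
  }
  st <- emrestore:::plateau_step(st, 0.9)
  expect_true(st$decay)
})

test_that("improvement below the relative threshold does not reset patience", {
  st <- emrestore:::plateau_new(patience = 2L)
  st <- emrestore:::plateau_step(st, 1.0)
  st <- emrestore:::plateau_step(st, 1.0 - 1e-9)   # not a real improvement
  expect_false(st$decay)
  st <- emrestore:::plateau_step(st, 1.0 - 1e-9)
  expect_true(st$decay)
})

make_const_pairs <- function(n, value = 0.3, cube = 8L, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(input = array(rnorm(cube^3, 0, 0.1), dim = rep(cube, 3)),
         target = array(value, dim = rep(cube, 3))))
}

test_that("training learns a constant bias and beats the zero predictor", {
  cfg <- unet_config(n_levels = 1L, convs_per_block = 1L, base_filters = 2L,
                     norm_groups = 1L)
  model <- build_model(cfg, seed = 1)
  tc <- train_config(batch_size = 8L, initial_lr = 0.05, max_epochs = 20L,
                     momentum = 0.9, seed = 1, augment = NULL)
  fit <- train(model, make_const_pairs(8), make_const_pairs(4, seed = 2), tc)
  expect_lt(min(fit$history$val_loss), 0.3)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("training is reproducible and the learning rate never increases", {
  cfg <- unet_config(n_levels = 1L, convs_per_block = 1L, base_filters = 2L,
                     norm_groups = 1L)
  pairs <- make_const_pairs(6)
  vp <- make_const_pairs(3, seed = 9)
  tc <- train_config(batch_size = 2L, max_epochs = 3L, seed = 77)
  f1 <- train(build_model(cfg, seed = 3), pairs, vp, tc)
  f2 <- train(build_model(cfg, seed = 3), pairs, vp, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  lr <- f1$history$lr
  expect_true(all(diff(lr) <= 0))
})

test_that("empty datasets and NaN-producing configs abort cleanly", {
  cfg <- unet_config(n_levels = 1L, convs_per_block = 1L, base_filters = 2L,
                     norm_groups = 1L)
  m <- build_model(cfg, seed = 1)
  expect_error(train(m, list(), make_const_pairs(2), train_config()),
               "empty dataset")
  expect_error(train_config(lr_decay_factor = 1.5), "lr_decay_factor")
})
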