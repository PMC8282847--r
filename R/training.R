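#' @title Training the U-net
#' @description Optimization follows the reference recipe: stochastic
#' gradient descent with a batch of 8 cubes, initial learning rate 1e-3
#' halved when the validation loss has not improved for 5 consecutive
#' epochs, and a mean-absolute-error loss. Augmentation applies random
#' axis-aligned 90-degree rotations (identically to input and target),
#' Gaussian blurring of the input only, and patch corruption of the input
#' only - the target is the clean supervision signal and is never blurred
#' or corrupted.
#' @name training
NULL

#' Augmentation configuration
#'
#' @param rotation_prob probability of applying one of the 24 axis-aligned
#'   cube orientations to both cubes.
#' @param blur_prob probability of Gaussian-blurring the input cube.
#' @param blur_sigma_range range (voxels) from which the blur sigma is
#'   drawn uniformly.
#' @param corrupt_prob probability of replacing a random sub-box of the
#'   input with N(0, 0.1) noise.
#' @param corrupt_patch_size edge (voxels) of the corrupted sub-box; must
#'   be smaller than the cube.
#' @return An `augment_config` object.
#' @export
augment_config <- function(rotation_prob = 0.3, blur_prob = 0.3,
                           blur_sigma_range = c(0.3, 1.5),
                           corrupt_prob = 0.3, corrupt_patch_size = 16L) {
  p <- c(rotation_prob, blur_prob, corrupt_prob)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  if (any(blur_sigma_range < 0) || length(blur_sigma_range) != 2L)
    stop("blur_sigma_range must be two nonnegative values")
  structure(list(rotation_prob = rotation_prob, blur_prob = blur_prob,
                 blur_sigma_range = sort(blur_sigma_range),
                 corrupt_prob = corrupt_prob,
                 corrupt_patch_size = as.integer(corrupt_patch_size)),
            class = "augment_config")
}

# the 24 proper axis-aligned orientations as (axis permutation, axis flips)
cube_orientations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  psign <- c(1, -1, -1, 1, 1, -1)
  out <- list()
  for (i in seq_along(perms))
    for (f1 in c(1, -1)) for (f2 in c(1, -1)) for (f3 in c(1, -1))
      if (psign[i] * f1 * f2 * f3 == 1)
        out[[length(out) + 1L]] <- list(perm = perms[[i]],
                                        flip = c(f1, f2, f3))
  out
}
.orient_cache <- new.env(parent = emptyenv())

#' Rotate a cube into one of its 24 proper orientations
#'
#' Orientation 1 is the identity. Single-axis 90-degree rotations are
#' elements of order 4: applying the same such orientation four times
#' recovers the original cube.
#'
#' @param a cubic 3-d array.
#' @param id orientation index in 1..24.
#' @return The reoriented array.
#' @export
rotate_cube <- function(a, id) {
  if (is.null(.orient_cache$o)) .orient_cache$o <- cube_orientations()
  rot <- .orient_cache$o[[id]]
  a <- aperm(a, rot$perm)
  d <- dim(a)
  if (rot$flip[1] < 0) a <- a[d[1]:1, , , drop = FALSE]
  if (rot$flip[2] < 0) a <- a[, d[2]:1, , drop = FALSE]
  if (rot$flip[3] < 0) a <- a[, , d[3]:1, drop = FALSE]
  a
}

# periodic Gaussian blur via FFT; sigma in voxels
gaussian_blur_cube <- function(a, sigma) {
  d <- dim(a)
  fr <- lapply(d, function(n) {
    k <- c(0:(n %/% 2), if (n > 1) -((n - (n %/% 2 + 1)):1)) / n
    k[seq_len(n)]
  })
  f2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  h <- exp(-2 * pi^2 * sigma^2 * f2)
  Re(stats::fft(stats::fft(a) * h, inverse = TRUE)) / prod(d)
}

#' Augment a training pair
#'
#' Rotation is applied identically to input and target; blur and patch
#' corruption affect the input only. Draws from R's global RNG, so results
#' are deterministic after `set.seed()`.
#'
#' @param input,target cubic 3-d arrays of identical shape.
#' @param config an [augment_config].
#' @return `list(input =, target =)` with the augmented pair.
#' @export
augment_pair <- function(input, target, config = augment_config()) {
  if (!identical(dim(input), dim(target))) stop("cube shape mismatch")
  if (stats::runif(1) < config$rotation_prob) {
    id <- sample.int(24L, 1L)
    input <- rotate_cube(input, id)
    target <- rotate_cube(target, id)
  }
  if (stats::runif(1) < config$blur_prob) {
    sigma <- stats::runif(1, config$blur_sigma_range[1],
                          config$blur_sigma_range[2])
    input <- gaussian_blur_cube(input, sigma)
  }
  if (stats::runif(1) < config$corrupt_prob) {
    ps <- min(config$corrupt_patch_size, dim(input)[1] - 1L)
    o <- vapply(dim(input), function(n) sample.int(n - ps + 1L, 1L),
                integer(1))
    input[o[1]:(o[1] + ps - 1L), o[2]:(o[2] + ps - 1L),
          o[3]:(o[3] + ps - 1L)] <- stats::rnorm(ps^3, 0, 0.1)
  }
  list(input = input, target = target)
}

#' Mean absolute error between cube batches
#'
#' @param pred,target arrays of identical shape.
#' @return Mean of `abs(pred - target)` over every voxel (and batch entry).
#' @export
mae_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  mean(abs(pred - target))
}

#' Training configuration
#'
#' @param batch_size cubes per SGD step.
#' @param initial_lr initial learning rate.
#' @param lr_decay_factor multiplier applied on plateau (in (0, 1)).
#' @param lr_patience epochs without validation improvement before decay.
#' @param max_epochs maximum epochs.
#' @param early_stop_patience optional epochs without improvement before
#'   stopping early.
#' @param momentum SGD momentum (0 = plain SGD, the default).
#' @param clip_norm global gradient-norm clip; `Inf` disables.
#' @param seed run seed (shuffling, augmentation).
#' @param augment an [augment_config]; `NULL` disables augmentation.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 8L, initial_lr = 1e-3,
                         lr_decay_factor = 0.5, lr_patience = 5L,
                         max_epochs = 25L, early_stop_patience = NULL,
                         momentum = 0, clip_norm = 1.0, seed = 1L,
                         augment = augment_config()) {
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1)
    stop("lr_decay_factor must lie in (0, 1)")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (lr_patience < 1L) stop("lr_patience must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 momentum = momentum, clip_norm = clip_norm,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

# plateau schedule: improvement means strictly below best by >= 1e-5
# relative; the counter resets on improvement and after each decay
plateau_new <- function(patience, min_delta = 1e-5) {
  list(best = Inf, count = 0L, patience = as.integer(patience),
       min_delta = min_delta)
}

plateau_step <- function(state, val_loss) {
  decay <- FALSE
  if (val_loss < state$best * (1 - state$min_delta)) {
    state$best <- val_loss
    state$count <- 0L
  } else {
    state$count <- state$count + 1L
    if (state$count >= state$patience) {
      decay <- TRUE
      state$count <- 0L
    }
  }
  state$decay <- decay
  state
}

stack_cubes <- function(cubes) {
  d <- dim(cubes[[1]])
  array(unlist(cubes, use.names = FALSE), dim = c(d, length(cubes)))
}

validation_mae <- function(params, cfg, pairs, batch_size) {
  tot <- 0
  n <- 0
  i <- 1L
  while (i <= length(pairs)) {
    j <- min(i + batch_size - 1L, length(pairs))
    x <- stack_cubes(lapply(pairs[i:j], `[[`, "input"))
    t <- stack_cubes(lapply(pairs[i:j], `[[`, "target"))
    y <- cpp_unet_forward(params, cfg, x)
    tot <- tot + sum(abs(y - t))
    n <- n + length(t)
    i <- j + 1L
  }
  tot / n
}

#' Train a U-net on paired cubes
#'
#' One epoch is a full pass over the (shuffled) training pairs. Validation
#' MAE is computed without augmentation after each epoch; the learning rate
#' follows the plateau schedule, and the weights with the best validation
#' loss are returned. Fully reproducible under the config seed.
#'
#' @param model a `unet_model` from [build_model()].
#' @param train_pairs,val_pairs lists of `list(input =, target =)` cubes,
#'   already normalized.
#' @param config a [train_config].
#' @param verbose print one line per epoch.
#' @return A list: `model` (best-validation weights), `last_model`,
#'   `history` (data.frame epoch/train_loss/val_loss/lr), `best_epoch`.
#' @export
train <- function(model, train_pairs, val_pairs, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(train_pairs) == 0L || length(val_pairs) == 0L)
    stop("empty dataset")
  cfg <- unclass(model$config)
  params <- model$params
  vel <- lapply(params, function(p) array(0, dim = dim(p)))
  set.seed(config$seed)
  sched <- plateau_new(config$lr_patience)
  lr <- config$initial_lr
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  best_val <- Inf
  best_epoch <- NA_integer_
  best_params <- params
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(train_pairs))
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + config$batch_size - 1L, length(ord))
      batch <- train_pairs[ord[i:j]]
      if (!is.null(config$augment))
        batch <- lapply(batch, function(p)
          augment_pair(p$input, p$target, config$augment))
      x <- stack_cubes(lapply(batch, `[[`, "input"))
      t <- stack_cubes(lapply(batch, `[[`, "target"))
      res <- cpp_unet_loss_grad(params, cfg, x, t)
      if (!is.finite(res$loss))
        stop(sprintf("non-finite loss at epoch %d (lr %.3g); aborting",
                     epoch, lr))
      g <- res$grads
      if (is.finite(config$clip_norm)) {
        gn <- sqrt(sum(vapply(g, function(m) sum(m^2), numeric(1))))
        if (gn > config$clip_norm)
          g <- lapply(g, function(m) m * (config$clip_norm / gn))
      }
      if (config$momentum > 0) {
        vel <- mapply(function(v, m) config$momentum * v + m, vel, g,
                      SIMPLIFY = FALSE)
        params <- mapply(function(p, v) p - lr * v, params, vel,
                         SIMPLIFY = FALSE)
      } else {
        params <- mapply(function(p, m) p - lr * m, params, g,
                         SIMPLIFY = FALSE)
      }
      ep_loss <- ep_loss + res$loss
      nb <- nb + 1L
      i <- j + 1L
    }
    val <- validation_mae(params, cfg, val_pairs, config$batch_size)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = val, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, ep_loss / nb, val, lr))
    if (val < best_val) {
      best_val <- val
      best_epoch <- epoch
      best_params <- params
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    sched <- plateau_step(sched, val)
    if (sched$decay) lr <- lr * config$lr_decay_factor
    if (!is.null(config$early_stop_patience) &&
        stall >= config$early_stop_patience) break
  }
  best <- model
  best$params <- best_params
  last <- model
  last$params <- params
  list(model = best, last_model = last, history = hist,
       best_epoch = best_epoch)
}
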