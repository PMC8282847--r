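#' 3D U-net architecture hyperparameters
#'
#' The default configuration mirrors the reference architecture: three
#' resolution levels with three convolutions per block (kernel 3, same
#' padding), 32/64/128 filters, each convolution followed by group
#' normalization and a per-channel PReLU; downsampling by stride-2 strided
#' convolution (doubling channels), upsampling by stride-2 transposed
#' convolution, channel-concatenation skip connections, and a final linear
#' 1x1x1 convolution to one channel with no output activation. Scaled-down
#' configurations (e.g. `base_filters = c(8, 16, 32)`) use the same code
#' path.
#'
#' @param n_levels number of resolution levels.
#' @param convs_per_block convolutions per encoder/decoder block.
#' @param base_filters integer vector of channel counts, one per level.
#' @param kernel_size odd convolution kernel edge (voxels).
#' @param norm_groups group-normalization groups; must divide every channel
#'   count.
#' @return A `unet_config` object.
#' @export
unet_config <- function(n_levels = 3L, convs_per_block = 3L,
                        base_filters = c(32L, 64L, 128L),
                        kernel_size = 3L, norm_groups = 8L) {
  n_levels <- as.integer(n_levels)
  base_filters <- as.integer(base_filters)
  if (length(base_filters) != n_levels)
    stop("base_filters must have one entry per level")
  if (kernel_size != 3L)
    stop("kernel_size is fixed at 3 (same-padded) in this implementation")
  if (any(base_filters %% as.integer(norm_groups) != 0L))
    stop("every channel count must be divisible by norm_groups")
  structure(list(n_levels = n_levels,
                 convs_per_block = as.integer(convs_per_block),
                 base_filters = base_filters,
                 kernel_size = as.integer(kernel_size),
                 norm_groups = as.integer(norm_groups)),
            class = "unet_config")
}

#' Build (initialize) a U-net model
#'
#' Deterministic He-style initialization under a fixed seed: convolution
#' weights are drawn N(0, 2/fan_in), biases and group-norm shifts start at
#' zero, group-norm scales at one, and PReLU slopes at 0.25. The final
#' 1x1x1 convolution starts small (untrained output RMS near the 0.1
#' working noise scale) so the early mean-absolute-error descent on
#' sparse masked targets is well-scaled.
#'
#' @param config a [unet_config].
#' @param seed integer seed controlling the initialization.
#' @return A `unet_model` (config + named parameter list).
#' @export
build_model <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  shapes <- cpp_param_shapes(unclass(config))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  params <- vector("list", length(shapes))
  names(params) <- names(shapes)
  for (i in seq_along(shapes)) {
    d <- shapes[[i]][1:2]      # (rows, cols); third entry is the fan-in
    fan_in <- shapes[[i]][3]
    nm <- names(shapes)[i]
    params[[i]] <- array(
      if (grepl("_gamma$", nm)) rep(1, prod(d))
      else if (grepl("_a$", nm)) rep(0.25, prod(d))
      else if (grepl("(_b$|_beta$)", nm)) rep(0, prod(d))
      else if (nm == "final_W")
        # small init: untrained output RMS ~ the 0.1 working noise scale,
        # keeping early MAE descent on sparse masked targets well-scaled
        stats::rnorm(prod(d), 0, 0.1 / sqrt(fan_in))
      else stats::rnorm(prod(d), 0, sqrt(2 / fan_in)),
      dim = d)
  }
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %d levels, filters %s, %s parameters\n",
              x$config$n_levels,
              paste(x$config$base_filters, collapse = "/"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `unet_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' Forward pass of the U-net
#'
#' Evaluation-mode forward pass (group normalization has no train/eval
#' distinction, so this is the only mode). Deterministic: repeated calls on
#' the same weights and input are identical, and each sample in a batch is
#' processed independently.
#'
#' @param model a `unet_model`.
#' @param cubes either a single 3-d array, a list of 3-d arrays, or a 4-d
#'   array (x, y, z, batch). All spatial dimensions must be divisible by
#'   `2^(n_levels - 1)`.
#' @return Predictions in the same form as the input.
#' @export
forward <- function(model, cubes) {
  stopifnot(inherits(model, "unet_model"))
  if (any(!vapply(model$params, function(p) all(is.finite(p)), logical(1))))
    stop("model weights contain non-finite values")
  single <- is.array(cubes) && length(dim(cubes)) == 3L
  aslist <- is.list(cubes)
  x <- if (single) array(cubes, dim = c(dim(cubes), 1L))
       else if (aslist) {
         d <- dim(cubes[[1]])
         array(unlist(cubes, use.names = FALSE), dim = c(d, length(cubes)))
       } else cubes
  if (length(dim(x)) != 4L) stop("cubes must be 3-d, a list of 3-d, or 4-d")
  div <- 2^(model$config$n_levels - 1L)
  if (any(dim(x)[1:3] %% div != 0))
    stop("spatial dimensions must be divisible by ", div)
  y <- cpp_unet_forward(model$params, unclass(model$config), x)
  if (single) array(y, dim = dim(cubes))
  else if (aslist) lapply(seq_len(dim(y)[4]),
                          function(i) array(y[, , , i], dim = dim(x)[1:3]))
  else y
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS container holding the weights and
#' configuration; a JSON sidecar (`<path>.json`) records the configuration
#' and package version for cross-version inspection.
#'
#' @param model a `unet_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$config),
                  package_version = as.character(utils::packageVersion("emrestore")),
                  n_parameters = count_parameters(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) stop("not a unet_model checkpoint")
  model
}
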