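#' Inference configuration
#'
#' @param cube_size network cube edge in voxels (default 64).
#' @param stride stride between overlapping inference cubes (default 16).
#' @param batch_size cubes per forward pass.
#' @param output_scale `"normalized"` (the network's target scale, the
#'   default) or `"denormalized"` (mapped back through the recorded noise
#'   normalization to input-comparable intensities).
#' @param working_voxel working sampling in A/voxel.
#' @return An `inference_config` object.
#' @export
inference_config <- function(cube_size = 64L, stride = 16L, batch_size = 8L,
                             output_scale = c("normalized", "denormalized"),
                             working_voxel = 1.0) {
  if (stride > cube_size) stop("stride must be <= cube_size")
  structure(list(cube_size = as.integer(cube_size),
                 stride = as.integer(stride),
                 batch_size = as.integer(batch_size),
                 output_scale = match.arg(output_scale),
                 working_voxel = working_voxel),
            class = "inference_config")
}

run_model_on_cubes <- function(model, cubes, batch_size) {
  out <- vector("list", length(cubes))
  i <- 1L
  while (i <= length(cubes)) {
    j <- min(i + batch_size - 1L, length(cubes))
    x <- stack_cubes(cubes[i:j])
    y <- if (inherits(model, "unet_model")) {
      cpp_unet_forward(model$params, unclass(model$config), x)
    } else if (is.function(model)) {
      model(x)
    } else stop("model must be a unet_model or a function on 4-d batches")
    for (k in i:j) out[[k]] <- array(y[, , , k - i + 1L], dim = dim(x)[1:3])
    i <- j + 1L
  }
  out
}

#' Post-process a cryo-EM map
#'
#' The full restoration chain: optional half-map averaging, resampling to
#' the 1 A/voxel working grid, noise-statistics normalization, extraction
#' of overlapping cubes, per-cube network prediction, overlap-averaged
#' reassembly, and resizing back to the original grid. Deterministic:
#' fixed weights and input give identical output.
#'
#' @param input a [density_map], or a list of two half [density_map]s
#'   which are averaged first.
#' @param model a `unet_model`, or (chiefly for testing) a function taking
#'   a 4-d `(x, y, z, batch)` array to an equal-shaped array.
#' @param config an [inference_config].
#' @return The processed [density_map] (shape and voxel size of the
#'   original input) with processing metadata in attribute `"provenance"`.
#' @export
postprocess_map <- function(input, model, config = inference_config()) {
  stopifnot(inherits(config, "inference_config"))
  if (is.list(input) && !is_density_map(input)) {
    if (length(input) != 2L) stop("expected two half maps")
    input <- average_half_maps(input[[1]], input[[2]])
  }
  stopifnot(is_density_map(input))
  rs <- resample_to_working_grid(input, config$working_voxel)
  nstats <- estimate_noise_stats(rs$map)
  norm <- normalize_map(rs$map, nstats)
  grid <- plan_chunks(dim(norm$data), config$cube_size, config$stride)
  cubes <- extract_chunks(norm, grid, pad_value = nstats$target_mean)
  preds <- run_model_on_cubes(model, cubes, config$batch_size)
  assembled <- assemble_chunks(preds, grid)
  working <- density_map(assembled, voxel_size = config$working_voxel,
                         origin = norm$origin)
  if (identical(config$output_scale, "denormalized"))
    working <- denormalize_map(working, nstats)
  out <- resize_to_original(working, rs$record)
  attr(out, "provenance") <- list(
    normalization = nstats,
    n_chunks = nrow(grid$origins),
    cube_size = config$cube_size, stride = config$stride,
    checkpoint_seed = if (inherits(model, "unet_model")) model$seed else NA,
    resample = rs$record)
  out
}

#' Post-process a batch of map files
#'
#' Failures are isolated per map: remaining maps are still processed and
#' the failure is recorded in the manifest.
#'
#' @param paths character vector of input MRC paths, or a list whose
#'   elements are either one path or a pair of half-map paths.
#' @param model as in [postprocess_map()].
#' @param config an [inference_config].
#' @param out_dir output directory (created if needed).
#' @return List: `outputs` (paths or NA), `manifest` (data.frame with
#'   status, error message, normalization stats) and `n_failed`.
#' @export
postprocess_batch <- function(paths, model, config = inference_config(),
                              out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.list(paths)) paths <- as.list(paths)
  rows <- vector("list", length(paths))
  outs <- rep(NA_character_, length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    base <- tools::file_path_sans_ext(basename(p[[1]]))
    res <- tryCatch({
      input <- if (length(p) == 2L) list(read_map(p[[1]]), read_map(p[[2]]))
               else read_map(p[[1]])
      out <- postprocess_map(input, model, config)
      op <- file.path(out_dir, paste0(base, "_processed.mrc"))
      write_map(out, op)
      pv <- attr(out, "provenance")
      list(path = op, err = NA_character_,
           noise_mean = pv$normalization$noise_mean,
           noise_std = pv$normalization$noise_std,
           ckpt = pv$checkpoint_seed)
    }, error = function(e) list(path = NA_character_,
                                err = conditionMessage(e),
                                noise_mean = NA_real_, noise_std = NA_real_,
                                ckpt = NA))
    outs[i] <- res$path
    rows[[i]] <- data.frame(input = p[[1]], output = res$path,
                            status = if (is.na(res$err)) "ok" else "failed",
                            error = res$err, noise_mean = res$noise_mean,
                            noise_std = res$noise_std,
                            checkpoint_seed = res$ckpt)
  }
  manifest <- do.call(rbind, rows)
  n_failed <- sum(manifest$status == "failed")
  if (n_failed == length(paths)) stop("all maps failed to process")
  utils::write.csv(manifest, file.path(out_dir, "process_manifest.csv"),
                   row.names = FALSE)
  list(outputs = outs, manifest = manifest, n_failed = n_failed)
}
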