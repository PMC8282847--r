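#' Build paired training cubes from map records
#'
#' For every record the input map is resampled to the working grid and
#' noise-normalized, the target is percentile-normalized under its mask,
#' and both are chunked on the same grid. Cubes are classified by in-mask
#' voxel fraction: cubes with at least `signal_frac` mask coverage are
#' signal cubes; noise-only cubes are retained but subsampled so they make
#' up at most `noise_cap` of the final set.
#'
#' @param records list of records as produced by [generate_dataset()]
#'   (fields `full`, `target`, `mask`, `id`).
#' @param cube_size,stride chunking parameters (training default:
#'   stride 32, i.e. 50\% overlap).
#' @param signal_frac minimum in-mask fraction for a signal cube.
#' @param noise_cap maximum fraction of noise-only cubes in the set.
#' @param seed seed for the noise-cube subsampling.
#' @return List of `list(input, target, map_id, signal_frac)` cube pairs.
#' @export
prepare_training_cubes <- function(records, cube_size = 64L, stride = 32L,
                                   signal_frac = 0.01, noise_cap = 0.2,
                                   seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sig <- list()
  noi <- list()
  for (rec in records) {
    rs <- resample_to_working_grid(rec$full)
    nstats <- estimate_noise_stats(rs$map)
    input <- normalize_map(rs$map, nstats)
    target <- normalize_target(rec$target, rec$mask)
    grid <- plan_chunks(dim(input$data), cube_size, stride)
    in_cubes <- extract_chunks(input, grid, pad_value = 0)
    tg_cubes <- extract_chunks(target, grid, pad_value = 0)
    sf <- chunk_signal_fraction(rec$mask, grid)
    for (i in seq_along(in_cubes)) {
      pair <- list(input = in_cubes[[i]], target = tg_cubes[[i]],
                   map_id = rec$id, signal_frac = sf[i])
      if (sf[i] >= signal_frac) sig[[length(sig) + 1L]] <- pair
      else noi[[length(noi) + 1L]] <- pair
    }
  }
  n_keep <- min(length(noi),
                floor(noise_cap / (1 - noise_cap) * length(sig)))
  if (n_keep > 0) {
    keep <- sample.int(length(noi), n_keep)
    out <- c(sig, noi[keep])
  } else out <- sig
  if (length(out) == 0L) stop("no training cubes produced")
  out
}

#' Crop random sub-cubes from training pairs
#'
#' Fully convolutional training does not require the inference cube size;
#' smaller random crops (applied identically to input and target) give
#' more, cheaper gradient steps per map.
#'
#' @param pairs cube pairs from [prepare_training_cubes()].
#' @param crop_size crop edge in voxels (must divide the network's
#'   downsampling factor).
#' @param n_per_cube random crops drawn from each pair.
#' @param min_signal_frac when positive, crops are rejection-sampled (up
#'   to `max_tries` draws) until at least this fraction of their voxels is
#'   inside the target support, biasing supervision toward the molecule.
#' @param max_tries rejection-sampling budget per crop; the best draw so
#'   far is kept when the budget is exhausted.
#' @param seed RNG seed.
#' @return A list of cropped pairs.
#' @export
crop_training_pairs <- function(pairs, crop_size = 32L, n_per_cube = 1L,
                                min_signal_frac = 0, max_tries = 20L,
                                seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  out <- list()
  for (p in pairs) {
    d <- dim(p$input)
    if (any(d < crop_size)) stop("crop_size larger than cube")
    for (j in seq_len(n_per_cube)) {
      best <- NULL
      best_sf <- -1
      for (try in seq_len(max(1L, max_tries))) {
        o <- vapply(d, function(n) sample.int(n - crop_size + 1L, 1L),
                    integer(1))
        ix <- o[1]:(o[1] + crop_size - 1L)
        iy <- o[2]:(o[2] + crop_size - 1L)
        iz <- o[3]:(o[3] + crop_size - 1L)
        tg <- p$target[ix, iy, iz]
        sf <- mean(tg > 1e-8)
        if (sf > best_sf) {
          best_sf <- sf
          best <- list(input = p$input[ix, iy, iz], target = tg,
                       map_id = p$map_id, signal_frac = sf)
        }
        if (sf >= min_signal_frac) break
      }
      out[[length(out) + 1L]] <- best
    }
  }
  out
}
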