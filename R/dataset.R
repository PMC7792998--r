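#' Generate a training corpus of simulated diffraction patterns
#'
#' Draws `n` random particles, forms each 2D pattern as the central slice of
#' the 3D diffraction intensity (computed equivalently, via the Fourier slice
#' theorem, as the 2D diffraction of the complex projection), and pairs it
#' with the ground-truth projected amplitude and scaled phase on the central
#' `n_det/2` crop. The phase target uses the fixed affine map
#' `(phi + pi) / (2*pi)` into `[0, 1]` and is zero outside the projected
#' particle support. Samples are split into disjoint train / validation sets.
#'
#' @param n Number of samples (>= 1).
#' @param config A [simulator_config()].
#' @param seed Integer master seed; per-sample seeds derive from it, so the
#'   corpus is a pure function of (n, config, seed).
#' @param train_frac Training fraction of the split (default 0.95).
#' @param axis Projection / slice axis.
#' @return A `cdi_dataset`: `samples` (each with `pattern`,
#'   `target_amplitude`, `target_phase_scaled`, `provenance`), `split`
#'   (`train`, `validation` index vectors), `meta`.
#' @export
make_dataset <- function(n, config = simulator_config(), seed = 1L,
                         train_frac = 0.95, axis = "z") {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (train_frac <= 0 || train_frac > 1) stop("train_frac must be in (0, 1]")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  samples <- lapply(seq_len(n), function(i) {
    make_training_sample(config, seeds[i], axis = axis)
  })
  n_train <- max(1L, floor(train_frac * n))
  ord <- with_seed(seed + 1L, sample.int(n))
  split <- list(train = sort(ord[seq_len(n_train)]),
                validation = sort(ord[-seq_len(n_train)]))
  structure(list(samples = samples, split = split,
                 meta = list(grid = config$grid, config = config, seed = seed,
                             train_frac = train_frac, axis = axis)),
            class = "cdi_dataset")
}

make_training_sample <- function(config, seed, axis = "z", phase_floor = 0.05) {
  p <- sample_random_particle(config, seed)
  pr <- project_object(p$object, axis = axis, phase_floor = phase_floor)
  pattern <- diffract_2d(pr$field)
  amp <- pr$image$amplitude
  mask <- amp >= phase_floor * max(amp)
  scaled <- (pr$image$phase + pi) / (2 * pi)
  scaled[!mask] <- 0
  list(pattern = pattern,
       target_amplitude = amp,
       target_phase_scaled = scaled,
       provenance = p$provenance)
}

#' @export
print.cdi_dataset <- function(x, ...) {
  cat(sprintf("<cdi_dataset> %d samples (%d train / %d validation), grid %d, seed %d\n",
              length(x$samples), length(x$split$train), length(x$split$validation),
              x$meta$grid$n_obj, x$meta$seed))
  invisible(x)
}

#' Provenance table of a dataset
#'
#' One row per sample: sampled superellipsoid parameters, correlation
#' lengths, orientation quaternion, seed, and split membership.
#'
#' @param dataset A `cdi_dataset`.
#' @return A tibble.
#' @export
dataset_provenance <- function(dataset) {
  rows <- lapply(seq_along(dataset$samples), function(i) {
    pv <- dataset$samples[[i]]$provenance
    tibble::tibble(sample = i,
                   a = pv$shape$a, b = pv$shape$b, c = pv$shape$c,
                   e = pv$shape$e, n = pv$shape$n,
                   L_x = pv$phase$L_x, L_y = pv$phase$L_y, L_z = pv$phase$L_z,
                   qw = pv$orientation[1], qx = pv$orientation[2],
                   qy = pv$orientation[3], qz = pv$orientation[4],
                   seed = pv$seed,
                   split = if (i %in% dataset$split$train) "train" else "validation")
  })
  do.call(rbind, rows)
}

#' Serialize / restore datasets, models and reconstructions
#'
#' Native R serialization (version 3 RDS). Groups mirror the in-memory
#' structure: patterns, target amplitude / scaled phase stacks, per-sample
#' provenance, and the split and meta records.
#'
#' @param x Object to write.
#' @param path File path.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly (`write_cdi`); the restored object (`read_cdi`).
#' @export
write_cdi <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("output file exists: ", path, " (use force = TRUE to overwrite)")
  }
  saveRDS(x, path, version = 3)
  invisible(path)
}

#' @rdname write_cdi
#' @export
read_cdi <- function(path) readRDS(path)
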