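#' Superellipsoid parameters
#'
#' Implicit solid `((|x/a|^(2/e) + |y/b|^(2/e))^(e/n) + |z/c|^(2/n)) <= 1`
#' (Barr form). `a`, `b`, `c` bound the solid along x, y, z; `e` and `n` are
#' the equatorial and meridional roundedness exponents. `e = n = 1` gives the
#' ellipsoid (a sphere when `a = b = c`); `e = n = 2` gives the octahedron
#' `|x/a| + |y/b| + |z/c| <= 1`.
#'
#' @param a,b,c Semi-axes in voxels (positive).
#' @param e,n Roundedness exponents (positive).
#' @return A `superellipsoid_params` object.
#' @export
superellipsoid_params <- function(a, b, c, e = 1, n = 1) {
  if (any(c(a, b, c) <= 0)) stop("semi-axes a, b, c must be positive")
  if (any(c(e, n) <= 0)) stop("roundedness exponents e, n must be positive")
  structure(list(a = a, b = b, c = c, e = e, n = n),
            class = "superellipsoid_params")
}

#' Gaussian-correlated phase-field parameters
#'
#' The interior phase is a Gaussian random field built by convolving
#' uncorrelated Gaussian white noise with the separable kernel
#' `exp(-x^2/L_x^2 - y^2/L_y^2 - z^2/L_z^2)`, then affinely rescaling so the
#' field spans `phase_span` radians centered on zero. The field
#' autocorrelation of the result is Gaussian with 1/e half-width
#' `sqrt(2) * L` along each axis.
#'
#' @param L_x,L_y,L_z Transverse correlation lengths in voxels (positive).
#' @param phase_span Target full span of the phase in radians, in (0, 2*pi].
#'   The default 2*pi is the strong-phase regime.
#' @return A `phase_field_params` object.
#' @export
phase_field_params <- function(L_x = 8, L_y = 8, L_z = 8, phase_span = 2 * pi) {
  if (any(c(L_x, L_y, L_z) <= 0)) stop("correlation lengths must be positive")
  if (phase_span <= 0 || phase_span > 2 * pi + 1e-12) {
    stop("phase_span must be in (0, 2*pi], got ", phase_span)
  }
  structure(list(L_x = L_x, L_y = L_y, L_z = L_z, phase_span = phase_span),
            class = "phase_field_params")
}

#' Voxelize a superellipsoid on the object grid
#'
#' Evaluates the implicit superellipsoid inequality on the centered voxel
#' lattice. The shape must fit inside the central `n_obj/2` cube so that any
#' rotation keeps the particle within the oversampling support.
#'
#' @param grid A [grid_spec()].
#' @param params A [superellipsoid_params()].
#' @return 3D 0/1 array of dimension `c(n_obj, n_obj, n_obj)`.
#' @examples
#' g <- grid_spec(32)
#' m <- voxelize_superellipsoid(g, superellipsoid_params(6, 6, 6, e = 1, n = 1))
#' sum(m)  # approximately (4/3) * pi * 6^3
#' @export
voxelize_superellipsoid <- function(grid, params) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "superellipsoid_params"))
  lim <- grid$n_obj / 4
  for (ax in c("a", "b", "c")) {
    if (params[[ax]] > lim) {
      stop("semi-axis ", ax, " = ", params[[ax]], " exceeds n_obj/4 = ", lim,
           "; the particle would leave the central half-cube under rotation")
    }
  }
  n <- grid$n_obj
  ax <- grid_axis(n)
  e <- params$e; nn <- params$n
  # separable accumulation of ((|x/a|^(2/e)+|y/b|^(2/e))^(e/n) + |z/c|^(2/n))
  fx <- abs(ax / params$a)^(2 / e)
  fy <- abs(ax / params$b)^(2 / e)
  fz <- abs(ax / params$c)^(2 / nn)
  xy <- outer(fx, fy, `+`)^(e / nn)
  f <- outer(xy, rep(1, n)) + outer(matrix(1, n, n), fz)
  array(as.numeric(f <= 1), dim = c(n, n, n))
}

#' Sample a Gaussian-correlated 3D phase field
#'
#' White noise is convolved (via FFT, periodic boundaries) with the separable
#' Gaussian kernel, then affinely rescaled so the field's minimum and maximum
#' map to `-phase_span/2` and `+phase_span/2`. Over the particle interior the
#' realized span approaches `phase_span` as the particle volume grows.
#'
#' @param grid A [grid_spec()].
#' @param params A [phase_field_params()].
#' @param seed Integer seed; the field is a pure function of (grid, params, seed).
#' @return 3D real array, values in `[-phase_span/2, phase_span/2]`.
#' @export
sample_phase_field <- function(grid, params, seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "phase_field_params"))
  n <- grid$n_obj
  with_seed(seed, {
    z <- array(rnorm(n^3), dim = c(n, n, n))
    ax <- c(0:(n %/% 2L), -(n %/% 2L - 1L):-1L)  # fft-ordered coordinates
    kx <- exp(-ax^2 / params$L_x^2)
    ky <- exp(-ax^2 / params$L_y^2)
    kz <- exp(-ax^2 / params$L_z^2)
    kern <- outer(outer(kx, ky), kz)
    f <- Re(fft(fft(z) * fft(kern), inverse = TRUE)) / n^3
    lo <- min(f); hi <- max(f)
    if (hi - lo < .Machine$double.eps) stop("degenerate phase field")
    (f - lo) / (hi - lo) * params$phase_span - params$phase_span / 2
  })
}

#' Assemble a complex object from a shape mask and a phase field
#'
#' The amplitude is the (optionally Gaussian-smoothed) shape mask renormalized
#' to maximum 1; smoothing emulates the soft particle boundary applied before
#' the Fourier transform. The phase is the field masked to the particle
#' (exactly zero wherever the amplitude is zero). Smoothing acts on the
#' amplitude only; the phase is already smooth by construction.
#'
#' @param mask 3D 0/1 array from [voxelize_superellipsoid()].
#' @param phase_field 3D real array from [sample_phase_field()] (same shape).
#' @param sigma Edge-smoothing Gaussian sd in voxels (default 1; 0 disables).
#' @param grid A [grid_spec()] consistent with the arrays.
#' @return A `complex_object` (list with 3D `amplitude`, 3D `phase`, `grid`).
#' @export
assemble_object <- function(mask, phase_field, sigma = 1, grid = NULL) {
  stopifnot(identical(dim(mask), dim(phase_field)))
  if (sum(mask) == 0) stop("empty shape mask: no voxels inside the particle")
  n <- dim(mask)[1]
  if (is.null(grid)) grid <- grid_spec(n)
  amp <- if (sigma > 0) gaussian_blur(mask, sigma) else mask
  amp <- pmax(amp, 0)
  # confine to the central half-cube exactly (smoothing tails are negligible
  # there by construction: semi-axes <= n/4 leave a >= n/4 margin)
  half <- half_cube_mask(n)
  amp <- amp * half
  amp <- amp / max(amp)
  phase <- phase_field * (mask * half)
  phase[amp == 0] <- 0
  new_complex_object(amp, phase, grid)
}

half_cube_mask <- function(n) {
  ax <- grid_axis(n)
  inside <- as.numeric(ax >= -(n / 4) & ax < n / 4)
  outer(outer(inside, inside), inside)
}

new_complex_object <- function(amplitude, phase, grid) {
  structure(list(amplitude = amplitude, phase = phase, grid = grid),
            class = "complex_object")
}

#' @export
print.complex_object <- function(x, ...) {
  cat(sprintf("<complex_object> %d^3 grid, %d nonzero voxels, phase span [%.3f, %.3f]\n",
              x$grid$n_obj, sum(x$amplitude > 0),
              min(x$phase[x$amplitude > 0]), max(x$phase[x$amplitude > 0])))
  invisible(x)
}

#' Uniform random orientation as a unit quaternion
#'
#' Shoemake's subgroup algorithm: three uniform deviates give an exactly
#' uniform draw from SO(3).
#'
#' @param seed Integer seed (optional).
#' @return Numeric length-4 unit quaternion `(w, x, y, z)`.
#' @export
random_orientation <- function(seed = NULL) {
  with_seed(seed, {
    u <- runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    q / sqrt(sum(q^2))
  })
}

quaternion_matrix <- function(q) {
  if (abs(sqrt(sum(q^2)) - 1) > 1e-12) stop("quaternion must have unit norm")
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Rotate a complex object in 3D
#'
#' Amplitude and phase are resampled identically by trilinear interpolation
#' under the rotation given by a unit quaternion (inverse mapping, zero fill
#' outside the grid). Lattice-preserving rotations (e.g. 90 degree turns about
#' a grid axis) are exact. The phase is re-masked so zero amplitude implies
#' zero phase.
#'
#' @param obj A `complex_object`.
#' @param q Unit quaternion `(w, x, y, z)`.
#' @return Rotated `complex_object`.
#' @export
rotate_object <- function(obj, q) {
  stopifnot(inherits(obj, "complex_object"))
  R <- quaternion_matrix(q)
  n <- obj$grid$n_obj
  ax <- grid_axis(n)
  co <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  src <- co %*% R  # inverse map: R^T applied as row-vector product
  amp <- trilinear(obj$amplitude, src, ax)
  ph <- trilinear(obj$phase, src, ax)
  amp <- array(amp, dim = c(n, n, n))
  ph <- array(ph, dim = c(n, n, n))
  amp[amp < 0] <- 0
  ph[amp == 0] <- 0
  new_complex_object(amp, ph, obj$grid)
}

# Vectorized trilinear interpolation of a 3D array at points `src` (rows =
# (x,y,z) in centered coordinates); zero outside the grid.
trilinear <- function(arr, src, ax) {
  n <- length(ax)
  off <- n %/% 2L + 1L  # centered coord 0 -> index off
  gx <- src[, 1] + off; gy <- src[, 2] + off; gz <- src[, 3] + off
  x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  val <- numeric(nrow(src))
  get3 <- function(i, j, k) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n & k >= 1 & k <= n
    v <- numeric(length(i))
    idx <- (k[ok] - 1) * n * n + (j[ok] - 1) * n + i[ok]
    v[ok] <- arr[idx]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      val[nz] <- val[nz] +
        w[nz] * get3(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
    }
  }
  val
}

#' Simulator configuration: parameter sampling ranges
#'
#' Ranges from which [sample_random_particle()] draws uniformly. Semi-axes are
#' in voxels and capped at `n_obj/4` so any orientation stays inside the
#' oversampling half-cube.
#'
#' @param grid A [grid_spec()].
#' @param axis_range Range for each semi-axis a, b, c in voxels.
#' @param e_range,n_range Ranges for the roundedness exponents.
#' @param L_range Range for each phase correlation length in voxels.
#' @param phase_span Full interior phase span in radians (default 2*pi,
#'   the strong-phase regime).
#' @param sigma Edge-smoothing sd in voxels.
#' @return A `simulator_config` list.
#' @export
simulator_config <- function(grid = grid_spec(64),
                             axis_range = c(4, grid$n_obj / 4),
                             e_range = c(0.5, 3),
                             n_range = c(0.5, 3),
                             L_range = c(2, 16),
                             phase_span = 2 * pi,
                             sigma = 1) {
  for (r in list(axis_range, e_range, n_range, L_range)) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) stop("invalid sampling range")
  }
  if (axis_range[2] > grid$n_obj / 4) {
    stop("axis_range upper bound exceeds n_obj/4 = ", grid$n_obj / 4)
  }
  structure(list(grid = grid, axis_range = axis_range, e_range = e_range,
                 n_range = n_range, L_range = L_range,
                 phase_span = phase_span, sigma = sigma),
            class = "simulator_config")
}

#' Draw one random particle
#'
#' Samples superellipsoid shape parameters, a correlated phase field and a
#' uniform 3D orientation from the configured ranges, then voxelizes,
#' assembles and rotates the complex object. Deterministic given the seed.
#'
#' @param config A [simulator_config()].
#' @param seed Integer seed.
#' @return List with `object` (a `complex_object`) and `provenance` (the
#'   sampled parameters, orientation quaternion and seed).
#' @export
sample_random_particle <- function(config, seed) {
  stopifnot(inherits(config, "simulator_config"))
  with_seed(seed, {
    ab <- runif(3, config$axis_range[1], config$axis_range[2])
    e <- runif(1, config$e_range[1], config$e_range[2])
    nn <- runif(1, config$n_range[1], config$n_range[2])
    L <- runif(3, config$L_range[1], config$L_range[2])
    q <- {
      u <- runif(3)
      v <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
             sqrt(1 - u[1]) * cos(2 * pi * u[2]),
             sqrt(u[1]) * sin(2 * pi * u[3]),
             sqrt(u[1]) * cos(2 * pi * u[3]))
      v / sqrt(sum(v^2))
    }
    sp <- superellipsoid_params(ab[1], ab[2], ab[3], e, nn)
    pp <- phase_field_params(L[1], L[2], L[3], config$phase_span)
    mask <- voxelize_superellipsoid(config$grid, sp)
    field <- sample_phase_field(config$grid, pp, seed = NULL)  # inherits stream
    obj <- assemble_object(mask, field, sigma = config$sigma, grid = config$grid)
    obj <- rotate_object(obj, q)
    # re-impose the oversampling confinement: low-roundedness shapes at the
    # semi-axis cap (and the smoothing skirt) can poke corners out of the
    # half-cube under rotation; the clipped mass is negligible
    half <- half_cube_mask(config$grid$n_obj)
    obj$amplitude <- obj$amplitude * half
    obj$phase[obj$amplitude == 0] <- 0
    obj$amplitude <- obj$amplitude / max(obj$amplitude)
    list(object = obj,
         provenance = list(shape = sp, phase = pp, orientation = q, seed = seed))
  })
}
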