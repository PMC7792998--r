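#' Grid specification for object and detector arrays
#'
#' The simulation operates on a cubic 3D object grid of `n_obj` voxels per
#' dimension and a square 2D detector grid of `n_det` pixels per dimension.
#' Keeping `n_det == n_obj` while confining the particle to the central
#' `n_obj/2` cube realizes linear oversampling >= 2 in every dimension, the
#' condition under which the phase problem is well posed. Network targets
#' (amplitude and phase images) live on the central `n_obj/2` crop, so the
#' output is one quarter of the area of the input pattern.
#'
#' @param n_obj Even integer, voxels per dimension of the object grid.
#' @param n_det Even integer, pixels per dimension of the detector grid.
#'   Must equal `n_obj`.
#' @return A `grid_spec` object (list with `n_obj`, `n_det`).
#' @examples
#' g <- grid_spec(64)
#' g$n_det
#' @export
grid_spec <- function(n_obj = 64L, n_det = n_obj) {
  n_obj <- as.integer(n_obj)
  n_det <- as.integer(n_det)
  if (n_obj < 8L || n_obj %% 2L != 0L) {
    stop("n_obj must be an even integer >= 8, got ", n_obj)
  }
  if (n_det != n_obj) {
    stop("n_det must equal n_obj (oversampled square geometry), got n_det = ",
         n_det, ", n_obj = ", n_obj)
  }
  structure(list(n_obj = n_obj, n_det = n_det), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> object %d^3 voxels, detector %d x %d pixels, targets %d x %d\n",
              x$n_obj, x$n_det, x$n_det, x$n_det %/% 2L, x$n_det %/% 2L))
  invisible(x)
}

# Centered coordinate axis for an even-length FFT grid: -n/2 .. n/2-1, with 0
# at index n/2 + 1 (the pixel fftshift maps the zero frequency to).
grid_axis <- function(n) seq_len(n) - (n %/% 2L + 1L)

# Swap half-spaces so the zero-frequency (or object-center) element moves
# between index 1 and index n/2+1. For even n, fftshift and its inverse
# coincide. Works for vectors, matrices and 3D arrays.
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    return(x[c((n %/% 2L + 1L):n, 1:(n %/% 2L))])
  }
  idx <- lapply(d, function(n) c((n %/% 2L + 1L):n, 1:(n %/% 2L)))
  do.call(`[`, c(list(x), idx))
}

ifftshift <- fftshift  # even-sized grids only

# Centered discrete Fourier transforms: zero frequency and object center both
# at index n/2+1. Unnormalized forward; `inverse = TRUE` applies the 1/N
# factor so ifft2c(fft2c(x)) == x.
fft2c <- function(x) fftshift(fft(ifftshift(x)))

ifft2c <- function(x) fftshift(fft(ifftshift(x), inverse = TRUE)) / length(x)

fft3c <- fft2c
ifft3c <- ifft2c

# Run code with a private RNG stream: seeds deterministically, restores the
# caller's .Random.seed afterwards so package functions are pure in (args, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Central n/2 x n/2 crop of an n x n matrix (object-centered convention).
central_crop <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  lo <- n %/% 4L + 1L
  m[lo:(lo + h - 1L), lo:(lo + h - 1L), drop = FALSE]
}

# Embed an h x h matrix centered in an n x n zero frame (inverse of central_crop).
central_embed <- function(m, n) {
  h <- nrow(m)
  out <- matrix(if (is.complex(m)) 0 + 0i else 0, n, n)
  lo <- (n - h) %/% 2L + 1L
  out[lo:(lo + h - 1L), lo:(lo + h - 1L)] <- m
  out
}

# Gaussian low-pass via FFT with transfer function exp(-2 pi^2 sigma^2 f^2);
# equivalent to convolution with a unit-mass Gaussian of sd `sigma` voxels,
# periodic boundaries. Works in 2D and 3D.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  freqs <- lapply(d, function(n) c(0:(n %/% 2L), -(n %/% 2L - 1L):-1L) / n)
  g2 <- 0
  for (k in seq_along(d)) {
    f2 <- freqs[[k]]^2
    shape <- rep(1L, length(d)); shape[k] <- d[k]
    g2 <- g2 + outer_broadcast(f2, shape, d)
  }
  tf <- exp(-2 * pi^2 * sigma^2 * g2)
  Re(fft(fft(x) * tf, inverse = TRUE)) / length(x)
}

# Broadcast a per-axis vector to the full array shape by recycling.
outer_broadcast <- function(v, shape, full_dim) {
  arr <- array(v[slice.index(array(0, full_dim), which(shape > 1L))], full_dim)
  arr
}
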