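#' Normalized chi-squared error between two moduli
#'
#' `chi2 = sum((calc - meas)^2) / sum(meas^2)`. Zero iff the arrays are
#' equal; equals `eps^2` when `calc = meas * (1 + eps)`; invariant under a
#' common rescaling of both arguments.
#'
#' @param calc Calculated (reconstructed) modulus, nonnegative array.
#' @param meas Measured reference modulus, nonnegative array of the same shape.
#' @return Nonnegative scalar.
#' @export
chi2_modulus <- function(calc, meas) {
  if (!identical(dim(calc), dim(meas))) stop("shape mismatch in chi2_modulus")
  denom <- sum(meas^2)
  if (denom == 0) stop("all-zero measured modulus: chi2 undefined")
  sum((calc - meas)^2) / denom
}

#' Real-space chi-squared error of a reconstructed image
#'
#' The same normalized quadratic form as [chi2_modulus()], applied to
#' amplitude or (scaled) phase maps. Iterative reconstructions should be
#' passed through [align_reconstruction()] first — phase retrieval is unique
#' only up to translation, global phase and the conjugate twin — whereas CNN
#' outputs live in the fixed training frame and are compared directly.
#'
#' @param pred Predicted map.
#' @param truth Reference map of the same shape.
#' @return Nonnegative scalar.
#' @export
chi2_real <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch in chi2_real")
  denom <- sum(truth^2)
  if (denom == 0) stop("all-zero reference image: chi2 undefined")
  sum((pred - truth)^2) / denom
}

#' Remove trivial phase-retrieval ambiguities against a reference
#'
#' Given only the Fourier modulus, a reconstruction is determined at best up
#' to (a) integer translation, (b) a global phase offset and (c) the
#' conjugate-inverted twin. This searches all circular translations of both
#' the candidate and its twin, with the optimal global phase at each shift
#' obtained in closed form from the complex cross-correlation (computed by
#' FFT), and returns the candidate minimizing complex L2 distance to the
#' reference.
#'
#' @param recon A `complex_image` or complex matrix.
#' @param truth Reference `complex_image` or complex matrix, same shape.
#' @return A `complex_image` (aligned amplitude and phase).
#' @export
align_reconstruction <- function(recon, truth) {
  zr <- as_complex_matrix(recon)
  zt <- as_complex_matrix(truth)
  if (!identical(dim(zr), dim(zt))) stop("shape mismatch in align_reconstruction")
  best <- NULL
  for (twin in c(FALSE, TRUE)) {
    z <- if (twin) conj_invert(zr) else zr
    # cross-correlation c(s) = sum_r conj(truth(r)) z(r + s) for all shifts
    cc <- fft(fft(z) * Conj(fft(zt)), inverse = TRUE) / length(z)
    # |distance|^2 = sum|z|^2 + sum|t|^2 - 2|c(s)| at the optimal global phase
    score <- Mod(cc)
    ij <- arrayInd(which.max(score), dim(score))
    cand <- list(twin = twin, shift = ij - 1L, corr = cc[ij[1], ij[2]],
                 val = max(score))
    if (is.null(best) || cand$val > best$val) best <- cand
  }
  z <- if (best$twin) conj_invert(zr) else zr
  z <- circ_shift(z, -best$shift)
  phi <- Arg(best$corr)
  z <- z * exp(-1i * phi)
  new_complex_image(Mod(z), Arg(z) * (Mod(z) > 0))
}

as_complex_matrix <- function(x) {
  if (inherits(x, "complex_image")) x$amplitude * exp(1i * x$phase)
  else if (is.matrix(x)) x + 0i
  else stop("expected a complex_image or a matrix")
}

# conjugate twin: complex conjugate of the coordinate-inverted image
# (inversion about the array origin, circularly)
conj_invert <- function(z) {
  n1 <- nrow(z); n2 <- ncol(z)
  Conj(z[c(1L, n1:2L), c(1L, n2:2L)])
}

circ_shift <- function(z, s) {
  n1 <- nrow(z); n2 <- ncol(z)
  i1 <- ((seq_len(n1) - 1L - s[1]) %% n1) + 1L
  i2 <- ((seq_len(n2) - 1L - s[2]) %% n2) + 1L
  z[i1, i2, drop = FALSE]
}

#' Fit a Gamma distribution to an error sample
#'
#' Maximum-likelihood Gamma fit (via [MASS::fitdistr()]); the headline
#' summary of a chi-squared error histogram is the fitted mean
#' `shape * scale`.
#'
#' @param errors Numeric vector of positive errors (>= 10 values).
#' @return A `gamma_fit` object with `shape`, `rate`, `scale`, `mean`, `n`.
#' @export
fit_gamma <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 10) stop("need at least 10 values for a Gamma fit")
  if (any(errors <= 0)) stop("Gamma fit requires strictly positive errors")
  if (sd(errors) < .Machine$double.eps * max(errors)) {
    stop("degenerate (constant) error sample: Gamma fit is ill-posed")
  }
  f <- MASS::fitdistr(errors, "gamma")
  shape <- unname(f$estimate["shape"]); rate <- unname(f$estimate["rate"])
  structure(list(shape = shape, rate = rate, scale = 1 / rate,
                 mean = shape / rate, n = length(errors), fit = f),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> shape %.4g, scale %.4g, mean %.4g (n = %d)\n",
              x$shape, x$scale, x$mean, x$n))
  invisible(x)
}

#' @rdname fit_gamma
#' @param x A `gamma_fit`.
#' @param ... Unused.
#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    std.error = as.numeric(x$fit$sd[c("shape", "rate")]) *
      c(1, 1 / x$rate^2)  # delta method for scale = 1/rate
  )
}

#' @rdname fit_gamma
#' @export
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(mean = x$mean, shape = x$shape, scale = x$scale,
                 logLik = as.numeric(x$fit$loglik), nobs = x$n)
}

#' Unwrap a 2D wrapped phase map
#'
#' Reliability-ordered region-growing unwrapping: pixels are joined across
#' edges in decreasing reliability (low local second differences first), each
#' join adding the integer multiple of 2*pi that makes the two regions
#' consistent. The output differs from the input by exact multiples of 2*pi
#' at every pixel inside the mask, so rewrapping reproduces the input
#' bit-for-bit up to that congruence. Residue-carrying fields are unwrapped
#' best effort.
#'
#' @param phase 2D phase map in radians (wrapped to (-pi, pi]).
#' @param mask Optional 0/1 matrix; only pixels inside are unwrapped (others
#'   returned unchanged).
#' @return Unwrapped phase matrix (equal to `phase + 2*pi*k`, integer `k`).
#' @export
unwrap_phase_2d <- function(phase, mask = NULL) {
  if (is.null(mask)) mask <- matrix(1, nrow(phase), ncol(phase))
  storage.mode(phase) <- "double"
  k <- unwrap2d_cpp(phase, matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  phase + 2 * pi * k
}

#' Wrap a phase map into (-pi, pi]
#' @param phase Phase in radians.
#' @return Wrapped phase.
#' @export
wrap_phase <- function(phase) {
  w <- (phase + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
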