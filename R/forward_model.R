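#' Complex field of an object
#'
#' @param obj A `complex_object`.
#' @return 3D complex array `amplitude * exp(i * phase)`.
#' @export
object_field <- function(obj) {
  stopifnot(inherits(obj, "complex_object"))
  obj$amplitude * exp(1i * obj$phase)
}

#' 3D diffraction intensity of a complex object
#'
#' The far-field intensity is the modulus squared of the (centered,
#' unnormalized) 3D discrete Fourier transform of the complex field
#' `s(r) exp(i phi(r))`. Zero frequency sits at index `n/2 + 1` along each
#' axis, the detector-image convention.
#'
#' @param obj A `complex_object`.
#' @return 3D nonnegative array of dimension `c(n, n, n)`.
#' @export
diffract_3d <- function(obj) {
  F <- fft3c(object_field(obj))
  Mod(F)^2
}

#' Central slice of a 3D intensity
#'
#' The zero-frequency plane perpendicular to the chosen axis, i.e. the plane
#' a flat-Ewald-sphere 2D detector records through the center of the peak.
#'
#' @param I 3D intensity array (zero-frequency centered).
#' @param axis One of "x", "y", "z": the normal of the slice plane.
#' @return A `diffraction_pattern` (n x n intensity matrix).
#' @export
central_slice <- function(I, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  n <- dim(I)[1]
  c0 <- n %/% 2L + 1L
  sl <- switch(axis,
    x = I[c0, , ],
    y = I[, c0, ],
    z = I[, , c0]
  )
  new_diffraction_pattern(sl)
}

new_diffraction_pattern <- function(intensity) {
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("diffraction intensity must be finite and nonnegative")
  }
  structure(list(intensity = intensity), class = "diffraction_pattern")
}

#' @export
print.diffraction_pattern <- function(x, ...) {
  n <- nrow(x$intensity)
  cat(sprintf("<diffraction_pattern> %d x %d, total intensity %.4g\n",
              n, n, sum(x$intensity)))
  invisible(x)
}

#' Complex projection of an object along a grid axis
#'
#' Line-sum of the complex field `s exp(i phi)` along the axis. By the Fourier
#' slice theorem, the 2D diffraction of this projection equals the central
#' slice of the 3D diffraction intensity perpendicular to the same axis —
#' which is why the projection (not an object slice) is the well-defined 2D
#' ground truth paired with a central-slice pattern.
#'
#' @param obj A `complex_object`.
#' @param axis One of "x", "y", "z".
#' @param phase_floor Relative amplitude below which the projected phase is
#'   set to zero (the projected support mask). Near-zero projected amplitude
#'   carries numerically meaningless phase.
#' @return List with `field` (full n x n complex projection) and `image`
#'   (a `complex_image`: amplitude renormalized to max 1 and masked phase on
#'   the central n/2 crop).
#' @export
project_object <- function(obj, axis = c("z", "x", "y"), phase_floor = 0.05) {
  axis <- match.arg(axis)
  f <- object_field(obj)
  proj <- switch(axis,
    x = apply(f, c(2, 3), sum),
    y = apply(f, c(1, 3), sum),
    z = apply(f, c(1, 2), sum)
  )
  amp <- Mod(proj)
  mx <- max(amp)
  if (mx == 0) stop("empty projection")
  ph <- Arg(proj)
  ph[amp < phase_floor * mx] <- 0
  img <- new_complex_image(central_crop(amp / mx), central_crop(ph))
  list(field = proj, image = img)
}

new_complex_image <- function(amplitude, phase) {
  stopifnot(identical(dim(amplitude), dim(phase)))
  phase[amplitude == 0] <- 0
  structure(list(amplitude = amplitude, phase = phase), class = "complex_image")
}

#' @export
print.complex_image <- function(x, ...) {
  cat(sprintf("<complex_image> %d x %d, support %d px, phase span [%.3f, %.3f]\n",
              nrow(x$amplitude), ncol(x$amplitude), sum(x$amplitude > 0),
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' 2D diffraction of a complex image
#'
#' Modulus squared of the centered 2D DFT of a (square, complex) image.
#'
#' @param img Square complex (or real) matrix.
#' @return A `diffraction_pattern`.
#' @export
diffract_2d <- function(img) {
  if (!is.matrix(img) || nrow(img) != ncol(img)) stop("img must be a square matrix")
  new_diffraction_pattern(Mod(fft2c(img))^2)
}

#' Friedel (centrosymmetry) violation of a pattern
#'
#' Normalized asymmetry `sum((I(Q) - I(-Q))^2) / sum(I^2)`; exactly 0 for a
#' real (zero-phase) object, measurably positive for strong-phase objects —
#' the broken centrosymmetry a multicentered strong-phase pattern exhibits.
#'
#' @param pattern A `diffraction_pattern` or intensity matrix.
#' @return Nonnegative scalar.
#' @export
friedel_violation <- function(pattern) {
  I <- if (inherits(pattern, "diffraction_pattern")) pattern$intensity else pattern
  n <- nrow(I)
  # centered convention: -Q of index i is 2 - i (mod n), i.e. reverse + roll
  Iflip <- I[c(1L, n:2L), c(1L, n:2L)]
  sum((I - Iflip)^2) / sum(I^2)
}
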