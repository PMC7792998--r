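# Shared fixtures: everything is generated in code at test time.

fix_grid <- function(n = 32L) grid_spec(n)

fix_config <- function(n = 32L, ...) simulator_config(fix_grid(n), ...)

# 1/e autocorrelation half-widths of a 3D field along its three axes
# (Wiener-Khinchin via FFT, mean removed, linear interpolation to 1/e)
acf_halfwidths <- function(f) {
  n <- dim(f)[1]
  f <- f - mean(f)
  a <- Re(fft(Mod(fft(f))^2, inverse = TRUE)) / length(f)
  a <- a / a[1]
  lagline <- list(a[1:(n %/% 2), 1, 1], a[1, 1:(n %/% 2), 1], a[1, 1, 1:(n %/% 2)])
  vapply(lagline, function(v) {
    i <- which(v < exp(-1))[1]
    if (is.na(i) || i < 2) return(NA_real_)
    approx(v[c(i - 1, i)], c(i - 2, i - 1), xout = exp(-1))$y
  }, 0)
}

# quarter turn about the z axis on the centered lattice: the inverse map of a
# +90 degree rotation sends output (x, y) to input (y, -x); index 1 (the
# unpaired -n/2 plane) has no partner and is zeroed
quarter_turn_z <- function(A) {
  n <- dim(A)[1]
  out <- array(0, dim(A))
  for (i in 2:n) out[i, , ] <- A[, n + 2L - i, ]  # out[i,j,k] = A[j, n+2-i, k]
  out
}

# one reproducible random particle on a small grid
fix_particle <- function(seed = 42L, n = 32L) {
  sample_random_particle(fix_config(n), seed)
}

# a support-confined random-phase starting state for an instance
run_seeded_state <- function(inst, seed = 1L) {
  n <- nrow(inst$pattern$intensity)
  m <- sqrt(inst$pattern$intensity)
  x0 <- cdinvert:::with_seed(seed, {
    phi <- matrix(runif(n * n, -pi, pi), n, n)
    cdinvert:::ifft2c(m * exp(1i * phi)) * inst$support
  })
  pr_state(x0, inst$support, m)
}

# a solvable retrieval instance: oversampled pattern + exactly consistent
# complex truth (the unmasked central crop of the complex projection, so the
# pattern is precisely its diffraction) + the projected support
fix_instance <- function(seed = 7L, n = 32L) {
  p <- sample_random_particle(fix_config(n), seed)
  pr <- cdinvert:::project_object(p$object, "z")
  truth <- cdinvert:::central_crop(pr$field)
  list(pattern = diffract_2d(pr$field),
       target_amplitude = pr$image$amplitude,
       target_phase_scaled = (pr$image$phase + pi) / (2 * pi) *
         (pr$image$phase != 0),
       truth = truth,
       # include every nonzero-amplitude pixel so the truth satisfies the
       # support constraint exactly
       support = support_from_amplitude(Mod(truth), 1e-12, n))
}
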