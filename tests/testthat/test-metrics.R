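test_that("chi2 closed forms and invariances hold", {
  set.seed(1)
  m <- matrix(runif(64, 0.1, 1), 8, 8)
  expect_identical(chi2_modulus(m, m), 0)
  expect_equal(chi2_modulus(m * 0, m), 1)                 # normalization anchor
  expect_equal(chi2_modulus(m * 1.1, m), 0.01, tolerance = 1e-12)
  expect_equal(chi2_modulus(3.7 * m * 1.1, 3.7 * m), 0.01, tolerance = 1e-12)
  expect_error(chi2_modulus(m, m * 0), "all-zero")

  p <- matrix(rnorm(64), 8, 8); t <- matrix(rnorm(64), 8, 8)
  expect_equal(chi2_real(p, t), sum((p - t)^2) / sum(t^2), tolerance = 1e-14)
})

test_that("alignment removes translation, global phase and the conjugate twin", {
  inst <- fix_instance(31)
  zt <- inst$truth

  resid <- function(img) {
    za <- img$amplitude * exp(1i * img$phase)
    sqrt(sum(Mod(za - zt)^2) / sum(Mod(zt)^2))
  }

  expect_lt(resid(align_reconstruction(zt, zt)), 1e-10)  # truth unchanged

  shifted <- zt[c(16, 1:15), c(2:16, 1)]  # one-pixel circular shift
  a <- align_reconstruction(shifted, zt)
  expect_lt(resid(a), 1e-10)
  expect_lt(chi2_real(a$amplitude, Mod(zt)), 1e-10)

  phased <- zt * exp(1i * 1.0)
  expect_lt(resid(align_reconstruction(phased, zt)), 1e-10)

  twin <- Conj(zt[c(1, 16:2), c(1, 16:2)])  # conjugate-inverted candidate
  expect_lt(resid(align_reconstruction(twin, zt)), 1e-10)
})

test_that("Gamma fits recover known parameters and reject degenerate input", {
  set.seed(42)
  x <- rgamma(1e4, shape = 2, scale = 0.01)
  f <- fit_gamma(x)
  expect_lt(abs(f$mean - 0.02) / 0.02, 0.05)

  y <- rexp(1e4, rate = 5)  # Gamma with shape 1
  f2 <- fit_gamma(y)
  expect_lt(abs(f2$shape - 1), 0.1)

  expect_error(fit_gamma(rep(0.3, 100)), "degenerate")
  expect_error(fit_gamma(c(-1, x[1:20])), "positive")
  expect_error(fit_gamma(x[1:5]), "at least 10")

  td <- tidy(f); expect_identical(td$term, c("shape", "scale"))
  gl <- glance(f); expect_equal(gl$mean, f$mean)
})

test_that("phase unwrapping inverts wrapping up to a 2*pi constant", {
  n <- 32L
  ramp <- outer(seq(0, 6 * pi, length.out = n), seq(0, 2 * pi, length.out = n), `+`)
  w <- wrap_phase(ramp)
  u <- unwrap_phase_2d(w)
  dev <- u - ramp
  expect_lt(max(abs(dev - dev[1])), 1e-9)            # ramp + constant
  expect_equal(wrap_phase(u), wrap_phase(w), tolerance = 1e-12)  # congruence

  smooth <- outer(sin(seq(0, 2, length.out = n)), cos(seq(0, 2, length.out = n)))
  us <- unwrap_phase_2d(smooth)
  d2 <- us - smooth
  expect_lt(max(abs(d2 - d2[1])), 1e-9)              # already-smooth unchanged

  # synthetic correlated field with span 4*pi, masked round trip
  g <- fix_grid(32)
  f3 <- sample_phase_field(g, phase_field_params(6, 6, 6, phase_span = 2 * pi), seed = 3)
  f <- 2 * f3[, , 16]                                # span 4*pi slice
  mask <- matrix(1, n, n)
  u3 <- unwrap_phase_2d(wrap_phase(f), mask)
  d3 <- u3 - f
  expect_lt(max(abs(d3 - d3[1])), 1e-6)
})

test_that("NNS retrieves library members exactly and improves with library size", {
  cfg <- fix_config(32)
  ds <- make_dataset(60, cfg, seed = 17, train_frac = 0.75)
  idx <- nns_index(ds)
  j <- ds$split$train[4]
  r <- nns_query(idx, ds$samples[[j]]$pattern)
  expect_identical(r$match, j)
  expect_lt(r$chi2, 1e-20)

  one <- nns_index(ds, idx = ds$split$train[1])
  r1 <- nns_query(one, ds$samples[[j]]$pattern)
  expect_identical(r1$match, ds$split$train[1])

  # nested libraries: mean error non-increasing with library size
  sizes <- c(5, 15, 45)
  qs <- ds$split$validation
  means <- sapply(sizes, function(k) {
    ik <- nns_index(ds, idx = ds$split$train[1:k])
    mean(nns_evaluate(ik, ds, qs)$chi2_modulus)
  })
  expect_true(all(diff(means) <= 1e-12))
})
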