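test_that("a single-voxel object diffracts to a flat unit pattern", {
  n <- 16L
  amp <- array(0, c(n, n, n)); amp[9, 9, 9] <- 1
  obj <- cdinvert:::new_complex_object(amp, amp * 0, grid_spec(n))
  I <- diffract_3d(obj)
  expect_equal(max(abs(I - 1)), 0, tolerance = 1e-12)
  img <- matrix(0 + 0i, n, n); img[9, 9] <- 1
  expect_equal(max(abs(diffract_2d(img)$intensity - 1)), 0, tolerance = 1e-12)
})

test_that("Parseval's identity holds in 2D and 3D", {
  p <- fix_particle(5)
  fld <- cdinvert:::object_field(p$object)
  I3 <- diffract_3d(p$object)
  expect_equal(sum(I3) / length(I3), sum(Mod(fld)^2), tolerance = 1e-10)

  pr <- cdinvert:::project_object(p$object)
  I2 <- diffract_2d(pr$field)$intensity
  expect_equal(sum(I2) / length(I2), sum(Mod(pr$field)^2), tolerance = 1e-10)
})

test_that("diffraction modulus is invariant under translation of the image", {
  p <- fix_particle(6)
  z <- cdinvert:::project_object(p$object)$field
  zs <- z[c(4:32, 1:3), c(30:32, 1:29)]  # circular shift
  expect_equal(diffract_2d(zs)$intensity, diffract_2d(z)$intensity,
               tolerance = 1e-10)
})

test_that("Friedel symmetry is exact for zero-phase objects and broken by strong phase", {
  g <- fix_grid(32)
  mask <- voxelize_superellipsoid(g, superellipsoid_params(6, 5, 7, 1.3, 0.9))
  zero_phase <- assemble_object(mask, array(0, dim(mask)), sigma = 1, grid = g)
  expect_lt(friedel_violation(central_slice(diffract_3d(zero_phase))), 1e-25)

  strong <- fix_particle(9)  # phase_span = 2*pi by default
  expect_gt(friedel_violation(central_slice(diffract_3d(strong$object))), 1e-4)
})

test_that("the central slice equals the diffraction of the complex projection", {
  for (s in c(3, 14, 27)) {
    p <- fix_particle(s)
    for (ax in c("x", "y", "z")) {
      sl <- central_slice(diffract_3d(p$object), ax)$intensity
      d2 <- diffract_2d(cdinvert:::project_object(p$object, ax)$field)$intensity
      expect_lt(max(abs(sl - d2)) / max(sl), 1e-8)
    }
  }
})

test_that("a separable object's slice factorizes as |FT2(f)|^2 |sum g|^2", {
  n <- 16L
  ax <- cdinvert:::grid_axis(n)
  f2 <- outer(exp(-ax^2 / 6), exp(-ax^2 / 4))  # in-plane factor
  gz <- exp(-ax^2 / 5)                          # axial factor
  mx <- max(outer(f2, gz))
  amp <- outer(f2, gz) / mx
  obj <- cdinvert:::new_complex_object(amp, amp * 0, grid_spec(n))
  sl <- central_slice(diffract_3d(obj), "z")$intensity
  expected <- Mod(cdinvert:::fft2c(f2 / mx))^2 * sum(gz)^2
  expect_equal(sl, expected, tolerance = 1e-8)
  # and the slice passes through the zero-frequency pixel of the 3D transform
  I3 <- diffract_3d(obj)
  expect_identical(sl[9, 9], I3[9, 9, 9])
})

test_that("projection of a single-slab object returns that slab, with zero phase for real objects", {
  n <- 16L
  amp <- array(0, c(n, n, n))
  slab <- matrix(0, n, n); slab[7:10, 6:11] <- 1
  amp[, , 9] <- slab
  obj <- cdinvert:::new_complex_object(amp, amp * 0, grid_spec(n))
  pr <- cdinvert:::project_object(obj, "z")
  expect_equal(Re(pr$field), slab, tolerance = 1e-12)
  expect_true(all(pr$image$phase == 0))
})
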