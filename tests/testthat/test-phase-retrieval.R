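test_that("an iterate satisfying both constraints is a fixed point of ER and HIO", {
  inst <- fix_instance(7)
  truth_frame <- cdinvert:::central_embed(inst$truth, 32L)
  st <- pr_state(truth_frame, inst$support, sqrt(inst$pattern$intensity))
  for (stepper in list(er_step, function(s) hio_step(s, 0.9))) {
    s <- st
    chis <- replicate(10, { s <<- stepper(s); s$chi2 })
    expect_lt(max(chis), 1e-12)
    expect_lt(max(abs(s$iterate - truth_frame)), 1e-8)
  }
})

test_that("ER projects exactly onto the support and decreases chi2 monotonically", {
  inst <- fix_instance(13)
  st <- run_seeded_state(inst, seed = 4)
  chis <- numeric(50)
  for (k in 1:50) {
    st <- er_step(st)
    chis[k] <- st$chi2
    expect_true(all(st$iterate[inst$support == 0] == 0))
  }
  expect_true(all(diff(chis) <= 1e-10))
})

test_that("HIO with beta = 0 leaves outside-support pixels unchanged", {
  inst <- fix_instance(8)
  st <- run_seeded_state(inst, seed = 2)
  before <- st$iterate
  st2 <- hio_step(st, beta = 0)
  out <- inst$support == 0
  expect_equal(st2$iterate[out], before[out], tolerance = 1e-14)
  expect_error(hio_step(st, beta = 1.5), "beta")
})

test_that("shrink-wrap recovers crisp blobs and tracks the threshold monotonically", {
  n <- 32L
  blob <- matrix(0, n, n); blob[10:20, 12:22] <- 1
  expect_identical(shrink_wrap(blob, sigma = 0, threshold_fraction = 0.5), blob)

  ax <- cdinvert:::grid_axis(n)
  disk_amp <- exp(-outer(ax^2, ax^2, `+`) / 50)  # blurred-disk amplitude
  s_low <- shrink_wrap(disk_amp, sigma = 1, threshold_fraction = 0.2)
  s_half <- shrink_wrap(disk_amp, sigma = 1, threshold_fraction = 0.5)
  s_high <- shrink_wrap(disk_amp, sigma = 1, threshold_fraction = 0.95)
  expect_gt(sum(s_low), sum(s_half))        # lower threshold, larger support
  expect_lt(sum(s_high), 12)                # near-1 threshold shrinks to the peak
  expect_true(s_high[17, 17] == 1)
  expect_error(shrink_wrap(disk_amp, sigma = 1, threshold_fraction = 1.2),
               "threshold_fraction")
})

test_that("support binarization of an amplitude follows the threshold exactly", {
  bin <- matrix(0, 8, 8); bin[3:6, 2:5] <- 1
  expect_identical(support_from_amplitude(bin, 0.4, n_det = 8L), bin)

  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  m <- support_from_amplitude(ramp, 0.5, n_det = 8L)
  expect_identical(m == 1, ramp >= 0.5)
  expect_error(support_from_amplitude(matrix(0, 4, 4)), "all-zero")
})

test_that("run_schedule is deterministic and flat when started at the solution", {
  inst <- fix_instance(19)
  sched <- list(schedule_step("ER", 5), schedule_step("HIO", 10, 0.9),
                schedule_step("ER", 5))
  r1 <- run_schedule(inst$pattern, "random", inst$support, sched, seed = 6)
  r2 <- run_schedule(inst$pattern, "random", inst$support, sched, seed = 6)
  expect_identical(r1$trace, r2$trace)
  expect_identical(nrow(r1$trace), 20L)
  expect_identical(r1$trace$algorithm, rep(c("ER", "HIO", "ER"), c(5, 10, 5)))

  truth_frame <- cdinvert:::central_embed(inst$truth, 32L)
  r3 <- run_schedule(inst$pattern, truth_frame, inst$support, sched)
  expect_lt(max(r3$trace$chi2), 1e-10)
})

test_that("the default schedule solves an oversampled instance from random phase", {
  inst <- fix_instance(23)
  ok <- sapply(1:3, function(s) {
    run_schedule(inst$pattern, "random", inst$support, default_schedule(),
                 seed = s)$final_chi2
  })
  expect_gt(sum(ok < 1e-3), 1)  # majority of restarts converge
})
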