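test_that("the network emits two quarter-area maps for any valid config", {
  for (cc in list(model_config(16, 4, 2), model_config(32, 6, 3))) {
    m <- build_model(cc, seed = 1)
    n <- cc$input_size
    X <- array(runif(n * n), c(n, n, 1, 1))
    pr <- cdinvert:::nn_forward_eval(m, X)
    expect_identical(dim(pr$amp), c(n %/% 2L, n %/% 2L, 1L, 1L))
    expect_identical(dim(pr$phase), c(n %/% 2L, n %/% 2L, 1L, 1L))
    expect_true(all(pr$amp >= 0) && all(pr$phase >= 0))  # final ReLU heads
    z <- cdinvert:::nn_forward_eval(m, X * 0)
    expect_true(all(is.finite(z$amp)) && all(is.finite(z$phase)))
  }
  expect_error(model_config(24, 4, 4), "divisible")
})

test_that("doubling base channels grows conv parameters about fourfold", {
  conv_params <- function(m) {
    sum(sapply(c(m$enc, m$amp, m$phase), function(l) {
      if (l$type == "conv") length(l$W) else 0
    }))
  }
  m1 <- build_model(model_config(32, 8, 3), seed = 1)
  m2 <- build_model(model_config(32, 16, 3), seed = 1)
  ratio <- conv_params(m2) / conv_params(m1)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.05)
})

test_that("analytic gradients match finite differences through every layer type", {
  mc <- model_config(8, 2, 1, batch_norm = TRUE)
  m <- build_model(mc, seed = 2)
  set.seed(3)
  X <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  TA <- array(runif(4 * 4 * 2), c(4, 4, 1, 2))
  TP <- array(runif(4 * 4 * 2), c(4, 4, 1, 2))
  mods <- lapply(1:2, function(k) matrix(runif(64) + 0.1, 8, 8))
  w <- loss_weights(1, 1, 0.3)
  r <- cdinvert:::nn_batch_grad(m, X, TA, TP, mods, w)
  for (probe in list(c("enc", 1, "W"), c("enc", 3, "gamma"), c("enc", 4, "W"),
                     c("enc", 9, "b"), c("enc", 15, "beta"), c("amp", 1, "W"),
                     c("phase", 1, "b"))) {
    seg <- probe[1]; li <- as.integer(probe[2]); nm <- probe[3]
    g <- r$grads[[seg]][[li]][[nm]]
    skip_if(is.null(g))
    idx <- which.max(abs(g))
    eps <- 1e-6
    f <- function(v) {
      mm <- m; mm[[seg]][[li]][[nm]][idx] <- v
      cdinvert:::nn_batch_grad(mm, X, TA, TP, mods, w)$loss
    }
    v0 <- m[[seg]][[li]][[nm]][idx]
    num <- (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-4)
  }
})

test_that("the composite loss is zero at truth and has the closed-form amplitude term", {
  s <- cdinvert:::make_training_sample(fix_config(32), 3)
  amp <- s$target_amplitude
  ps <- s$target_phase_scaled
  # modulus consistent with the truth pair under the loss's phase convention
  truth_c <- amp * exp(1i * (2 * pi * ps - pi))
  consistent_mod <- Mod(cdinvert:::fft2c(cdinvert:::central_embed(truth_c, 32L)))
  l0 <- composite_loss(amp, ps, amp, ps, consistent_mod)
  expect_lt(l0$loss, 1e-10)
  expect_identical(l0$amp, 0)

  # support-violating perturbation raises the reciprocal term
  pert <- amp; pert[1, 1] <- pert[1, 1] + 0.5
  expect_gt(composite_loss(pert, ps, amp, ps, consistent_mod)$recip, 1e-6)

  # w_recip = 0: amplitude off by delta on a fraction f of pixels -> delta * f
  delta <- 0.2
  pa <- amp; pa[1:8, 1:16] <- pa[1:8, 1:16] + delta  # f = 1/2
  l <- composite_loss(pa, ps, amp, ps, consistent_mod,
                      loss_weights(1, 1, 0))
  expect_equal(l$amp, delta * 0.5, tolerance = 1e-12)
})

test_that("training is deterministic, records history, and can overfit a tiny corpus", {
  cfg <- fix_config(16, L_range = c(2, 6))
  ds <- make_dataset(6, cfg, seed = 21, train_frac = 0.84)
  mc <- model_config(16, 6, 2, batch_norm = TRUE)
  m0 <- build_model(mc, seed = 4)

  m1 <- train_inverter(m0, ds, epochs = 1, batch_size = 5, seed = 9)
  m2 <- train_inverter(m0, ds, epochs = 1, batch_size = 5, seed = 9)
  expect_identical(m1$history$train, m2$history$train)

  m0b <- build_model(model_config(16, 8, 2, batch_norm = TRUE), seed = 4)
  m <- train_inverter(m0b, ds, weights = loss_weights(1, 1, 0), epochs = 300,
                      batch_size = 5, lr = 5e-3, seed = 9)
  h <- m$history
  expect_identical(nrow(h), 300L)
  # capacity check: the real-space loss on a handful of samples collapses
  expect_lt(min(h$train), 0.15 * h$train[1])
})

test_that("inference is scale-invariant, masks the phase, and matches shapes", {
  cfg <- fix_config(16, L_range = c(2, 6))
  ds <- make_dataset(3, cfg, seed = 33, train_frac = 1)
  m <- build_model(model_config(16, 4, 2), seed = 5)
  pat <- ds$samples[[1]]$pattern
  img1 <- infer(m, pat)
  img2 <- infer(m, pat$intensity * 7.3)
  expect_equal(img1$amplitude, img2$amplitude, tolerance = 1e-12)
  expect_equal(img1$phase, img2$phase, tolerance = 1e-12)
  expect_true(all(img1$phase[img1$amplitude < 0.1 * max(img1$amplitude)] == 0))
  expect_identical(dim(img1$amplitude), c(8L, 8L))
  expect_error(infer(m, matrix(1, 12, 12)), "expects")
})
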