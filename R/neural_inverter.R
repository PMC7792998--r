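#' CNN architecture configuration
#'
#' Two-branch encoder-decoder: a convolutional encoder shared by both heads,
#' then two independent deconvolutional decoders emitting the amplitude and
#' the (scaled) phase. Each level pairs a 3x3 convolution block with a
#' separable 3x1 + 1x3 block, each followed by a leaky ReLU and (optionally)
#' batch normalization; the encoder downsamples by 2x2 max pooling and the
#' decoders upsample by nearest-neighbour doubling. The final convolution of
#' each head uses a plain ReLU so outputs are nonnegative. The output maps
#' are `input_size/2` per dimension — one quarter of the input pattern area —
#' keeping the inversion overdetermined.
#'
#' @param input_size Detector pixels per dimension (must be divisible by
#'   `2^depth`).
#' @param base_channels Channels of the first encoder level; doubled per level.
#' @param depth Number of pooling levels.
#' @param negative_slope Leaky-ReLU slope for negative inputs.
#' @param batch_norm Include batch-normalization layers.
#' @return A `model_config` list.
#' @export
model_config <- function(input_size = 64L, base_channels = 32L, depth = 4L,
                         negative_slope = 0.1, batch_norm = TRUE) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (input_size %% (2L^depth) != 0L) {
    stop("input_size ", input_size, " is not divisible by 2^depth = ", 2L^depth)
  }
  if (input_size %/% (2L^depth) < 2L) stop("depth too large for input_size")
  structure(list(input_size = input_size, base_channels = as.integer(base_channels),
                 depth = depth, negative_slope = negative_slope,
                 batch_norm = batch_norm),
            class = "model_config")
}

#' Loss-term weights
#'
#' @param w_amp,w_phase Weights of the real-space absolute-error terms on the
#'   amplitude and scaled-phase heads.
#' @param w_recip Weight of the reciprocal-space consistency term: the
#'   scale-invariant normalized L2 misfit between the Fourier modulus of the
#'   predicted complex image and the input modulus.
#' @param phase_weighting `"amplitude"` (default) weights the phase
#'   absolute-error term by the true amplitude, concentrating it where the
#'   object has density — the phase of a near-empty pixel is physically
#'   meaningless; `"uniform"` is a plain pixel mean.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_amp = 1, w_phase = 1, w_recip = 1,
                         phase_weighting = c("amplitude", "uniform")) {
  if (any(c(w_amp, w_phase, w_recip) < 0) || w_amp + w_phase + w_recip <= 0) {
    stop("weights must be nonnegative with at least one positive")
  }
  structure(list(w_amp = w_amp, w_phase = w_phase, w_recip = w_recip,
                 phase_weighting = match.arg(phase_weighting)),
            class = "loss_weights")
}

# weighted phase |error| term and its gradient factor
phase_err_term <- function(dphase, true_amp, weighting) {
  if (weighting == "amplitude") {
    wsum <- sum(true_amp)
    list(term = sum(true_amp * abs(dphase)) / wsum, w = true_amp / wsum)
  } else {
    list(term = mean(abs(dphase)),
         w = array(1 / length(dphase), dim(dphase)))
  }
}

conv_block <- function(cin, cout, cfg) {
  out <- list(lyr_conv(3, 3, cin, cout, slope = cfg$negative_slope),
              lyr_lrelu(cfg$negative_slope))
  if (cfg$batch_norm) out <- c(out, list(lyr_bn(cout)))
  out
}

sep_block <- function(c, cfg) {
  out <- list(lyr_conv(3, 1, c, c, slope = cfg$negative_slope),
              lyr_conv(1, 3, c, c, slope = cfg$negative_slope),
              lyr_lrelu(cfg$negative_slope))
  if (cfg$batch_norm) out <- c(out, list(lyr_bn(c)))
  out
}

#' Build an untrained inverter model
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `inverter_model` with segments `enc`, `amp`, `phase`, the
#'   config, and the parameter count in `n_params`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    ch <- config$base_channels * 2L^(0:config$depth)
    enc <- list()
    cin <- 1L
    for (lev in seq_len(config$depth)) {
      enc <- c(enc, conv_block(cin, ch[lev], config), sep_block(ch[lev], config),
               list(lyr_pool()))
      cin <- ch[lev]
    }
    # bottleneck
    enc <- c(enc, conv_block(cin, ch[config$depth + 1L], config),
             sep_block(ch[config$depth + 1L], config))
    decoder <- function() {
      dec <- list()
      c_now <- ch[config$depth + 1L]
      for (lev in rev(seq_len(config$depth))[-config$depth]) {
        dec <- c(dec, list(lyr_up()), conv_block(c_now, ch[lev], config),
                 sep_block(ch[lev], config))
        c_now <- ch[lev]
      }
      c(dec, list(lyr_conv(3, 3, c_now, 1L, slope = config$negative_slope),
                  lyr_relu()))
    }
    m <- structure(list(enc = enc, amp = decoder(), phase = decoder(),
                        config = config, norm = "per-pattern max of sqrt(I)"),
                   class = "inverter_model")
    m$n_params <- n_params_seg(m$enc) + n_params_seg(m$amp) + n_params_seg(m$phase)
    m
  })
}

#' @export
print.inverter_model <- function(x, ...) {
  cat(sprintf("<inverter_model> input %d -> 2 x %d outputs, depth %d, base %d channels, %s params%s\n",
              x$config$input_size, x$config$input_size %/% 2L, x$config$depth,
              x$config$base_channels, format(x$n_params, big.mark = ","),
              if (!is.null(x$history)) sprintf(", trained %d epochs", nrow(x$history)) else " (untrained)"))
  invisible(x)
}

# normalized input: sqrt intensity scaled by its own maximum
normalize_pattern <- function(intensity) {
  m <- sqrt(pmax(intensity, 0))
  mx <- max(m)
  if (mx == 0) stop("all-zero diffraction pattern")
  m / mx
}

# scale-invariant reciprocal misfit 1 - (u.t)^2/((u.u)(t.t)) between the
# Fourier modulus u of the embedded predicted complex image and the measured
# modulus t, with its gradients w.r.t. amplitude and scaled phase maps
recip_term <- function(amp, phase_scaled, meas_modulus, want_grad = FALSE) {
  n <- nrow(meas_modulus)
  theta <- 2 * pi * phase_scaled - pi
  z <- central_embed(amp * exp(1i * theta), n)
  G <- fft2c(z)
  u <- Mod(G)
  t <- meas_modulus
  uu <- sum(u^2); tt <- sum(t^2); ut <- sum(u * t)
  if (tt == 0) stop("all-zero measured modulus")
  loss <- 1 - ut^2 / (uu * tt)
  if (!want_grad) return(list(loss = loss))
  gu <- -2 * ut / (uu * tt) * (t - (ut / uu) * u)
  gG <- gu * G / pmax(u, 1e-12)
  gz <- fftshift(fft(ifftshift(gG), inverse = TRUE))  # adjoint of fft2c
  gz_c <- central_crop(gz)
  ephi <- exp(1i * theta)
  gA <- Re(Conj(ephi) * gz_c)
  gP <- 2 * pi * amp * Im(Conj(ephi) * gz_c)
  list(loss = loss, gA = gA, gP = gP)
}

#' Composite real- plus reciprocal-space loss
#'
#' `loss = w_amp * MAE(pred_amp, true_amp) + w_phase * WAE(pred_phase_scaled,
#' true_phase_scaled) + w_recip * R`, where `WAE` is the (by default
#' amplitude-weighted, see [loss_weights()]) mean absolute phase error and
#' `R` is the scale-invariant
#' normalized L2 misfit between the Fourier modulus of the predicted complex
#' image (`pred_amp * exp(i(2*pi*pred_phase_scaled - pi))`, zero-embedded to
#' the detector frame) and the input modulus. The reciprocal term ties the
#' two heads together through the forward model; it is zero iff the predicted
#' complex image diffracts (up to scale) to the measured modulus.
#'
#' @param pred_amp,true_amp Amplitude maps (n/2 x n/2).
#' @param pred_phase_scaled,true_phase_scaled Scaled-phase maps in `[0, 1]`.
#' @param input_modulus Measured modulus (n x n), e.g. `sqrt(intensity)`.
#' @param weights A [loss_weights()].
#' @return List with `loss` and the per-term breakdown
#'   (`amp`, `phase`, `recip`, unweighted).
#' @export
composite_loss <- function(pred_amp, pred_phase_scaled, true_amp,
                           true_phase_scaled, input_modulus,
                           weights = loss_weights()) {
  stopifnot(identical(dim(pred_amp), dim(true_amp)),
            identical(dim(pred_phase_scaled), dim(true_phase_scaled)))
  if (any(!is.finite(pred_amp)) || any(!is.finite(pred_phase_scaled))) {
    stop("non-finite prediction passed to composite_loss")
  }
  amp_term <- mean(abs(pred_amp - true_amp))
  phase_term <- phase_err_term(pred_phase_scaled - true_phase_scaled,
                               true_amp, weights$phase_weighting)$term
  recip <- recip_term(pred_amp, pred_phase_scaled, input_modulus)$loss
  list(loss = weights$w_amp * amp_term + weights$w_phase * phase_term +
         weights$w_recip * recip,
       amp = amp_term, phase = phase_term, recip = recip)
}

# Forward + loss + full parameter gradients for one batch.
# X: (n, n, 1, B) normalized moduli; TA/TP: (n/2, n/2, 1, B) targets;
# mod_list: list of B measured-modulus matrices (the normalized inputs).
nn_batch_grad <- function(model, X, TA, TP, mod_list, weights) {
  e <- seg_forward(model$enc, X, training = TRUE)
  a <- seg_forward(model$amp, e$y, training = TRUE)
  p <- seg_forward(model$phase, e$y, training = TRUE)
  model$enc <- e$layers; model$amp <- a$layers; model$phase <- p$layers
  B <- dim(X)[4]
  npix <- prod(dim(a$y)[1:2])
  amp_term <- mean(abs(a$y - TA))
  pt <- phase_err_term(p$y - TP, TA, weights$phase_weighting)
  phase_term <- pt$term
  gA <- weights$w_amp * sign(a$y - TA) / (npix * B)
  gP <- weights$w_phase * pt$w * sign(p$y - TP)
  recip <- 0
  if (weights$w_recip > 0) {
    for (k in seq_len(B)) {
      r <- recip_term(a$y[, , 1, k], p$y[, , 1, k], mod_list[[k]], want_grad = TRUE)
      recip <- recip + r$loss / B
      gA[, , 1, k] <- gA[, , 1, k] + weights$w_recip * r$gA / B
      gP[, , 1, k] <- gP[, , 1, k] + weights$w_recip * r$gP / B
    }
  }
  ba <- seg_backward(model$amp, a$caches, gA)
  bp <- seg_backward(model$phase, p$caches, gP)
  be <- seg_backward(model$enc, e$caches, ba$gx + bp$gx)
  list(model = model,
       grads = list(enc = be$grads, amp = ba$grads, phase = bp$grads),
       loss = weights$w_amp * amp_term + weights$w_phase * phase_term +
         weights$w_recip * recip,
       amp = amp_term, phase = phase_term, recip = recip)
}

nn_forward_eval <- function(model, X) {
  e <- seg_forward(model$enc, X, training = FALSE)
  a <- seg_forward(model$amp, e$y, training = FALSE)
  p <- seg_forward(model$phase, e$y, training = FALSE)
  list(amp = a$y, phase = p$y)
}

# stack a list of matrices into (H, W, 1, N)
stack4 <- function(mats) {
  d <- dim(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(d[1], d[2], 1L, length(mats)))
}

dataset_inputs <- function(dataset, idx) {
  lapply(dataset$samples[idx], function(s) normalize_pattern(s$pattern$intensity))
}

#' Train the inverter on a dataset
#'
#' Mini-batch Adam on the composite loss. Per-epoch training and validation
#' losses are recorded and the best-validation weights are retained.
#' Deterministic given the seed.
#'
#' @param model An `inverter_model` from [build_model()].
#' @param dataset A dataset from [make_dataset()] (carries the train /
#'   validation split).
#' @param weights A [loss_weights()].
#' @param epochs Number of complete passes over the training split.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed (shuffling).
#' @param verbose Print a line per epoch.
#' @return The trained `inverter_model`, with `history` (tibble of per-epoch
#'   train/validation losses).
#' @export
train_inverter <- function(model, dataset, weights = loss_weights(),
                           epochs = 30L, batch_size = 16L, lr = 1e-3,
                           seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "inverter_model"))
  tr_idx <- dataset$split$train
  va_idx <- dataset$split$validation
  if (!length(tr_idx)) stop("dataset has an empty training split")
  tr_in <- dataset_inputs(dataset, tr_idx)
  tr_ta <- lapply(dataset$samples[tr_idx], `[[`, "target_amplitude")
  tr_tp <- lapply(dataset$samples[tr_idx], `[[`, "target_phase_scaled")
  va_in <- dataset_inputs(dataset, va_idx)
  va_ta <- lapply(dataset$samples[va_idx], `[[`, "target_amplitude")
  va_tp <- lapply(dataset$samples[va_idx], `[[`, "target_phase_scaled")
  state <- adam_init(model)
  hist <- list()
  best <- list(val = Inf, model = model)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(tr_idx))
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1, length(ord))]
        r <- nn_batch_grad(model, stack4(tr_in[bi]), stack4(tr_ta[bi]),
                           stack4(tr_tp[bi]), tr_in[bi], weights)
        if (!is.finite(r$loss)) stop("divergent (non-finite) training loss at epoch ", ep)
        model <- r$model
        u <- adam_update(model, r$grads, state, lr)
        model <- u$model; state <- u$state
        ep_loss <- ep_loss + r$loss; nb <- nb + 1
      }
      val <- if (length(va_idx)) {
        pr <- nn_forward_eval(model, stack4(va_in))
        vl <- 0
        for (k in seq_along(va_idx)) {
          cl <- composite_loss(pr$amp[, , 1, k], pr$phase[, , 1, k],
                               va_ta[[k]], va_tp[[k]], va_in[[k]], weights)
          vl <- vl + cl$loss / length(va_idx)
        }
        vl
      } else NA_real_
      hist[[ep]] <- c(epoch = ep, train = ep_loss / nb, validation = val)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %s", ep, ep_loss / nb,
                        ifelse(is.na(val), "-", sprintf("%.5f", val))))
      }
      if (is.finite(val) && val < best$val) best <- list(val = val, model = model)
    }
  })
  out <- if (is.finite(best$val)) best$model else model
  out$history <- tibble::as_tibble(do.call(rbind, hist))
  out$loss_weights <- weights
  out
}

#' @rdname train_inverter
#' @param x A trained `inverter_model`.
#' @param ... Unused.
#' @export
tidy.inverter_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  x$history
}

#' @rdname train_inverter
#' @export
glance.inverter_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = if (is.null(h)) 0L else nrow(h),
    final_train = if (is.null(h)) NA_real_ else h$train[nrow(h)],
    best_validation = if (is.null(h)) NA_real_ else min(h$validation, na.rm = TRUE),
    n_params = x$n_params
  )
}

#' Invert a diffraction pattern with a trained model
#'
#' Applies the model's input normalization (per-pattern maximum of the
#' modulus), runs the network, and converts the scaled-phase head back to
#' radians via the fixed affine map `phase = 2*pi*scaled - pi`. The phase is
#' zeroed where the predicted amplitude falls below `support_threshold`
#' times its maximum. Normalization makes the prediction invariant to a
#' constant rescaling of the input pattern.
#'
#' @param model A trained `inverter_model`.
#' @param pattern A `diffraction_pattern` (or intensity matrix) of the
#'   model's input size.
#' @param support_threshold Relative amplitude threshold for the phase mask.
#' @return A `complex_image`; attribute `phase_scaled` holds the raw clamped
#'   `[0,1]` head output.
#' @export
infer <- function(model, pattern, support_threshold = 0.1) {
  I <- if (inherits(pattern, "diffraction_pattern")) pattern$intensity else pattern
  n <- model$config$input_size
  if (!identical(dim(I), c(n, n))) {
    stop("pattern is ", paste(dim(I), collapse = " x "),
         " but the model expects ", n, " x ", n)
  }
  X <- stack4(list(normalize_pattern(I)))
  pr <- nn_forward_eval(model, X)
  amp <- pr$amp[, , 1, 1]
  ps <- pmin(pmax(pr$phase[, , 1, 1], 0), 1)
  phase <- 2 * pi * ps - pi
  m <- amp >= support_threshold * max(amp)
  phase[!m] <- 0
  img <- new_complex_image(amp, phase)
  attr(img, "phase_scaled") <- ps * m
  img
}

#' Per-sample reconstruction errors over a dataset split
#'
#' Runs [infer()] on each sample and computes three chi-squared errors: the
#' diffraction modulus (max-normalized predicted vs measured modulus), the
#' real-space amplitude, and the real-space scaled phase. CNN outputs live in
#' the fixed training frame, so no ambiguity alignment is applied.
#'
#' @param model A trained `inverter_model`.
#' @param dataset A dataset from [make_dataset()].
#' @param split `"validation"`, `"train"`, or an integer index vector.
#' @return A tibble with `sample`, `chi2_modulus`, `chi2_amplitude`,
#'   `chi2_phase`; attribute `"gamma_means"` carries the Gamma-fit means when
#'   fits succeed.
#' @export
evaluate_on_split <- function(model, dataset, split = "validation") {
  idx <- if (is.character(split)) {
    switch(split, validation = dataset$split$validation,
           train = dataset$split$train, stop("unknown split ", split))
  } else as.integer(split)
  rows <- lapply(idx, function(i) {
    s <- dataset$samples[[i]]
    img <- infer(model, s$pattern)
    ps <- attr(img, "phase_scaled")
    meas <- normalize_pattern(s$pattern$intensity)
    calc <- Mod(fft2c(central_embed(img$amplitude * exp(1i * img$phase),
                                    nrow(meas))))
    calc <- calc / max(calc)
    c(sample = i,
      chi2_modulus = chi2_modulus(calc, meas),
      chi2_amplitude = chi2_real(img$amplitude, s$target_amplitude),
      chi2_phase = chi2_real(ps, s$target_phase_scaled))
  })
  tb <- tibble::as_tibble(do.call(rbind, rows))
  gm <- tryCatch(
    c(modulus = fit_gamma(tb$chi2_modulus)$mean,
      amplitude = fit_gamma(tb$chi2_amplitude)$mean,
      phase = fit_gamma(tb$chi2_phase)$mean),
    error = function(e) NULL)
  attr(tb, "gamma_means") <- gm
  tb
}
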