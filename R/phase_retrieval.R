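#' Phase-retrieval state
#'
#' Holds the current real-space iterate (the algorithm "input" object), the
#' support mask, and the fixed measured Fourier modulus.
#'
#' @param iterate Complex n x n matrix, the real-space iterate.
#' @param support 0/1 n x n matrix.
#' @param modulus Nonnegative n x n matrix, `sqrt(intensity)`.
#' @return A `pr_state`.
#' @export
pr_state <- function(iterate, support, modulus) {
  stopifnot(identical(dim(iterate), dim(support)),
            identical(dim(iterate), dim(modulus)))
  if (sum(modulus) == 0) stop("measured modulus is identically zero")
  if (sum(support) == 0) stop("support mask is empty")
  if (any(!is.finite(iterate))) stop("non-finite iterate")
  structure(list(iterate = iterate, support = support, modulus = modulus,
                 iteration = 0L, chi2 = NA_real_),
            class = "pr_state")
}

# Fourier magnitude projection: replace modulus, keep phase.
magnitude_project <- function(state) {
  F <- fft2c(state$iterate)
  Fp <- state$modulus * exp(1i * Arg(F))
  list(y = ifft2c(Fp))
}

# chi2 of the current support-projected estimate: the conventional
# per-iteration error (the raw iterate right after a magnitude projection
# satisfies the modulus constraint trivially, so it is not what is traced)
estimate_chi2 <- function(y, support, modulus) {
  chi2_modulus(Mod(fft2c(y * support)), modulus)
}

#' One error-reduction step
#'
#' Alternating projections: Fourier magnitude projection followed by the
#' support projection (zero outside the support). The recorded `chi2` is the
#' modulus misfit of the incoming iterate; for support-confined iterates the
#' sequence is non-increasing, and any iterate satisfying both constraints is
#' a fixed point.
#'
#' @param state A `pr_state`.
#' @return Updated `pr_state` (fields `iteration`, `chi2` advanced; `chi2` is
#'   the modulus misfit of the new support-projected estimate).
#' @export
er_step <- function(state) {
  mp <- magnitude_project(state)
  state$iterate <- mp$y * state$support
  state$iteration <- state$iteration + 1L
  state$chi2 <- chi2_modulus(Mod(fft2c(state$iterate)), state$modulus)
  state
}

#' One hybrid input-output step
#'
#' Inside the support the Fourier-projected value is kept; outside, the
#' feedback update `new = old - beta * projected` drives the iterate toward
#' the support constraint while escaping stagnation. `beta = 0` leaves
#' outside-support pixels untouched.
#'
#' @param state A `pr_state`.
#' @param beta Feedback parameter in (0, 1] (0 allowed as the degenerate
#'   no-feedback limit).
#' @return Updated `pr_state`.
#' @export
hio_step <- function(state, beta = 0.9) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  mp <- magnitude_project(state)
  inside <- state$support > 0
  x <- state$iterate - beta * mp$y
  x[inside] <- mp$y[inside]
  state$iterate <- x
  state$iteration <- state$iteration + 1L
  state$chi2 <- estimate_chi2(mp$y, state$support, state$modulus)
  state
}

#' Shrink-wrap support update
#'
#' Blurs the current amplitude estimate with a Gaussian of sd `sigma` and
#' thresholds at `threshold_fraction` of the blurred maximum. The support may
#' both grow and shrink between updates.
#'
#' @param state A `pr_state`, or a nonnegative amplitude matrix.
#' @param sigma Blur sd in pixels (>= 0).
#' @param threshold_fraction Threshold in (0, 1).
#' @return 0/1 support matrix.
#' @export
shrink_wrap <- function(state, sigma = 3, threshold_fraction = 0.1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  amp <- if (inherits(state, "pr_state")) {
    Mod(magnitude_project(state)$y * state$support)
  } else state
  sm <- if (sigma > 0) gaussian_blur(amp, sigma) else amp
  s <- matrix(as.numeric(sm >= threshold_fraction * max(sm)), nrow(sm), ncol(sm))
  if (sum(s) == 0) {
    stop("shrink-wrap produced an empty support; lower threshold_fraction")
  }
  s
}

#' Support from a predicted amplitude
#'
#' Binarization of a (CNN-predicted) amplitude at a fraction of its maximum,
#' embedded centered in the full detector frame.
#'
#' @param amp Nonnegative amplitude matrix (typically n/2 x n/2).
#' @param threshold_fraction Threshold in (0, 1).
#' @param n_det Frame size; defaults to `2 * nrow(amp)`.
#' @return 0/1 `n_det` x `n_det` support matrix.
#' @export
support_from_amplitude <- function(amp, threshold_fraction = 0.1,
                                   n_det = 2L * nrow(amp)) {
  if (any(amp < 0)) stop("amplitude must be nonnegative")
  mx <- max(amp)
  if (mx == 0) stop("all-zero amplitude: no support")
  m <- matrix(as.numeric(amp >= threshold_fraction * mx), nrow(amp), ncol(amp))
  central_embed(m, n_det)
}

#' Central rectangular support
#'
#' The central `n/2` square of the detector frame — the loose support implied
#' by twofold oversampling.
#'
#' @param n_det Frame size.
#' @return 0/1 matrix.
#' @export
support_rect <- function(n_det) {
  central_embed(matrix(1, n_det %/% 2L, n_det %/% 2L), n_det)
}

#' One schedule step
#'
#' @param algorithm `"ER"` or `"HIO"`.
#' @param n_iter Number of iterations of this step (>= 1).
#' @param beta HIO feedback parameter.
#' @param shrinkwrap Optional list `(period, sigma, threshold_fraction,
#'   sigma_decay)`: run a shrink-wrap support update every `period`
#'   iterations (on the global iteration counter), multiplying `sigma` by
#'   `sigma_decay` after each event (floored at 1 pixel).
#' @return A `schedule_step`.
#' @export
schedule_step <- function(algorithm = c("ER", "HIO"), n_iter, beta = 0.9,
                          shrinkwrap = NULL) {
  algorithm <- match.arg(algorithm)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  structure(list(algorithm = algorithm, n_iter = n_iter, beta = beta,
                 shrinkwrap = shrinkwrap),
            class = "schedule_step")
}

#' Default algorithm switch schedule
#'
#' 20 ER iterations, then 5 cycles of (100 HIO at `beta` + 20 ER): 620
#' iterations total, a standard CDI practice of HIO exploration bracketed by
#' ER polishing. Optionally with shrink-wrap support refinement every 30
#' iterations, `sigma` annealed from 3 by a factor 0.95 per event,
#' threshold 0.1.
#'
#' @param beta HIO feedback parameter.
#' @param shrinkwrap Enable shrink-wrap refinement.
#' @return List of [schedule_step()]s.
#' @export
default_schedule <- function(beta = 0.9, shrinkwrap = FALSE) {
  sw <- if (shrinkwrap) {
    list(period = 30L, sigma = 3, threshold_fraction = 0.1, sigma_decay = 0.95)
  } else NULL
  steps <- list(schedule_step("ER", 20, shrinkwrap = sw))
  for (k in 1:5) {
    steps <- c(steps, list(schedule_step("HIO", 100, beta = beta, shrinkwrap = sw),
                           schedule_step("ER", 20, shrinkwrap = sw)))
  }
  steps
}

#' Run an iterative phase-retrieval schedule
#'
#' Executes the steps in order from the given initialization, recording the
#' chi-squared modulus error of every iterate, and returns the central-crop
#' complex image of the final support-projected estimate. Deterministic
#' given the seed.
#'
#' @param pattern A `diffraction_pattern` (or intensity matrix).
#' @param init_phase `"random"` (uniform Fourier phase in (-pi, pi] applied
#'   to the measured modulus) or a complex n x n matrix used as the initial
#'   real-space iterate (e.g. a CNN or NNS prediction embedded in the frame);
#'   its Fourier phase then seeds the first magnitude projection.
#' @param init_support 0/1 n x n support matrix.
#' @param schedule List of [schedule_step()]s.
#' @param seed Integer seed (used by the random initialization).
#' @return A `pr_result`: `image` (`complex_image`, amplitude renormalized to
#'   max 1, central crop), `full` (final complex frame), `support` (final
#'   support), `trace` (tibble: iteration, algorithm, chi2), `final_chi2`.
#' @export
run_schedule <- function(pattern, init_phase = "random", init_support,
                         schedule = default_schedule(), seed = 1L) {
  I <- if (inherits(pattern, "diffraction_pattern")) pattern$intensity else pattern
  modulus <- sqrt(pmax(I, 0))
  n <- nrow(modulus)
  if (!identical(dim(init_support), dim(modulus))) {
    stop("support shape does not match the pattern")
  }
  if (!all(vapply(schedule, inherits, TRUE, "schedule_step"))) {
    stop("schedule must be a list of schedule_step objects")
  }
  x0 <- if (is.character(init_phase) && identical(init_phase, "random")) {
    with_seed(seed, {
      phi <- matrix(runif(n * n, -pi, pi), n, n)
      ifft2c(modulus * exp(1i * phi))
    })
  } else if (is.matrix(init_phase)) {
    init_phase + 0i
  } else stop("init_phase must be \"random\" or a matrix")
  state <- pr_state(x0, init_support, modulus)
  total <- sum(vapply(schedule, `[[`, 0L, "n_iter"))
  chi2 <- numeric(total)
  alg <- character(total)
  it <- 0L
  sw_sigma <- NULL
  for (step in schedule) {
    if (!is.null(step$shrinkwrap) && is.null(sw_sigma)) sw_sigma <- step$shrinkwrap$sigma
    for (k in seq_len(step$n_iter)) {
      state <- if (step$algorithm == "ER") er_step(state) else hio_step(state, step$beta)
      it <- it + 1L
      chi2[it] <- state$chi2
      alg[it] <- step$algorithm
      sw <- step$shrinkwrap
      if (!is.null(sw) && it %% sw$period == 0L) {
        state$support <- shrink_wrap(state, sigma = sw_sigma,
                                     threshold_fraction = sw$threshold_fraction)
        sw_sigma <- max(1, sw_sigma * sw$sigma_decay)
      }
    }
  }
  est <- magnitude_project(state)$y * state$support
  amp <- Mod(est)
  ph <- Arg(est)
  ph[amp == 0] <- 0
  mx <- max(amp)
  image <- new_complex_image(central_crop(amp / mx), central_crop(ph))
  structure(list(image = image, full = est, support = state$support,
                 trace = tibble::tibble(iteration = seq_len(total),
                                        algorithm = alg, chi2 = chi2),
                 final_chi2 = chi2[total]),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result> %d iterations, starting chi2 %.4g, final chi2 %.4g\n",
              nrow(x$trace), x$trace$chi2[1], x$final_chi2))
  invisible(x)
}

#' @rdname run_schedule
#' @param x A `pr_result`.
#' @param ... Unused.
#' @export
tidy.pr_result <- function(x, ...) x$trace

#' @rdname run_schedule
#' @export
glance.pr_result <- function(x, ...) {
  tibble::tibble(iterations = nrow(x$trace),
                 start_chi2 = x$trace$chi2[1],
                 final_chi2 = x$final_chi2,
                 support_area = sum(x$support))
}

#' Write an error trace as CSV
#'
#' @param result A `pr_result`.
#' @param path Output CSV path (columns iteration, algorithm, chi2).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
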