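# ggplot2 renderings of the result types: chi2-vs-iteration traces, error
# histograms with their Gamma fits, and image galleries in the canonical
# 5-row layout (input pattern, true/predicted amplitude, true/predicted phase).

matrix_df <- function(m, label = NULL) {
  d <- data.frame(x = rep(seq_len(nrow(m)), ncol(m)),
                  y = rep(seq_len(ncol(m)), each = nrow(m)),
                  value = as.numeric(m))
  if (!is.null(label)) d$panel <- label
  d
}

#' Plot a 2D array as an image
#'
#' @param m Matrix (intensity shown on log1p scale if `log = TRUE`).
#' @param title Plot title.
#' @param log Log-compress values (for diffraction patterns).
#' @return A ggplot.
#' @export
plot_image <- function(m, title = NULL, log = FALSE) {
  d <- matrix_df(m)
  if (log) d$value <- log1p(d$value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Training-history curve of a trained model
#'
#' @param object A trained `inverter_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.inverter_model <- function(object, ...) {
  h <- object$history
  if (is.null(h)) stop("model has no training history")
  d <- rbind(data.frame(epoch = h$epoch, loss = h$train, set = "train"),
             data.frame(epoch = h$epoch, loss = h$validation, set = "validation"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "composite loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' chi2-versus-iteration trace of a retrieval run
#'
#' @param object A `pr_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$chi2,
                               colour = .data$algorithm, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = expression(chi^2), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean chi2 traces of a four-arm benchmark, with spread bands
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot (one facet per query).
#' @export
autoplot.benchmark_report <- function(object, ...) {
  tr <- object$traces
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$chi2_mean,
                                   colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$chi2_mean - .data$chi2_sd, 1e-12),
      ymax = .data$chi2_mean + .data$chi2_sd), alpha = 0.2, colour = NA,
      na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~query) +
    ggplot2::labs(y = expression(chi^2), colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Error histogram with its Gamma fit
#'
#' @param errors Positive error values.
#' @param bins Histogram bins.
#' @param title Plot title.
#' @return A ggplot with the fitted Gamma density overlaid.
#' @export
plot_error_histogram <- function(errors, bins = 30, title = NULL) {
  fit <- tryCatch(fit_gamma(errors), error = function(e) NULL)
  p <- ggplot2::ggplot(data.frame(chi2 = errors),
                       ggplot2::aes(x = .data$chi2)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::labs(title = title, x = expression(chi^2), y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(errors), max(errors), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = data.frame(chi2 = xs,
                        density = stats::dgamma(xs, fit$shape, fit$rate)),
      ggplot2::aes(x = .data$chi2, y = .data$density), colour = "firebrick")
  }
  p
}

#' Reconstruction gallery
#'
#' Five-row layout over a set of test samples: input pattern (log scale),
#' true amplitude, predicted amplitude, true phase, predicted phase.
#'
#' @param model A trained `inverter_model`.
#' @param dataset A `cdi_dataset`.
#' @param idx Sample indices to show (default: first 6 validation samples).
#' @return A ggplot.
#' @export
plot_gallery <- function(model, dataset, idx = head(dataset$split$validation, 6)) {
  rows <- list()
  for (k in seq_along(idx)) {
    s <- dataset$samples[[idx[k]]]
    img <- infer(model, s$pattern)
    panels <- list(`1 input` = log1p(s$pattern$intensity),
                   `2 true amp` = s$target_amplitude,
                   `3 pred amp` = img$amplitude,
                   `4 true phase` = s$target_phase_scaled,
                   `5 pred phase` = attr(img, "phase_scaled"))
    for (nm in names(panels)) {
      d <- matrix_df(panels[[nm]], label = nm)
      d$sample <- paste0("sample ", idx[k])
      rows[[length(rows) + 1L]] <- d
    }
  }
  d <- do.call(rbind, rows)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::facet_grid(panel ~ sample, scales = "free") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
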