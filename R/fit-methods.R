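#' @export
print.tuning_fit <- function(x, digits = 3, ...) {
  id <- if (is.null(x$neuron_id)) "" else paste0(" (", x$neuron_id, ")")
  cat("Spectral tuning curve fit", id, "\n", sep = "")
  cat("  weights (S, M, L): ",
      paste(formatC(x$w, digits = digits, format = "g"), collapse = ", "), "\n")
  cat("  alpha: ", formatC(x$alpha, digits = digits, format = "g"),
      "  (half-response b = ", formatC(x$b, digits = digits, format = "g"),
      ")\n", sep = "")
  cat("  weighted cost G: ", formatC(x$cost, digits = digits, format = "g"),
      "   R-squared: ", formatC(x$r_squared, digits = digits, format = "f"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.tuning_fit <- function(object, ...) {
  rw <- object$relative_weights
  structure(list(fit = object, shares = rw$shares,
                 multi_input = rw$multi_input, all_input = rw$all_input,
                 n_points = nrow(object$curve),
                 residual_range = range(object$curve$response -
                                          object$fitted_values)),
            class = "summary.tuning_fit")
}

#' @export
print.summary.tuning_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("  relative input shares: ",
      paste(names(x$shares),
            formatC(x$shares, digits = digits, format = "f"),
            sep = "=", collapse = ", "), "\n")
  cat("  multi-input (>10%): ", x$multi_input,
      "   all-input: ", x$all_input, "\n", sep = "")
  cat("  points: ", x$n_points, "; residual range [",
      formatC(x$residual_range[1], digits = digits, format = "g"), ", ",
      formatC(x$residual_range[2], digits = digits, format = "g"), "]\n",
      sep = "")
  cat("  starts: ", length(x$fit$start_costs), " (best #",
      x$fit$start_index, "), iterations: ", x$fit$n_iter, " [",
      x$fit$stop_reason, "]\n", sep = "")
  invisible(x)
}

#' @export
coef.tuning_fit <- function(object, ...) {
  c(w_S = unname(object$w["S"]), w_M = unname(object$w["M"]),
    w_L = unname(object$w["L"]), alpha = object$alpha)
}

#' Predict model responses at new wavelengths
#'
#' @param object A `tuning_fit`.
#' @param wavelengths Wavelengths (nm) at which to evaluate the fitted
#'   neuron; defaults to the fitted curve's own wavelengths.
#' @param ... Unused.
#' @return Numeric vector of model response changes.
#' @export
predict.tuning_fit <- function(object, wavelengths = NULL, ...) {
  if (is.null(wavelengths)) return(object$fitted_values)
  sweep <- monochromatic_sweep(object$receptors, wavelengths)
  x <- presynaptic_input(tm_response(sweep$E), as.numeric(object$w))
  as.numeric(sigmoid_activation(x, object$alpha, object$config$A0))
}

#' @export
fitted.tuning_fit <- function(object, ...) object$fitted_values

#' @export
residuals.tuning_fit <- function(object, ...) {
  object$curve$response - object$fitted_values
}

#' Plot a fitted tuning curve
#'
#' Measured points against the fitted model curve evaluated on a fine
#' wavelength grid.
#'
#' @param x A `tuning_fit`.
#' @param step Wavelength spacing (nm) for the fitted-curve line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tuning_fit <- function(x, step = 2, ...) {
  lam <- x$curve$wavelength_nm
  gl <- seq(ceiling(min(lam)), floor(max(lam)), by = step)
  yl <- predict(x, gl)
  graphics::plot(lam, x$curve$response, pch = 19,
                 xlab = "wavelength (nm)", ylab = "normalised response change",
                 ylim = range(c(-1, 1, x$curve$response)), ...)
  graphics::lines(gl, yl, col = "steelblue", lwd = 2)
  graphics::abline(h = 0, lty = 3, col = "grey")
  invisible(x)
}

#' Simulate replicate curves from a fitted neuron
#'
#' Draws noisy replicates of the fitted model curve at the original
#' wavelengths (additive Gaussian noise on the normalised response).
#'
#' @param object A `tuning_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param noise_sd Noise standard deviation.
#' @param ... Unused.
#' @return Data frame with one column per replicate, wavelengths as rows.
#' @export
simulate.tuning_fit <- function(object, nsim = 1, seed = NULL,
                                noise_sd = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$fitted_values
  out <- replicate(nsim, base + stats::rnorm(length(base), 0, noise_sd))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "wavelength_nm") <- object$curve$wavelength_nm
  out
}

#' @export
print.tuning_fit_batch <- function(x, digits = 3, ...) {
  cat("Batch of", nrow(x$summary), "tuning-curve fits\n")
  cat("  R-squared range: ",
      paste(formatC(range(x$summary$r_squared), digits = digits,
                    format = "f"), collapse = " - "), "\n")
  cat("  multi-input: ", sum(x$summary$multi_input), "/", nrow(x$summary),
      "; all-input: ", sum(x$summary$all_input), "/", nrow(x$summary),
      "\n", sep = "")
  invisible(x)
}
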