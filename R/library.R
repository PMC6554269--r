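#' Library configuration
#'
#' Settings for generating a population of randomly wired third-order
#' neurons (one per medulla column; default 5500).
#'
#' @param n_neurons Number of neurons.
#' @param weight_sampler Function `(n)` returning an n x 3 matrix of
#'   synaptic weights; default i.i.d. uniform on `[-1, 1]`.
#' @param alpha_range Steepness sampling range (uniform; default `[10, 70]`,
#'   the displayed range of activation slopes).
#' @param t_max_mode `"absolute"` sets each neuron's saturation threshold to
#'   the maximum absolute presynaptic input over the sweep; `"signed"` uses
#'   the signed maximum.
#' @param threshold_rule Passed to [piecewise_thresholds()].
#' @param seed Integer seed.
#' @return A `library_config` list.
#' @export
library_config <- function(n_neurons = 5500, weight_sampler = NULL,
                           alpha_range = c(10, 70),
                           t_max_mode = c("absolute", "signed"),
                           threshold_rule = c("scaled", "literal"),
                           seed = 1L) {
  stopifnot(n_neurons >= 1)
  if (is.null(weight_sampler))
    weight_sampler <- function(n) matrix(stats::runif(3 * n, -1, 1), n, 3)
  structure(list(n_neurons = as.integer(n_neurons),
                 weight_sampler = weight_sampler, alpha_range = alpha_range,
                 t_max_mode = match.arg(t_max_mode),
                 threshold_rule = match.arg(threshold_rule),
                 seed = as.integer(seed)),
            class = "library_config")
}

#' Sample one randomly wired neuron
#'
#' Draws a synaptic weight triplet from the configured sampler (resampling
#' in the degenerate case where all three weights are numerically zero) and
#' a steepness from the configured range. Thresholds are attached later,
#' once the sweep inputs are known (see [set_thresholds()]).
#'
#' @param cfg A [library_config()]. Uses the current RNG state.
#' @return A `third_order_neuron` with piecewise activation (thresholds
#'   unset).
#' @export
sample_neuron <- function(cfg = library_config()) {
  repeat {
    w <- drop(cfg$weight_sampler(1L))
    if (any(abs(w) >= 1e-6)) break
  }
  alpha <- stats::runif(1, cfg$alpha_range[1], cfg$alpha_range[2])
  structure(list(w = stats::setNames(as.numeric(w), c("S", "M", "L")),
                 activation = "piecewise", alpha = alpha,
                 t_min = NULL, t_max = NULL, A0 = 1, baseline = NULL,
                 v = c(-1, -1, -1)),
            class = "third_order_neuron")
}

#' Set piecewise thresholds from sweep inputs
#'
#' Sets the neuron's saturation threshold to the maximum (absolute, by
#' default) presynaptic input over the monochromatic sweep, so every neuron
#' saturates somewhere within the sweep, and derives the lower threshold
#' from the neuron's half-response point (see [piecewise_thresholds()]).
#'
#' @param neuron A `third_order_neuron`.
#' @param x Presynaptic inputs over the sweep.
#' @param mode `"absolute"` or `"signed"`.
#' @param rule Threshold rule, see [piecewise_thresholds()].
#' @return The neuron with `t_min` and `t_max` set.
#' @export
set_thresholds <- function(neuron, x, mode = c("absolute", "signed"),
                           rule = c("scaled", "literal")) {
  mode <- match.arg(mode)
  t_max <- if (mode == "absolute") max(abs(x)) else max(x)
  if (!is.finite(t_max) || t_max <= 0)
    stop("sweep inputs give a non-positive saturation threshold")
  th <- piecewise_thresholds(neuron$alpha, t_max, rule = match.arg(rule))
  neuron$t_min <- th$t_min
  neuron$t_max <- th$t_max
  neuron
}

#' Generate a library of randomly wired neurons
#'
#' Samples `n_neurons` neurons, sets per-neuron thresholds from the sweep,
#' and computes the full matrix of spectral tuning curves. Regeneration with
#' the same seed is bit-identical.
#'
#' @param cfg A [library_config()].
#' @param receptors A `receptor_set`.
#' @param sweep_lambda Wavelengths of the monochromatic sweep (default
#'   300--700 nm every 10 nm).
#' @return A `neuron_library`: list with `neurons`, `curves`
#'   (n_neurons x n_wavelengths, in `[-1, 1]`), `lambda`, and the configs.
#' @export
generate_library <- function(cfg = library_config(),
                             receptors = honeybee_sensitivities(),
                             sweep_lambda = seq(300, 700, by = 10)) {
  sw <- monochromatic_sweep(receptors, sweep_lambda)
  dr <- tm_response(sw$E)                      # n_lambda x 3
  with_seed(cfg$seed, {
    neurons <- vector("list", cfg$n_neurons)
    curves <- matrix(NA_real_, cfg$n_neurons, length(sweep_lambda))
    for (i in seq_len(cfg$n_neurons)) {
      nr <- sample_neuron(cfg)
      x <- drop(dr %*% as.numeric(nr$w))
      nr <- set_thresholds(nr, x, cfg$t_max_mode, cfg$threshold_rule)
      neurons[[i]] <- nr
      curves[i, ] <- piecewise_activation(x, nr$t_min, nr$t_max)
    }
    colnames(curves) <- sweep_lambda
    structure(list(neurons = neurons, curves = curves,
                   lambda = sweep_lambda, config = cfg,
                   receptors = receptors),
              class = "neuron_library")
  })
}

#' @export
print.neuron_library <- function(x, ...) {
  cat("Library of", length(x$neurons), "randomly wired third-order neurons\n")
  cat("  sweep:", min(x$lambda), "-", max(x$lambda), "nm,",
      length(x$lambda), "wavelengths\n")
  cat("  curve range: [", min(x$curves), ",", max(x$curves), "]\n")
  invisible(x)
}

# Locate strict local extrema of one curve, tolerating the flat plateaus the
# piecewise activation produces: equal-value runs are compressed and an
# extremal run is reported at its centre index. Endpoints count when the
# curve approaches them monotonically.
curve_extrema <- function(y, min_prominence) {
  n <- length(y)
  runs <- rle(y)
  k <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  centre <- floor((starts + ends) / 2)
  v <- runs$values
  peaks <- integer(0); troughs <- integer(0)
  for (j in seq_len(k)) {
    is_peak <- (j == 1 || v[j] > v[j - 1]) && (j == k || v[j] > v[j + 1])
    is_trough <- (j == 1 || v[j] < v[j - 1]) && (j == k || v[j] < v[j + 1])
    if (k == 1) next                            # constant curve: no extrema
    if (is_peak) peaks <- c(peaks, centre[j])
    if (is_trough) troughs <- c(troughs, centre[j])
  }
  thr <- min_prominence * max(abs(y))
  list(peaks = peaks[abs(y[peaks]) >= thr],
       troughs = troughs[abs(y[troughs]) >= thr])
}

#' Peak/trough histogram of a neuron library
#'
#' Locates the local maxima (peaks) and minima (troughs) of every tuning
#' curve in the library and aggregates their wavelengths. Extrema must have
#' absolute response at least `min_prominence` times the curve's maximum
#' absolute response; flat saturation plateaus count once, at their centre;
#' endpoints count when approached monotonically.
#'
#' @param lib A `neuron_library`.
#' @param min_prominence Relative prominence threshold (default 0.2).
#' @return An `extrema_histogram`: data frame with `lambda`, `peaks`,
#'   `troughs`, `combined` counts per sweep wavelength.
#' @export
extrema_histogram <- function(lib, min_prominence = 0.2) {
  nl <- length(lib$lambda)
  pk <- integer(nl); tr <- integer(nl)
  for (i in seq_len(nrow(lib$curves))) {
    ex <- curve_extrema(lib$curves[i, ], min_prominence)
    for (j in ex$peaks) pk[j] <- pk[j] + 1L
    for (j in ex$troughs) tr[j] <- tr[j] + 1L
  }
  structure(data.frame(lambda = lib$lambda, peaks = pk, troughs = tr,
                       combined = pk + tr),
            class = c("extrema_histogram", "data.frame"))
}
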