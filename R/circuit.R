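#' Transmedullary cell responses
#'
#' One-to-one inhibitory relay of receptor responses: the firing-rate change
#' of transmedullary cell i is `v_i * E_i`, with presynaptic weights
#' `v_i` in `[-1, 0]` (default all -1, the inhibitory-transmission
#' hypothesis).
#'
#' @param E Receptor responses: length-3 vector or n x 3 matrix in
#'   (S, M, L) order.
#' @param v Length-3 weight vector in `[-1, 0]`.
#' @return Firing-rate changes, same shape as `E`.
#' @export
tm_response <- function(E, v = c(-1, -1, -1)) {
  stopifnot(length(v) == 3, all(v >= -1), all(v <= 0))
  if (is.matrix(E)) {
    stopifnot(ncol(E) == 3)
    sweep(E, 2, v, "*")
  } else {
    stopifnot(length(E) == 3)
    v * E
  }
}

#' Total presynaptic input to a third-order neuron
#'
#' Dot product of the neuron's synaptic weight vector with the
#' transmedullary firing-rate changes.
#'
#' @param delta_r Transmedullary responses: length-3 vector or n x 3 matrix.
#' @param w Length-3 synaptic weight vector (any sign).
#' @return Scalar input x, or vector of inputs for a matrix `delta_r`.
#' @export
presynaptic_input <- function(delta_r, w) {
  stopifnot(length(w) == 3)
  if (is.matrix(delta_r)) drop(delta_r %*% w) else sum(delta_r * w)
}

#' Half-response input of the sigmoidal activation
#'
#' The rule `b = ln(1/99)/alpha + 0.75` anchors all neurons to respond at
#' 0.99 of maximum at input 0.75, regardless of steepness.
#'
#' @param alpha Steepness (> 0).
#' @return Half-response input b.
#' @export
half_response_b <- function(alpha) {
  stopifnot(all(alpha > 0))
  log(1 / 99) / alpha + 0.75
}

#' Sigmoidal activation of third-order neurons
#'
#' Odd-symmetric saturating activation: for x > 0,
#' `F = A0 / (1 + exp(-alpha (x - b)))`; for x < 0 the mirrored negative
#' branch; `F(0) = 0` (the two branches do not meet at 0; the zero value
#' preserves odd symmetry and the no-response-below-threshold reading).
#'
#' @param x Total presynaptic input(s).
#' @param alpha Steepness (> 0).
#' @param A0 Maximum firing-rate change (default 1).
#' @return Activation value(s) in `(-A0, A0)`.
#' @export
sigmoid_activation <- function(x, alpha, A0 = 1) {
  stopifnot(alpha > 0)
  .cpp_sigmoid(as.numeric(x), alpha, A0)
}

#' Piecewise linear activation
#'
#' Fast approximation of the sigmoid: zero inside `(-t_min, t_min)`,
#' saturated at +/-1 beyond `+/-t_max`, linear ramp in between;
#' odd-symmetric.
#'
#' @param x Input(s).
#' @param t_min,t_max Lower and upper thresholds, `0 <= t_min < t_max`.
#' @return Activation value(s) in `[-1, 1]`.
#' @export
piecewise_activation <- function(x, t_min, t_max) {
  if (t_max <= t_min) stop("t_max must exceed t_min")
  if (t_min < 0) stop("t_min must be non-negative")
  ax <- abs(x)
  ramp <- pmin(pmax((ax - t_min) / (t_max - t_min), 0), 1)
  sign(x) * ramp
}

#' Piecewise thresholds matched to a sigmoid
#'
#' Thresholds for the piecewise approximation of a sigmoid of steepness
#' `alpha`: the curve is defined by its maximum-response point `t_max` and
#' its half-response point. At the reference `t_max = 0.75` this is the rule
#' `t_min = t_max - 2 (t_max - b)` with `b` from [half_response_b()]; for
#' other saturation points the half-response input is scaled proportionally
#' (`rule = "scaled"`, default) so the ramp keeps its shape, or the
#' reference rule is applied literally (`rule = "literal"`), clamped into
#' `[0, t_max)`.
#'
#' @param alpha Sigmoid steepness.
#' @param t_max Saturation input (> 0).
#' @param rule `"scaled"` or `"literal"`.
#' @return List with `t_min` and `t_max`.
#' @export
piecewise_thresholds <- function(alpha, t_max = 0.75, rule = c("scaled", "literal")) {
  rule <- match.arg(rule)
  stopifnot(t_max > 0)
  b <- half_response_b(alpha)
  t_min <- if (rule == "scaled") t_max * (2 * b / 0.75 - 1) else 2 * b - t_max
  t_min <- min(max(t_min, 0), t_max * (1 - 1e-9))
  list(t_min = t_min, t_max = t_max)
}

#' Construct a third-order model neuron
#'
#' @param w Length-3 synaptic weights in (S, M, L) order, not all zero.
#' @param activation `"sigmoid"` or `"piecewise"`.
#' @param alpha Sigmoid steepness (sigmoid neurons, and used to derive
#'   piecewise thresholds when `t_min`/`t_max` are not given).
#' @param t_min,t_max Piecewise thresholds (piecewise neurons).
#' @param A0 Maximum firing-rate change.
#' @param baseline Optional baseline firing rate (spikes/s) for the
#'   firing-rate variant.
#' @param v Transmedullary weights.
#' @return A `third_order_neuron` object.
#' @export
third_order_neuron <- function(w, activation = c("sigmoid", "piecewise"),
                               alpha = 30, t_min = NULL, t_max = NULL,
                               A0 = 1, baseline = NULL, v = c(-1, -1, -1)) {
  activation <- match.arg(activation)
  stopifnot(length(w) == 3, all(is.finite(w)))
  if (all(abs(w) < 1e-12)) stop("synaptic weights must not all be zero")
  w <- as.numeric(w)
  names(w) <- c("S", "M", "L")
  if (activation == "piecewise" && (is.null(t_min) || is.null(t_max))) {
    th <- piecewise_thresholds(alpha)
    t_min <- th$t_min; t_max <- th$t_max
  }
  structure(list(w = w, activation = activation, alpha = alpha,
                 t_min = t_min, t_max = t_max, A0 = A0,
                 baseline = baseline, v = v),
            class = "third_order_neuron")
}

#' Spectral tuning curve of a model neuron
#'
#' Response change of a third-order neuron at each wavelength of a
#' monochromatic sweep: receptor responses are relayed through the
#' transmedullary cells, summed with the neuron's synaptic weights, and
#' passed through its activation.
#'
#' @param neuron A `third_order_neuron`.
#' @param sweep A `receptor_sweep` (see [monochromatic_sweep()]).
#' @return Numeric vector of response changes, one per sweep wavelength.
#' @export
tuning_curve <- function(neuron, sweep) {
  dr <- tm_response(sweep$E, neuron$v)
  x <- presynaptic_input(dr, neuron$w)
  if (neuron$activation == "sigmoid") {
    sigmoid_activation(x, neuron$alpha, neuron$A0)
  } else {
    piecewise_activation(x, neuron$t_min, neuron$t_max)
  }
}

#' Firing-rate variant of the neuron response
#'
#' Maps a normalised response change onto actual firing rates around a
#' baseline: excitation scales towards `max_rate`, inhibition scales the
#' baseline down, floored at 0. A variant of the dimensionless model, not
#' the canonical form.
#'
#' @param delta_y Normalised response change(s) in `[-1, 1]`.
#' @param baseline Baseline firing rate (>= 0).
#' @param max_rate Maximum firing rate (> baseline).
#' @return Firing rate(s), >= 0.
#' @export
firing_rate_response <- function(delta_y, baseline, max_rate) {
  stopifnot(baseline >= 0, max_rate > baseline)
  rate <- ifelse(delta_y >= 0,
                 baseline + delta_y * (max_rate - baseline),
                 baseline * (1 + delta_y))
  pmax(rate, 0)
}
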