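#' Synthetic tuning-curve specification
#'
#' Ground-truth parameters and sampling design for one synthetic
#' "empirical" tuning curve: a known weight triplet and steepness, a set of
#' monochromatic test wavelengths, and additive Gaussian measurement noise
#' on the normalised response.
#'
#' @param w True synaptic weights (S, M, L order).
#' @param alpha True steepness.
#' @param lambda Test wavelengths (nm), default 13 points over 310--630 nm.
#' @param noise_sd Noise standard deviation on the normalised response.
#' @param zero_threshold Responses below this absolute value are labelled
#'   `zero` (matches the fitter's weighting semantics).
#' @return A `synthetic_curve_spec` list.
#' @export
synthetic_curve_spec <- function(w, alpha, lambda = seq(310, 630, by = 25),
                                 noise_sd = 0.05, zero_threshold = 0.05) {
  stopifnot(length(w) == 3, alpha > 0, noise_sd >= 0,
            all(lambda >= 300), all(lambda <= 700))
  structure(list(w = as.numeric(w), alpha = alpha, lambda = lambda,
                 noise_sd = noise_sd, zero_threshold = zero_threshold),
            class = "synthetic_curve_spec")
}

#' Generate one synthetic tuning curve
#'
#' Evaluates the circuit model at the spec's wavelengths, adds Gaussian
#' noise, renormalises to maximum absolute response 1, and labels points:
#' the global extremum becomes `peak` (positive) or `trough` (negative),
#' near-zero responses become `zero`, the rest `plain`. Uses the current
#' RNG state.
#'
#' @param spec A [synthetic_curve_spec()].
#' @param receptors A `receptor_set`.
#' @return List with `curve` (data frame ready for [fit_spectral_tuning()]),
#'   `truth` (w, alpha) and `noise_free` (the un-noised normalised curve).
#' @export
make_curve <- function(spec, receptors = honeybee_sensitivities()) {
  neuron <- third_order_neuron(spec$w, "sigmoid", alpha = spec$alpha)
  sw <- monochromatic_sweep(receptors, spec$lambda)
  y0 <- tuning_curve(neuron, sw)
  y <- y0 + stats::rnorm(length(y0), 0, spec$noise_sd)
  m <- max(abs(y))
  if (m > 0) y <- y / m
  cls <- rep("plain", length(y))
  cls[abs(y) < spec$zero_threshold] <- "zero"
  i_ext <- which.max(abs(y))
  cls[i_ext] <- if (y[i_ext] >= 0) "peak" else "trough"
  list(curve = data.frame(wavelength_nm = spec$lambda, response = y,
                          point_class = cls),
       truth = list(w = spec$w, alpha = spec$alpha),
       noise_free = y0 / max(abs(y0)))
}

# Scale a direction vector so the maximum absolute presynaptic input over
# the sweep equals x_peak; keeps every synthetic neuron saturating within
# the tested range, like the normalised empirical curves.
scale_to_peak_input <- function(w, receptors, lambda, x_peak = 1) {
  sw <- monochromatic_sweep(receptors, lambda)
  x <- presynaptic_input(tm_response(sw$E), as.numeric(w))
  m <- max(abs(x))
  if (m == 0) stop("weight direction gives zero input everywhere")
  w * x_peak / m
}

#' Generate a batch of synthetic tuning curves
#'
#' Draws `n_curves` random specifications (Dirichlet-distributed relative
#' weight shares, random excitatory/inhibitory signs, steepness uniform on
#' `alpha_range`, weights scaled so each neuron saturates within the tested
#' wavelengths) and generates the curves reproducibly.
#'
#' @param n_curves Number of curves (22 emulates the empirical study size).
#' @param seed Integer seed.
#' @param noise_sd Measurement-noise sd.
#' @param lambda Test wavelengths.
#' @param alpha_range Steepness range.
#' @param receptors A `receptor_set`.
#' @param x_peak Saturation input reached by every neuron within the sweep.
#' @return A `synthetic_batch`: list with `curves` (named list of data
#'   frames), `truth` (data frame of true parameters) and `noise_free`
#'   (list of noise-free normalised curves).
#' @export
make_batch <- function(n_curves = 22, seed = 1L, noise_sd = 0.05,
                       lambda = seq(310, 630, by = 25),
                       alpha_range = c(10, 70),
                       receptors = honeybee_sensitivities(), x_peak = 1) {
  sw <- monochromatic_sweep(receptors, lambda)
  with_seed(seed, {
    specs <- lapply(seq_len(n_curves), function(i) {
      # Resample specs whose noise-free curve is nearly constant: the
      # emulated recordings are of neurons selected for colour-sensitive
      # (wavelength-dependent) responses, and a flat curve is not a
      # spectral tuning curve.
      repeat {
        shares <- stats::rexp(3)
        shares <- shares / sum(shares)
        signs <- sample(c(-1, 1), 3, replace = TRUE)
        w <- scale_to_peak_input(signs * shares, receptors, lambda, x_peak)
        alpha <- stats::runif(1, alpha_range[1], alpha_range[2])
        y0 <- tuning_curve(third_order_neuron(w, "sigmoid", alpha = alpha), sw)
        if (diff(range(y0)) >= 0.5 * max(abs(y0))) break
      }
      synthetic_curve_spec(w, alpha, lambda, noise_sd)
    })
    assemble_batch(specs, receptors)
  })
}

assemble_batch <- function(specs, receptors) {
  made <- lapply(specs, make_curve, receptors = receptors)
  ids <- sprintf("syn_%02d", seq_along(made))
  curves <- stats::setNames(lapply(made, `[[`, "curve"), ids)
  truth <- do.call(rbind, lapply(seq_along(made), function(i)
    data.frame(neuron_id = ids[i],
               w_S = made[[i]]$truth$w[1], w_M = made[[i]]$truth$w[2],
               w_L = made[[i]]$truth$w[3], alpha = made[[i]]$truth$alpha)))
  nf <- stats::setNames(lapply(made, `[[`, "noise_free"), ids)
  structure(list(curves = curves, truth = truth, noise_free = nf,
                 lambda = specs[[1]]$lambda),
            class = "synthetic_batch")
}

# Fixed design of the 22-curve synthetic stand-in: relative weight shares,
# input signs (negative w = excitatory after the inhibitory relay) and
# steepness for each neuron. Composition mirrors the reported empirical
# population: 3 UV+/blue-green- colour-opponent cells, 15 neurons with all
# three shares > 10%, 5 more with exactly two, 2 single-input; steepness
# spans 10-70. Weight magnitudes follow from the saturation constraint.
km_design <- function() {
  d <- rbind(
    # sS    sM    sL   gS gM gL alpha  category
    c(0.40, 0.32, 0.28, -1, 1, 1, 28), # co: UV+ blue- green-
    c(0.50, 0.25, 0.25, -1, 1, 1, 45), # co: UV+ blue- green-
    c(0.34, 0.33, 0.33, -1, 1, 1, 20), # co: UV+ blue- green-
    c(0.33, 0.33, 0.34,  1, 1, 1, 12), # bb inhibitory
    c(0.30, 0.36, 0.34, -1, -1, -1, 15), # bb excitatory
    c(0.22, 0.39, 0.39,  1, 1, 1, 17), # bb inhibitory
    c(0.30, 0.40, 0.30,  1, -1, 1, 33), # co: M+ S- L-
    c(0.25, 0.30, 0.45,  1, 1, -1, 38), # co: L+ S- M-
    c(0.55, 0.25, 0.20, -1, -1, -1, 60), # s-dominated narrow-band
    c(0.18, 0.27, 0.55, -1, -1, -1, 55), # l-dominated narrow-band
    c(0.20, 0.60, 0.20, -1, -1, -1, 50), # m-dominated narrow-band
    c(0.35, 0.35, 0.30, -1, -1, 1, 30), # co: S+ M+ L-
    c(0.40, 0.25, 0.35,  1, -1, -1, 42), # co: S- M+ L+
    c(0.28, 0.28, 0.44,  1, 1, 1, 22), # bb inhibitory
    c(0.16, 0.42, 0.42, -1, -1, -1, 65), # m-l narrow-band
    c(0.48, 0.48, 0.04, -1, -1, -1, 40), # two-input s-m
    c(0.04, 0.46, 0.50, -1, -1, -1, 35), # two-input m-l
    c(0.50, 0.04, 0.46, -1, 1, 1, 30),   # two-input co S+ L-
    c(0.45, 0.51, 0.04,  1, 1, -1, 26),  # two-input inhibitory s-m
    c(0.04, 0.52, 0.44,  1, 1, 1, 21),   # two-input inhibitory m-l
    c(0.94, 0.03, 0.03, -1, -1, -1, 58), # single-input s narrow-band
    c(0.03, 0.03, 0.94,  1, 1, 1, 48))   # single-input l inhibitory
  colnames(d) <- c("sS", "sM", "sL", "gS", "gM", "gL", "alpha")
  as.data.frame(d)
}

#' Synthetic stand-in for the 22 empirical tuning curves
#'
#' A reproducible batch of 22 synthetic tuning curves emulating the
#' published population of higher-order colour-sensitive bee neurons
#' (8--20 monochromatic test wavelengths, responses normalised to maximum
#' absolute value 1, additive measurement noise). This is a synthetic
#' stand-in -- the digitised recordings themselves are not redistributed
#' here -- with a fixed ground-truth design matching the reported
#' composition of the empirical population (3 UV+/blue-green- colour
#' opponent cells; 15 of 22 neurons with substantial input from all three
#' receptor classes, 20 of 22 from at least two).
#'
#' @param seed Integer seed for the measurement noise.
#' @param noise_sd Noise standard deviation (default 0.05).
#' @param receptors A `receptor_set`.
#' @return A `synthetic_batch` (see [make_batch()]).
#' @export
km_synthetic_batch <- function(seed = 20L, noise_sd = 0.05,
                               receptors = honeybee_sensitivities()) {
  des <- km_design()
  sets <- list(seq(310, 630, by = 25),
               seq(320, 640, by = 20),
               c(334, 356, 380, 404, 428, 452, 476, 500, 524, 548, 572,
                 596, 620))
  with_seed(seed, {
    specs <- lapply(seq_len(nrow(des)), function(i) {
      lam <- sets[[(i - 1L) %% 3L + 1L]]
      dir <- c(des$gS[i] * des$sS[i], des$gM[i] * des$sM[i],
               des$gL[i] * des$sL[i])
      w <- scale_to_peak_input(dir, receptors, lam, x_peak = 1)
      synthetic_curve_spec(w, des$alpha[i], lam, noise_sd)
    })
    assemble_batch(specs, receptors)
  })
}

#' Recovery report for a fitted synthetic batch
#'
#' Compares each fit against the batch's ground truth in curve space
#' (R-squared of the fitted responses against the noise-free generating
#' curve) and in relative-weight space (L1 distance between true and fitted
#' input shares). The fitter never sees the truth; this is evaluation only.
#'
#' @param batch A `synthetic_batch`.
#' @param fits A `tuning_fit_batch` fitted to `batch$curves`.
#' @return List with `per_curve` (data frame: neuron_id, r2_curve,
#'   share_error, alpha_true, alpha_hat) and `summary` (median R-squared,
#'   mean share error).
#' @export
recovery_report <- function(batch, fits) {
  stopifnot(inherits(batch, "synthetic_batch"),
            inherits(fits, "tuning_fit_batch"))
  per <- do.call(rbind, lapply(seq_along(fits$fits), function(i) {
    f <- fits$fits[[i]]
    nf <- batch$noise_free[[i]]
    r2 <- r_squared(nf, f$fitted_values)
    tw <- relative_weights(as.numeric(batch$truth[i, c("w_S", "w_M", "w_L")]))
    err <- sum(abs(tw$shares - f$relative_weights$shares))
    data.frame(neuron_id = f$neuron_id, r2_curve = r2, share_error = err,
               alpha_true = batch$truth$alpha[i], alpha_hat = f$alpha)
  }))
  list(per_curve = per,
       summary = list(median_r2 = stats::median(per$r2_curve),
                      min_r2 = min(per$r2_curve),
                      mean_share_error = mean(per$share_error)))
}
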