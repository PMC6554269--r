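#' Ensemble perceptual distance matrix
#'
#' Perceptual distance between two monochromatic stimuli, defined as the
#' Euclidean distance between the response vectors of the whole neuron
#' library to them, normalised by the matrix maximum.
#'
#' @param lib A `neuron_library`.
#' @param normalise Divide by the maximum distance (default TRUE).
#' @param scale_by_n Additionally divide by `sqrt(n_neurons)` so scales are
#'   comparable across library sizes (applied before normalisation).
#' @return A `distance_matrix`: list with `lambda`, `d` (symmetric, zero
#'   diagonal), `norm_const`.
#' @export
ensemble_distance <- function(lib, normalise = TRUE, scale_by_n = FALSE) {
  # stimuli are the columns of the curve matrix
  make_distance(lib$curves, lib$lambda, normalise,
                if (scale_by_n) sqrt(nrow(lib$curves)) else 1)
}

#' Receptor-space distance matrix
#'
#' Pairwise Euclidean distances between monochromatic stimuli in the
#' three-dimensional receptor space, computed either on quantum catches P
#' or on transduced responses E.
#'
#' @param sweep A `receptor_sweep`.
#' @param space `"transduced"` (E) or `"catch"` (P).
#' @inheritParams ensemble_distance
#' @return A `distance_matrix`.
#' @export
receptor_distance <- function(sweep, space = c("transduced", "catch"),
                              normalise = TRUE) {
  space <- match.arg(space)
  X <- if (space == "transduced") sweep$E else sweep$P
  make_distance(t(X), sweep$lambda, normalise, 1)
}

#' Regular two-channel opponent model
#'
#' Channel weight vectors over (E_S, E_M, E_L) for the classical regular
#' wiring: UV vs blue-green and blue vs UV-green. Each channel is
#' antagonistic (mixed signs).
#'
#' @param ch1,ch2 Length-3 weight vectors in (S, M, L) order.
#' @return An `opponent_model` list.
#' @export
opponent_model <- function(ch1 = c(1, -0.5, -0.5), ch2 = c(-0.5, 1, -0.5)) {
  stopifnot(length(ch1) == 3, length(ch2) == 3)
  if (min(ch1) >= 0 || max(ch1) <= 0 || min(ch2) >= 0 || max(ch2) <= 0)
    stop("opponent channels must have mixed signs")
  structure(list(ch1 = ch1, ch2 = ch2), class = "opponent_model")
}

#' Opponent-model distance matrix
#'
#' Pairwise Euclidean distances between monochromatic stimuli in the
#' two-dimensional space spanned by the opponent channels.
#'
#' @param sweep A `receptor_sweep`.
#' @param model An [opponent_model()].
#' @inheritParams ensemble_distance
#' @return A `distance_matrix`.
#' @export
opponent_distance <- function(sweep, model = opponent_model(),
                              normalise = TRUE) {
  ch <- cbind(drop(sweep$E %*% model$ch1), drop(sweep$E %*% model$ch2))
  make_distance(t(ch), sweep$lambda, normalise, 1)
}

make_distance <- function(cols, lambda, normalise, pre_scale) {
  # cols: one column per stimulus
  d <- unname(as.matrix(stats::dist(t(cols)))) / pre_scale
  dimnames(d) <- NULL
  nc <- if (normalise) max(d) else 1
  if (nc == 0) nc <- 1
  structure(list(lambda = lambda, d = d / nc, norm_const = nc),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Perceptual distance matrix over", length(x$lambda), "wavelengths (",
      min(x$lambda), "-", max(x$lambda), "nm ), max",
      round(max(x$d), 3), "\n")
  invisible(x)
}

#' Signed distance gain between two matrices
#'
#' Elementwise difference `a - b` of two normalised distance matrices on
#' the same wavelength grid (e.g. ensemble minus receptor space: where
#' neural processing enhances perceptual differences).
#'
#' @param a,b `distance_matrix` objects on the same grid.
#' @return A matrix of signed normalised differences.
#' @export
distance_gain <- function(a, b) {
  if (!isTRUE(all.equal(a$lambda, b$lambda)))
    stop("distance matrices are on different wavelength grids")
  a$d - b$d
}

#' Monotone-scaling statistic of a distance matrix
#'
#' Spearman rank correlation between the wavelength difference
#' `|lambda_i - lambda_j|` and the perceptual distance `d(i, j)` over all
#' unordered stimulus pairs. 1 means distance increases monotonically with
#' wavelength difference; 0 (also returned for constant distances) means no
#' monotone relation.
#'
#' @param dm A `distance_matrix`.
#' @return Scalar in `[-1, 1]`.
#' @export
monotonicity_statistic <- function(dm) {
  i <- which(upper.tri(dm$d), arr.ind = TRUE)
  dl <- abs(dm$lambda[i[, 1]] - dm$lambda[i[, 2]])
  dv <- dm$d[upper.tri(dm$d)]
  if (stats::sd(dv) == 0 || stats::sd(dl) == 0) return(0)
  stats::cor(dl, dv, method = "spearman")
}

#' Mean pairwise distance within a spectral region
#'
#' Mean of `d(i, j)` over all unordered pairs whose wavelengths both fall
#' in `[lo, hi]`, optionally restricted to a maximum wavelength difference.
#'
#' @param dm A `distance_matrix`.
#' @param lo,hi Region bounds (nm).
#' @param max_dl Optional cap on `|lambda_i - lambda_j|`, so regions of
#'   equal width are compared at matched wavelength differences.
#' @return Mean distance (scalar).
#' @export
region_mean_distance <- function(dm, lo, hi, max_dl = Inf) {
  keep <- dm$lambda >= lo & dm$lambda <= hi
  sub <- dm$d[keep, keep, drop = FALSE]
  lam <- dm$lambda[keep]
  iu <- which(upper.tri(sub), arr.ind = TRUE)
  dl <- abs(lam[iu[, 1]] - lam[iu[, 2]])
  vals <- sub[upper.tri(sub)]
  mean(vals[dl <= max_dl])
}
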