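#' Wavelength grid
#'
#' Ordered, uniformly spaced wavelengths (nm) on which all spectral
#' quantities are sampled. The default spans the bee visual range used for
#' quantum-catch integration, 300--700 nm at 1 nm.
#'
#' @param start,stop Grid bounds in nm.
#' @param step Grid spacing in nm.
#' @return Numeric vector of wavelengths with class `"wavelength_grid"`.
#' @export
wavelength_grid <- function(start = 300, stop = 700, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            step > 0, stop > start)
  g <- seq(start, stop, by = step)
  structure(g, class = c("wavelength_grid", "numeric"))
}

grid_step <- function(grid) {
  d <- diff(grid)
  if (length(d) == 0L) stop("grid must contain at least two wavelengths")
  if (max(d) - min(d) > 1e-9) stop("wavelength grid must be uniformly spaced")
  d[1]
}

#' Visual pigment template sensitivity
#'
#' Parametric rhodopsin (A1) absorbance template of Govardovskii et al.
#' (2000): an alpha band plus a small beta band, renormalised so the maximum
#' on the grid is exactly 1. Used as the built-in stand-in for tabulated
#' photoreceptor sensitivities; measured curves can be supplied via
#' [read_sensitivities()].
#'
#' @param lambda_max Peak wavelength (nm), within `[300, 700]`.
#' @param grid Wavelength grid (nm).
#' @return Numeric vector of sensitivities in `[0, 1]` on `grid`.
#' @export
pigment_template <- function(lambda_max, grid = wavelength_grid()) {
  stopifnot(lambda_max >= 300, lambda_max <= 700)
  if (lambda_max < min(grid) || lambda_max > max(grid))
    stop("lambda_max lies outside the wavelength grid")
  # locate the raw template's peak on a fine grid, then shift so the
  # returned curve peaks exactly at the nominal lambda_max
  fine <- seq(max(300, lambda_max - 30), min(700, lambda_max + 30), by = 0.1)
  shift <- lambda_max - fine[which.max(template_raw(lambda_max, fine))]
  s <- template_raw(lambda_max, grid - shift)
  s / max(s)
}

template_raw <- function(lambda_max, lambda) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha_band <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                       exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band; omitted for UV pigments, where it merges with the alpha band
  # and would displace the nominal peak
  if (lambda_max >= 380) {
    lmb <- 189 + 0.315 * lambda_max
    bwb <- -40.5 + 0.195 * lambda_max
    beta_band <- 0.26 * exp(-((lambda - lmb) / bwb)^2)
  } else beta_band <- 0
  alpha_band + beta_band
}

#' Honeybee receptor sensitivities
#'
#' The three honeybee photoreceptor spectral sensitivities (S = UV,
#' lambda_max 344 nm; M = blue, 436 nm; L = green, 544 nm), generated from
#' the pigment template on the requested grid.
#'
#' @param grid Wavelength grid.
#' @param lambda_max Named numeric vector of peak wavelengths for S, M, L.
#' @return A `receptor_set`: list with `grid` and an `S` matrix
#'   (length(grid) x 3, columns S, M, L, each peaking at 1).
#' @export
honeybee_sensitivities <- function(grid = wavelength_grid(),
                                   lambda_max = c(S = 344, M = 436, L = 544)) {
  stopifnot(all(c("S", "M", "L") %in% names(lambda_max)))
  S <- vapply(lambda_max[c("S", "M", "L")], pigment_template,
              numeric(length(grid)), grid = grid)
  colnames(S) <- c("S", "M", "L")
  structure(list(grid = grid, S = S, lambda_max = lambda_max[c("S", "M", "L")]),
            class = "receptor_set")
}

#' Read receptor sensitivities from CSV
#'
#' Expects a header `wavelength_nm,S,M,L` with ascending wavelengths and
#' sensitivities in `[0, 1]` (each column is renormalised to peak at 1).
#'
#' @param path CSV file path.
#' @return A `receptor_set` (see [honeybee_sensitivities()]).
#' @export
read_sensitivities <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "S", "M", "L")
  if (!all(need %in% names(df)))
    stop("sensitivity CSV must have columns wavelength_nm,S,M,L")
  if (is.unsorted(df$wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly ascending")
  S <- as.matrix(df[, c("S", "M", "L")])
  if (any(S < 0)) stop("sensitivities must be non-negative")
  S <- sweep(S, 2, apply(S, 2, max), "/")
  grid <- wavelength_grid(min(df$wavelength_nm), max(df$wavelength_nm),
                          grid_step(df$wavelength_nm))
  lm <- df$wavelength_nm[apply(S, 2, which.max)]
  names(lm) <- c("S", "M", "L")
  structure(list(grid = grid, S = S, lambda_max = lm), class = "receptor_set")
}

#' Quantum catch of a receptor
#'
#' Relative amount of light absorbed by one receptor class:
#' `P = R * integral I_S(lambda) S(lambda) D(lambda) dlambda` over the grid
#' (trapezoid rule). For a monochromatic stimulus the integral collapses to
#' `P = R * intensity * S(lambda0) * D(lambda0)` (delta-function convention).
#'
#' @param stimulus Either a single wavelength given as
#'   `list(lambda = , intensity = )` (monochromatic) or a numeric vector of
#'   spectral intensities on `grid` (spectrum).
#' @param sensitivity Numeric sensitivity vector on `grid`.
#' @param grid Wavelength grid shared by all spectral arguments.
#' @param illuminant Numeric vector on `grid`, or a single number for a flat
#'   illuminant (default 1, uniform illumination).
#' @param R Overall sensitivity factor (> 0, default 6).
#' @return Quantum catch P (non-negative scalar).
#' @export
quantum_catch <- function(stimulus, sensitivity, grid = wavelength_grid(),
                          illuminant = 1, R = 6) {
  stopifnot(R > 0)
  if (length(sensitivity) != length(grid))
    stop("sensitivity and grid lengths differ")
  if (any(sensitivity < 0)) stop("sensitivity must be non-negative")
  D <- if (length(illuminant) == 1L) rep(illuminant, length(grid)) else illuminant
  if (length(D) != length(grid)) stop("illuminant and grid lengths differ")
  if (any(D < 0)) stop("illuminant must be non-negative")
  if (is.list(stimulus)) {
    lam <- stimulus$lambda
    scale <- if (is.null(stimulus$intensity)) 1 else stimulus$intensity
    if (scale <= 0) stop("monochromatic intensity must be positive")
    i <- which.min(abs(grid - lam))
    if (abs(grid[i] - lam) > grid_step(grid) / 2 + 1e-9)
      stop("monochromatic wavelength outside grid")
    return(R * scale * sensitivity[i] * D[i])
  }
  if (length(stimulus) != length(grid)) stop("stimulus and grid lengths differ")
  if (any(stimulus < 0)) stop("stimulus must be non-negative")
  integrand <- stimulus * sensitivity * D
  h <- grid_step(grid)
  R * h * (sum(integrand) - (integrand[1] + integrand[length(integrand)]) / 2)
}

#' Normalised receptor response
#'
#' The saturating transduction nonlinearity `E = P / (P + 1)`, mapping
#' quantum catches to dimensionless responses in `[0, 1)`.
#'
#' @param P Quantum catch(es), non-negative.
#' @return Normalised response(s) E.
#' @export
receptor_response <- function(P) {
  if (any(P < 0)) stop("quantum catch must be non-negative")
  P / (P + 1)
}

#' Receptor responses to a monochromatic sweep
#'
#' Responses of the three receptor classes to equal-intensity monochromatic
#' lights at each wavelength of `sweep`.
#'
#' @param receptors A `receptor_set`.
#' @param sweep Wavelengths (nm) of the test lights; defaults to the
#'   receptor set's own grid.
#' @param R Sensitivity factor.
#' @param intensity Common intensity scale of the monochromatic lights.
#' @param illuminant Flat illuminant value (default 1).
#' @return A `receptor_sweep`: list with `lambda` and matrices `E` and `P`
#'   (length(sweep) x 3, columns S, M, L).
#' @export
monochromatic_sweep <- function(receptors, sweep = receptors$grid, R = 6,
                                intensity = 1, illuminant = 1) {
  if (length(sweep) == 0L) stop("empty wavelength sweep")
  idx <- vapply(sweep, function(l) which.min(abs(receptors$grid - l)), 1L)
  if (any(abs(receptors$grid[idx] - sweep) > 1e-6))
    warning("some sweep wavelengths snapped to the sensitivity grid")
  P <- R * intensity * illuminant * receptors$S[idx, , drop = FALSE]
  E <- receptor_response(P)
  dimnames(P) <- dimnames(E) <- list(NULL, c("S", "M", "L"))
  structure(list(lambda = as.numeric(receptors$grid[idx]), E = E, P = P),
            class = "receptor_sweep")
}
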