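# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

test_receptors <- function() memo_fixture("receptors", honeybee_sensitivities())

# the default study-scale library (5500 neurons, 10 nm sweep)
test_library <- function() {
  memo_fixture("lib5500", generate_library(library_config(5500, seed = 3),
                                           test_receptors()))
}

# the synthetic stand-in batch and its fits at desk-scale settings
test_km <- function() {
  memo_fixture("km", {
    batch <- km_synthetic_batch()
    fits <- fit_tuning_batch(batch$curves, test_receptors(),
                             fit_config(n_starts = 5))
    list(batch = batch, fits = fits)
  })
}

random_curve <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(wavelength_nm = sort(sample(seq(310, 640, by = 10), n)),
             response = stats::runif(n, -1, 1),
             point_class = sample(c("peak", "trough", "zero", "plain"), n,
                                  replace = TRUE))
}

# Central finite-difference gradient of the weighted cost. The step is
# scaled to each parameter (alpha is O(10-70), weights O(1)) to balance
# truncation against roundoff in the difference quotient.
fd_gradients <- function(curve, w, alpha, config, h = 1e-5) {
  vapply(1:4, function(i) {
    hi <- if (i < 4) h else h * max(1, alpha)
    cost_at <- function(d) {
      ww <- w; aa <- alpha
      if (i < 4) ww[i] <- ww[i] + d else aa <- aa + d
      weighted_cost(curve, ww, aa, test_receptors(), config)
    }
    (cost_at(hi) - cost_at(-hi)) / (2 * hi)
  }, numeric(1))
}
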