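test_that("weighted cost multiplies squared residuals by the class weights", {
  rec <- test_receptors()
  curve <- random_curve(8, seed = 3)
  w <- c(0.4, -0.6, 0.3); a <- 25
  cfg <- fit_config()
  # oracle: manual composition through the circuit module
  sw <- monochromatic_sweep(rec, curve$wavelength_nm)
  x <- presynaptic_input(tm_response(sw$E), w)
  y <- sigmoid_activation(x, a)
  cm <- cfg$weight_map[curve$point_class]
  expect_equal(weighted_cost(curve, w, a, rec, cfg),
               sum(cm * (y - curve$response)^2))
  # promoting one plain point to peak adds exactly 2x its squared residual
  plain <- curve; plain$point_class <- "plain"
  peak1 <- plain; peak1$point_class[3] <- "peak"
  expect_equal(weighted_cost(peak1, w, a, rec, cfg) -
                 weighted_cost(plain, w, a, rec, cfg),
               2 * (y[3] - curve$response[3])^2)
  # all-plain cost is the unweighted sum of squares
  expect_equal(weighted_cost(plain, w, a, rec, cfg),
               sum((y - curve$response)^2))
  # invariant to point order
  perm <- sample(nrow(curve))
  expect_equal(weighted_cost(curve[perm, ], w, a, rec, cfg),
               weighted_cost(curve, w, a, rec, cfg))
  # perfect reproduction gives zero cost
  exact <- data.frame(wavelength_nm = curve$wavelength_nm, response = y)
  expect_equal(weighted_cost(exact, w, a, rec, cfg), 0)
  expect_error(weighted_cost(curve[1:2, ], w, a, rec, cfg), "at least 4")
})

test_that("analytic gradients match central finite differences", {
  rec <- test_receptors()
  cfg <- fit_config(gradient = "chain")
  set.seed(11)
  for (i in 1:6) {
    curve <- random_curve(10, seed = 100 + i)
    w <- runif(3, -1, 1); a <- runif(1, 10, 70)
    g <- analytic_gradients(curve, w, a, rec, cfg)
    fd <- fd_gradients(curve, w, a, cfg)
    expect_lt(sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)), 1e-5)
  }
  # literal mode differs from chain mode only in the alpha component
  curve <- random_curve(10, seed = 42)
  gl <- analytic_gradients(curve, c(0.5, 0.2, -0.4), 30, rec, fit_config())
  gc <- analytic_gradients(curve, c(0.5, 0.2, -0.4), 30, rec, cfg)
  expect_equal(gl[1:3], gc[1:3])
  expect_false(isTRUE(all.equal(gl[4], gc[4])))
  # zero residuals give zero gradients
  sw <- monochromatic_sweep(rec, curve$wavelength_nm)
  y <- sigmoid_activation(presynaptic_input(tm_response(sw$E),
                                            c(0.5, 0.2, -0.4)), 30)
  exact <- data.frame(wavelength_nm = curve$wavelength_nm, response = y)
  expect_equal(unname(analytic_gradients(exact, c(0.5, 0.2, -0.4), 30, rec, cfg)),
               rep(0, 4))
})

test_that("gradient descent descends, freezes at zero learning rate, and polishes", {
  rec <- test_receptors()
  b <- make_batch(1, seed = 7, noise_sd = 0)
  curve <- b$curves[[1]]
  start <- list(w = c(0.2, -0.1, 0.4), alpha = 15)
  frozen <- gradient_descent(curve, start, rec,
                             fit_config(eta_w = 0, eta_alpha = 0,
                                        max_iter = 500))
  expect_equal(unname(frozen$w), start$w)
  expect_equal(frozen$alpha, start$alpha)
  run <- gradient_descent(curve, start, rec, fit_config(max_iter = 2e4))
  expect_lte(run$cost, weighted_cost(curve, start$w, start$alpha, rec))
  expect_true(all(diff(run$trace) <= 1e-12))  # best-cost trace non-increasing
  # a noise-free synthetic curve is recovered to near-zero cost
  fit <- fit_spectral_tuning(curve, rec, fit_config(n_starts = 8,
                                                    max_iter = 3e5))
  expect_lt(fit$cost, 1e-4)
  expect_gt(fit$r_squared, 0.999)
})

test_that("multi-start fitting is seeded, nested, and reproducible", {
  rec <- test_receptors()
  b <- make_batch(1, seed = 9, noise_sd = 0.05)
  curve <- b$curves[[1]]
  cfg1 <- fit_config(n_starts = 1, max_iter = 2e4, seed = 5)
  cfg5 <- fit_config(n_starts = 5, max_iter = 2e4, seed = 5)
  f1 <- fit_spectral_tuning(curve, rec, cfg1)
  f5 <- fit_spectral_tuning(curve, rec, cfg5)
  expect_lte(f5$cost, f1$cost)           # best-of-5 cannot lose to start 1
  expect_equal(f5$start_costs[1], f1$cost)
  # n_starts = 1 reproduces a single gradient_descent run exactly
  E <- monochromatic_sweep(rec, curve$wavelength_nm)$E
  set.seed(5)
  w0 <- runif(3, -1, 1)
  w0 <- w0 / max(abs(drop(E %*% w0)))
  gd <- gradient_descent(curve, list(w = w0, alpha = 10), rec, cfg1)
  expect_equal(f1$cost, gd$cost)
  expect_equal(f1$w, gd$w)
  # same config twice: bit-identical result
  expect_equal(fit_spectral_tuning(curve, rec, cfg5)$w, f5$w)
})

test_that("relative weight shares classify substantial inputs", {
  rw <- relative_weights(c(1, 1, 1))
  expect_equal(unname(rw$shares), rep(1 / 3, 3))
  expect_true(rw$all_input)
  rw2 <- relative_weights(c(0.95, 0.05, 0))
  expect_equal(unname(rw2$shares), c(0.95, 0.05, 0))
  expect_false(rw2$multi_input)
  # signs do not change shares
  expect_equal(relative_weights(c(-0.95, 0.05, 0))$shares, rw2$shares)
  rw3 <- relative_weights(c(0.5, -0.4, 0.05))
  expect_true(rw3$multi_input)
  expect_false(rw3$all_input)
  expect_error(relative_weights(c(0, 0, 0)))
})

test_that("R-squared matches its definition on hand-checkable cases", {
  expect_equal(r_squared(c(0.2, 0.5, -0.3), c(0.2, 0.5, -0.3)), 1)
  obs <- c(0.2, 0.5, -0.3)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  pred <- c(0.1, 0.4, -0.2)
  expect_equal(r_squared(obs, pred),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
})

test_that("tuning_fit objects support the standard model-object methods", {
  rec <- test_receptors()
  b <- make_batch(2, seed = 13, noise_sd = 0.05)
  fit <- fit_spectral_tuning(b$curves[[1]], rec,
                             fit_config(n_starts = 2, max_iter = 2e4),
                             neuron_id = "demo")
  expect_s3_class(fit, "tuning_fit")
  expect_named(coef(fit), c("w_S", "w_M", "w_L", "alpha"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), b$curves[[1]]$response - fitted(fit))
  expect_length(predict(fit, c(400, 500)), 2)
  expect_output(print(fit), "Spectral tuning curve fit")
  expect_output(print(summary(fit)), "relative input shares")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(b$curves[[1]]), 3))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))

  fits <- fit_tuning_batch(b$curves, rec, fit_config(n_starts = 2,
                                                     max_iter = 2e4))
  expect_equal(nrow(fits$summary), 2)
  expect_output(print(fits), "Batch of 2")
})
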