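test_that("synthetic curves are the model output plus labelled, normalised noise", {
  rec <- test_receptors()
  spec <- synthetic_curve_spec(c(-0.6, 0.3, 0.4), alpha = 25, noise_sd = 0)
  set.seed(2); m1 <- make_curve(spec, rec)
  set.seed(2); m2 <- make_curve(spec, rec)
  expect_identical(m1, m2)
  # noise-free curve equals the normalised model output
  n <- third_order_neuron(spec$w, "sigmoid", alpha = spec$alpha)
  y0 <- tuning_curve(n, monochromatic_sweep(rec, spec$lambda))
  expect_equal(m1$curve$response, y0 / max(abs(y0)))
  expect_equal(max(abs(m1$curve$response)), 1)
  # labels: global extremum is peak/trough, small responses are zero
  i <- which.max(abs(m1$curve$response))
  expect_true(m1$curve$point_class[i] %in% c("peak", "trough"))
  expect_true(all(m1$curve$point_class[abs(m1$curve$response) < 0.05 &
                                         seq_along(m1$curve$response) != i]
                  == "zero"))
  # normalisation preserves the sign pattern (positive rescaling)
  expect_equal(sign(m1$curve$response), sign(y0))
  # with modest noise on a saturating curve, clear responses keep their sign
  b <- km_synthetic_batch(seed = 33, noise_sd = 0.03)
  for (j in c(1, 8, 20)) {
    nf <- b$noise_free[[j]]
    resp <- b$curves[[j]]$response
    clear <- abs(nf) > 0.2
    expect_true(all(sign(resp[clear]) == sign(nf[clear])))
  }
})

test_that("synthetic batches are reproducible with aligned truth tables", {
  b1 <- make_batch(6, seed = 3)
  b2 <- make_batch(6, seed = 3)
  expect_identical(b1, b2)
  expect_length(b1$curves, 6)
  expect_equal(nrow(b1$truth), 6)
  # truth rows regenerate the stored noise-free curves
  rec <- honeybee_sensitivities()
  for (i in c(1, 4)) {
    w <- as.numeric(b1$truth[i, c("w_S", "w_M", "w_L")])
    nr <- third_order_neuron(w, "sigmoid", alpha = b1$truth$alpha[i])
    y0 <- tuning_curve(nr, monochromatic_sweep(rec, b1$lambda))
    expect_equal(b1$noise_free[[i]], y0 / max(abs(y0)))
  }
  # a single-channel spec yields a narrow-band-like curve
  spec <- synthetic_curve_spec(c(-1.2, 0, 0), alpha = 60, noise_sd = 0)
  set.seed(1)
  m <- make_curve(spec, rec)
  sw <- monochromatic_sweep(rec, spec$lambda)
  expect_equal(which.max(m$curve$response), which.max(sw$E[, "S"]))
  expect_lt(mean(abs(m$curve$response) > 0.5), 0.5)  # responds narrowly
})

test_that("the 22-curve stand-in matches its designed composition", {
  b <- km_synthetic_batch()
  expect_length(b$curves, 22)
  expect_identical(b$curves, km_synthetic_batch()$curves)
  truth_rw <- lapply(seq_len(22), function(i)
    relative_weights(as.numeric(b$truth[i, c("w_S", "w_M", "w_L")])))
  expect_equal(sum(vapply(truth_rw, `[[`, TRUE, "multi_input")), 20)
  expect_equal(sum(vapply(truth_rw, `[[`, TRUE, "all_input")), 15)
  # the three colour-opponent cells: UV-excitatory, blue/green-inhibitory
  co <- b$truth[1:3, ]
  expect_true(all(co$w_S < 0 & co$w_M > 0 & co$w_L > 0))
  # every curve is normalised and non-degenerate
  for (cv in b$curves) {
    expect_equal(max(abs(cv$response)), 1)
    expect_gte(nrow(cv), 8)
  }
})

test_that("recovery degrades monotonically with measurement noise", {
  rec <- test_receptors()
  cfg <- fit_config(n_starts = 3, max_iter = 3e4)
  med <- vapply(c(0, 0.2, 0.5), function(ns) {
    b <- make_batch(5, seed = 17, noise_sd = ns)
    f <- fit_tuning_batch(b$curves, rec, cfg)
    rep <- recovery_report(b, f)
    expect_equal(nrow(rep$per_curve), 5)
    rep$summary$median_r2
  }, numeric(1))
  expect_gt(med[1], 0.98)          # near-perfect at zero noise
  expect_true(all(diff(med) < 0))  # monotone degradation
})
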