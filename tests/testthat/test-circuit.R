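test_that("transmedullary relay is a one-to-one weighted (inhibitory) map", {
  expect_equal(tm_response(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(tm_response(c(0.3, 0.5, 0.2), v = c(0, 0, 0)), c(0, 0, 0))
  # blue receptor response 0.5 with v = -1 gives a -0.5 rate change
  expect_equal(unname(tm_response(c(0, 0.5, 0))[2]), -0.5)
  m <- tm_response(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 2, 3))
  expect_equal(m, -matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 2, 3))
  expect_error(tm_response(c(0.1, 0.2, 0.3), v = c(0.5, -1, -1)))
})

test_that("presynaptic input is the weighted sum of relay responses", {
  expect_equal(presynaptic_input(c(-0.2, -0.3, -0.1), c(1, 1, 1)), -0.6)
  expect_equal(presynaptic_input(c(-0.5, 0, 0), c(2, 0, 0)), -1)
  expect_equal(presynaptic_input(c(0, 0, 0), c(0.4, -0.2, 1)), 0)
  m <- matrix(c(-0.2, -0.1, -0.3, -0.2, -0.1, -0.4), 2, 3)
  expect_equal(presynaptic_input(m, c(1, 2, 3)),
               as.numeric(m %*% c(1, 2, 3)))
})

test_that("sigmoid activation is anchored, half-responding at b, and odd", {
  for (a in c(10, 25, 40, 55, 70)) {
    expect_equal(sigmoid_activation(0.75, a), 0.99, tolerance = 1e-12)
    expect_equal(sigmoid_activation(-0.75, a), -0.99, tolerance = 1e-12)
    b <- half_response_b(a)
    expect_equal(sigmoid_activation(b, a), 0.5, tolerance = 1e-9)
    x <- seq(-2, 2, by = 0.13)
    expect_equal(sigmoid_activation(-x, a), -sigmoid_activation(x, a))
  }
  expect_equal(sigmoid_activation(0, 30), 0)
  expect_true(all(abs(sigmoid_activation(seq(-5, 5, 0.1), 20, A0 = 2)) <= 2))
  expect_true(all(abs(sigmoid_activation(seq(-1, 1, 0.05), 15, A0 = 2)) < 2))
  expect_error(sigmoid_activation(0.5, -1))
})

test_that("piecewise activation ramps between thresholds and is odd", {
  expect_equal(piecewise_activation(0.75, 0.3, 0.75), 1)
  expect_equal(piecewise_activation(-0.75, 0.3, 0.75), -1)
  expect_equal(piecewise_activation(0.525, 0.3, 0.75), 0.5)  # ramp midpoint
  expect_equal(piecewise_activation(0.1, 0.3, 0.75), 0)      # dead zone
  # frozen threshold-rule example: alpha 30, t_max 0.75
  th <- piecewise_thresholds(30, 0.75)
  expect_equal(th$t_min, 2 * half_response_b(30) - 0.75, tolerance = 1e-12)
  expect_equal(piecewise_activation(0.5, th$t_min, th$t_max),
               (0.5 - th$t_min) / (0.75 - th$t_min))
  expect_equal(piecewise_activation(0.5, th$t_min, th$t_max), 0.184,
               tolerance = 1e-3)
  x <- seq(-2, 2, by = 0.17)
  expect_equal(piecewise_activation(-x, 0.2, 0.9),
               -piecewise_activation(x, 0.2, 0.9))
  expect_error(piecewise_activation(0.5, 0.8, 0.5), "exceed")
})

test_that("scaled threshold rule reduces to the reference rule at t_max 0.75", {
  for (a in c(15, 30, 50, 70)) {
    sc <- piecewise_thresholds(a, 0.75, rule = "scaled")
    li <- piecewise_thresholds(a, 0.75, rule = "literal")
    expect_equal(sc$t_min, li$t_min, tolerance = 1e-12)
    # rescaling t_max preserves the ramp shape under the scaled rule
    sc2 <- piecewise_thresholds(a, 1.5, rule = "scaled")
    expect_equal(sc2$t_min / sc2$t_max, sc$t_min / sc$t_max,
                 tolerance = 1e-12)
  }
  # small alpha would give a negative dead zone; clamped at 0
  expect_equal(piecewise_thresholds(10, 0.75)$t_min, 0)
})

test_that("piecewise approximation tracks the sigmoid at its anchor points", {
  for (a in c(15, 25, 40, 55, 70)) {
    th <- piecewise_thresholds(a, 0.75)
    b <- half_response_b(a)
    for (x in c(0, b, 0.75)) {
      d <- abs(sigmoid_activation(x, a) -
                 piecewise_activation(x, th$t_min, th$t_max))
      expect_lte(d, 0.07)
    }
  }
})

test_that("tuning curves follow the receptor -> relay -> activation chain", {
  rec <- test_receptors()
  sw <- monochromatic_sweep(rec, seq(300, 700, by = 5))
  # single-channel neuron peaks where its receptor's transduced response peaks
  n_uv <- third_order_neuron(c(-1, 0, 0), "sigmoid", alpha = 20)
  y <- tuning_curve(n_uv, sw)
  expect_equal(which.max(y), which.max(sw$E[, "S"]))
  # curve shape is monotone in that receptor's response before thresholding
  expect_gte(cor(y, sw$E[, "S"], method = "spearman"), 0.99)
  # all-zero receptor input gives zero response
  sw0 <- sw
  sw0$E <- sw$E * 0
  expect_equal(tuning_curve(n_uv, sw0), rep(0, nrow(sw$E)))
  # inhibitory front end: positive weights + v = -1 can only suppress
  n_inh <- third_order_neuron(c(1, 1, 1), "sigmoid", alpha = 20)
  y_inh <- tuning_curve(n_inh, sw)
  expect_true(all(y_inh <= 0))
  # increasing any receptor response decreases the output
  e1 <- c(0.2, 0.3, 0.1); e2 <- e1 + c(0.2, 0, 0)
  x1 <- presynaptic_input(tm_response(e1), c(1, 1, 1))
  x2 <- presynaptic_input(tm_response(e2), c(1, 1, 1))
  expect_lt(sigmoid_activation(x2, 30), sigmoid_activation(x1, 30))
})

test_that("firing-rate variant maps response changes onto bounded rates", {
  expect_equal(firing_rate_response(0, 20, 100), 20)
  expect_equal(firing_rate_response(-1, 20, 100), 0)
  expect_equal(firing_rate_response(1, 20, 100), 100)
  d <- seq(-1, 1, by = 0.05)
  r <- firing_rate_response(d, 35, 120)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r <= 120))
  expect_error(firing_rate_response(0, 50, 40))
})
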