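test_that("pigment template gives normalised unimodal sensitivities at the stated peaks", {
  grid <- wavelength_grid()
  s <- pigment_template(436, grid)
  expect_equal(grid[which.max(s)], 436)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(max(s), 1)

  rec <- test_receptors()
  peaks <- as.numeric(rec$grid[apply(rec$S, 2, which.max)])
  expect_equal(peaks, c(344, 436, 544))
  expect_error(pigment_template(250, grid))
  expect_error(pigment_template(500, wavelength_grid(300, 400)))
})

test_that("quantum catch matches closed forms and is linear in intensity", {
  grid <- wavelength_grid()
  s436 <- pigment_template(436, grid)
  # monochromatic at the peak: P = R * scale * S(lambda_max) = 6
  expect_equal(quantum_catch(list(lambda = 436, intensity = 1), s436,
                             grid, R = 6), 6)
  # zero stimulus
  expect_equal(quantum_catch(rep(0, length(grid)), s436, grid), 0)
  # unit triangle of half-width 50 nm: area 50, trapezoid exact for a
  # piecewise-linear integrand on a 1 nm grid
  tri <- pmax(0, 1 - abs(grid - 500) / 50)
  expect_equal(quantum_catch(rep(1, length(grid)), tri, grid, R = 6),
               6 * 50, tolerance = 1e-12)
  # linearity in intensity scale
  p1 <- quantum_catch(list(lambda = 400, intensity = 1), s436, grid)
  p3 <- quantum_catch(list(lambda = 400, intensity = 3), s436, grid)
  expect_equal(p3, 3 * p1)
  # errors
  expect_error(quantum_catch(rep(1, 10), s436, grid), "lengths differ")
  expect_error(quantum_catch(rep(-1, length(grid)), s436, grid))
  expect_error(quantum_catch(list(lambda = 400), s436, grid, R = -1))
})

test_that("transduction is the saturating E = P/(P+1) nonlinearity", {
  expect_equal(receptor_response(0), 0)
  expect_equal(receptor_response(1), 0.5)
  expect_equal(receptor_response(6), 6 / 7)
  expect_error(receptor_response(-0.1))
  p <- seq(0, 50, by = 0.5)
  e <- receptor_response(p)
  expect_true(all(diff(e) > 0))
  expect_true(all(e < 1))
  # composed response is concave in stimulus intensity
  f <- function(s) receptor_response(6 * s * 0.8)
  a <- 0.3; b <- 2.5
  expect_gte(f((a + b) / 2), (f(a) + f(b)) / 2)
})

test_that("monochromatic sweep composes catch and transduction exactly", {
  rec <- test_receptors()
  lam <- seq(320, 620, by = 50)
  sw <- monochromatic_sweep(rec, lam)
  expect_equal(nrow(sw$E), length(lam))
  # compositional oracle: per-wavelength quantum_catch + receptor_response
  for (i in seq_along(lam)) {
    for (j in 1:3) {
      p <- quantum_catch(list(lambda = lam[i]), rec$S[, j], rec$grid)
      expect_equal(unname(sw$P[i, j]), p)
      expect_equal(unname(sw$E[i, j]), receptor_response(p))
    }
  }
  # S channel dominates at its own peak
  sw344 <- monochromatic_sweep(rec, 344)
  expect_equal(which.max(sw344$E[1, ]), c(S = 1))
  expect_error(monochromatic_sweep(rec, numeric(0)), "empty")
})

test_that("spectrum-stimulus catch is robust to halving the grid spacing", {
  g1 <- wavelength_grid(300, 700, 1)
  g05 <- wavelength_grid(300, 700, 0.5)
  for (lm in c(344, 436, 544)) {
    p1 <- quantum_catch(rep(1, length(g1)), pigment_template(lm, g1), g1)
    p05 <- quantum_catch(rep(1, length(g05)), pigment_template(lm, g05), g05)
    expect_lt(abs(p1 - p05) / p05, 0.01)
  }
})

test_that("sensitivity CSV round-trips and rejects malformed input", {
  rec <- test_receptors()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  df <- data.frame(wavelength_nm = as.numeric(rec$grid),
                   S = rec$S[, 1], M = rec$S[, 2], L = rec$S[, 3])
  write.csv(df, path, row.names = FALSE)
  rec2 <- read_sensitivities(path)
  expect_equal(rec2$S, rec$S, ignore_attr = TRUE)
  # CSV serialisation can tie near-1 values at the peak; allow grid jitter
  expect_true(all(abs(unname(rec2$lambda_max) - c(344, 436, 544)) <= 2))

  bad <- df[, c(1, 2, 3)]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_sensitivities(path), "columns")
})
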