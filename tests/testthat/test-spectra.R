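test_that("VACF is normalized, cosine-faithful and time-reversal symmetric", {
  dt <- 0.5
  n <- 6000
  om0 <- cm1_to_omega_au(1500)
  t_au <- (0:(n - 1)) * dt * rd_constants$fs_au
  V <- matrix(cos(om0 * t_au), ncol = 1)
  attr(V, "dt") <- dt
  cv <- vacf(V, "centroid", max_lag_fs = 800, masses_per_col = 2)
  expect_identical(cv$c[1], 1)
  expect_lt(max(abs(cv$c - cos(om0 * cv$lags * rd_constants$fs_au))), 2e-3)

  Vr <- V[n:1, , drop = FALSE]
  attr(Vr, "dt") <- dt
  cvr <- vacf(Vr, "centroid", max_lag_fs = 800, masses_per_col = 2)
  expect_equal(cvr$c, cv$c, tolerance = 1e-12)

  V1 <- V[1, , drop = FALSE]
  attr(V1, "dt") <- dt
  expect_error(vacf(V1, "centroid", masses_per_col = 1), "empty|shorter")
})

test_that("VDOS resolves a cosine line and flattens white correlation", {
  dt <- 0.5
  om0 <- cm1_to_omega_au(2000)
  lags <- (0:2000) * dt
  cv <- structure(list(lags = lags, c = cos(om0 * lags * rd_constants$fs_au),
                       dt = dt), class = "rd_vacf")
  sp <- vdos(cv)
  expect_lt(abs(peak_position(sp, c(1500, 2500)) - 2000), 4)
  expect_true(all(sp$values >= 0))

  # delta correlation at zero lag -> flat spectrum
  cw <- structure(list(lags = lags, c = c(1, numeric(2000)), dt = dt),
                  class = "rd_vacf")
  sw <- vdos(cw, window = "none")
  expect_lt(diff(range(sw$values)) / mean(sw$values), 1e-8)
})

test_that("z transform preserves areas and maps peaks to squared frequencies", {
  wT <- omega_thermal(400, "cm-1")
  omega <- seq(1, 8000, by = 1)
  vals <- dnorm(omega, 3000, 30)
  s <- spectrum(omega, vals, "cl")
  grid <- zgrid((8000 / wT)^2, 0.05)
  g <- to_z(s, wT, grid)
  expect_lt(abs(spectrum_area(g) - spectrum_area(s)) / spectrum_area(s), 1e-8)
  zpk <- g$z[which.max(g$values)]
  expect_lt(abs(zpk - (3000 / wT)^2), 2 * grid$spacing)

  # round trip back to omega
  s2 <- from_z(g)
  expect_lt(abs(spectrum_area(s2) - spectrum_area(s)) / spectrum_area(s), 1e-6)
  expect_lt(abs(peak_position(s2, c(2800, 3200)) - 3000), 5)

  # equal-area doublet at omega and 2 omega keeps equal z areas
  s3 <- spectrum(omega, dnorm(omega, 1500, 25) + dnorm(omega, 3000, 25), "cl")
  g3 <- to_z(s3, wT, grid)
  zc <- (c(1500, 3000) / wT)^2
  a1 <- sum(g3$values[abs(g3$z - zc[1]) < 5]) * grid$spacing
  a2 <- sum(g3$values[abs(g3$z - zc[2]) < 5]) * grid$spacing
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("convolution operator replicates peaks at the mode offsets", {
  grid <- zgrid(60, 0.05)
  op <- pi_convolution_operator(2, grid)
  e <- numeric(grid$n)
  i0 <- 101                              # z0 = 5
  e[i0] <- 1
  out <- apply_pi_operator(op, e)
  expect_equal(out[i0], 0.5)
  expect_equal(out[i0 + 80], 0.5)        # z0 + 4
  expect_equal(sum(out != 0), 2L)

  expect_equal(apply_pi_operator(op, numeric(grid$n)), numeric(grid$n))

  A <- pi_operator_matrix(op)
  cs <- colSums(A)
  interior <- 1:(grid$n - 81)
  expect_true(all(abs(cs[interior] - 1) < 1e-12))  # unit column sums
})

test_that("deconvolution inverts the forward model and respects bounds", {
  fx <- generate_fixture_spectrum(fixture_spec(peaks = c(1600, 3700),
                                               areas = c(1, 2), seed = 11))
  dec <- deconvolve(fx$g_pi, fx$operator, deconv_config())
  # noiseless round trip: peak bins exact, areas within 1%
  for (i in 1:2) {
    pk <- c(1600, 3700)[i]
    zc <- (pk / fx$omega_T_cm1)^2
    sel <- abs(fx$g_cl$z - zc) < 8
    expect_lt(abs(fx$g_cl$z[sel][which.max(dec$values[sel])] -
                  fx$g_cl$z[sel][which.max(fx$g_cl$values[sel])]),
              1.5 * fx$g_cl$grid$spacing)
    expect_lt(abs(sum(dec$values[sel]) / sum(fx$g_cl$values[sel]) - 1), 0.01)
  }
  expect_true(all(dec$values >= 0))
  # zero above the physical cutoff
  zphys <- (5000 / fx$omega_T_cm1)^2
  expect_true(all(dec$values[dec$z > zphys] == 0))

  # zero input -> zero output
  g0 <- fx$g_pi
  g0$values[] <- 0
  d0 <- deconvolve(g0, fx$operator, deconv_config())
  expect_true(all(d0$values == 0))

  # grid mismatch is refused
  other <- pi_convolution_operator(2, zgrid(50, 0.05))
  expect_error(deconvolve(fx$g_pi, other), "grid")
})

test_that("noisy deconvolution stays non-negative with two resolved peaks", {
  fx <- generate_fixture_spectrum(fixture_spec(peaks = c(1600, 3700),
                                               noise = 0.01, seed = 21))
  dec <- deconvolve(fx$g_pi, fx$operator, deconv_config())
  expect_true(all(dec$values >= 0))
  spd <- from_z(dec)
  for (pk in c(1600, 3700)) {
    sel <- abs(spd$omega - pk) < 250
    expect_gt(max(spd$values[sel]), 10 * max(1e-12, stats::median(spd$values)))
  }
})

test_that("projected-gradient solver matches Lawson-Hanson NNLS", {
  fx <- generate_fixture_spectrum(fixture_spec(peaks = 2500, widths = 120,
                                               P = 4, dz = 1, seed = 5,
                                               artifact_max = 6000))
  pg <- deconvolve(fx$g_pi, fx$operator,
                   deconv_config(artifact_max = 6000, physical_max = 4000,
                                 objective_min = 0))
  lh <- deconvolve(fx$g_pi, fx$operator,
                   deconv_config(artifact_max = 6000, physical_max = 4000,
                                 objective_min = 0, solver = "lawson-hanson"))
  expect_lt(max(abs(pg$values - lh$values)) / max(lh$values), 1e-6)
})

test_that("quantum correction amplifies only high frequencies", {
  wT <- omega_thermal(400, "cm-1")
  w1 <- weight_table_p1(omega_max = 30)
  omega <- seq(1, 10000, by = 2)
  lowpk <- spectrum(omega, dnorm(omega, 0.02 * wT, 0.004 * wT), "dec")
  q <- quantum_correct(lowpk, w1, wT)
  expect_lt(max(abs(q$values - lowpk$values)) / max(lowpk$values), 1e-3)

  # delta near omega' = 1 scales by w(1) = coth(1)
  onepk <- spectrum(omega, dnorm(omega, wT, 2), "dec")
  q1 <- quantum_correct(onepk, w1, wT)
  expect_equal(spectrum_area(q1) / spectrum_area(onepk), weight_p1(1),
               tolerance = 1e-3)

  zero <- spectrum(omega, numeric(length(omega)), "dec")
  expect_equal(quantum_correct(zero, w1, wT)$values, zero$values)

  # range mismatch is refused
  expect_error(quantum_correct(onepk, weight_table_p1(omega_max = 2), wT),
               "cover")
})

test_that("peak positions interpolate below the bin width", {
  x <- seq(100, 200, by = 5)
  y <- exp(-(x - 162)^2 / 50)
  s <- spectrum(x, y, "cl")
  expect_lt(abs(peak_position(s) - 162), 0.5)
  expect_lt(abs(peak_position(s, method = "centroid") - 162), 3)
})
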