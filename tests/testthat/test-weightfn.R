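test_that("normal-mode offsets match the diagonalized ring-polymer Hessian", {
  # independent oracle: eigenvalues of the cyclic Hessian at omega = 0,
  # reduced by omega_T^2 (omega_T = 2 omega_P / P)
  for (P in c(2L, 4L, 7L)) {
    omegaP <- 3.7          # arbitrary chain frequency
    omegaT <- 2 * omegaP / P
    ev <- ring_hessian_freqs2(P, 0, omegaP) / omegaT^2
    expect_equal(sort(c(0, normal_mode_offsets(P))), ev, tolerance = 1e-10)
  }
  expect_equal(normal_mode_offsets(2), 4)
  expect_equal(normal_mode_offsets(4), c(8, 16, 8))
})

test_that("offsets are palindromic and invalid P is refused", {
  for (P in c(3, 5, 8, 16)) {
    ck <- normal_mode_offsets(P)
    expect_equal(ck, rev(ck))
    expect_true(all(ck > 0))
  }
  expect_error(normal_mode_offsets(1), "P must be")
  expect_error(normal_mode_offsets(2.5), "P must be")
})

test_that("single-bead weight has the classical limit and asymptote", {
  expect_identical(weight_p1(0), 1)
  # high-frequency asymptote: w - x = 2 x exp(-2x)/(1 - exp(-2x))
  expect_lt(abs(weight_p1(10) - 10), 5e-8)
  expect_gt(abs(weight_p1(10) - 10), 1e-9)   # but not exactly x
  # quadruple-precision closed-form oracle at omega' = 1
  expect_equal(weight_p1(1), 1^2 * ringdeconv:::cpp_coth_over_x_quad(1),
               tolerance = 1e-14)
  expect_error(weight_p1(-0.1), "must be >= 0")
})

test_that("eta kernel snaps offsets onto the grid and applies as a convolution", {
  g <- zgrid(100, 4)
  k2 <- build_eta_kernel(2, g)
  expect_equal(which(k2$band != 0) - 1L, c(0L, 1L))
  # impulse response reproduces the kernel itself
  e1 <- numeric(g$n); e1[5] <- 1
  out <- kernel_apply(k2, e1)
  expect_equal(out[5], 1)
  expect_equal(out[6], 1)
  expect_equal(sum(out != 0), 2L)

  g8 <- zgrid(100, 8)
  k4 <- build_eta_kernel(4, g8)
  expect_equal(which(k4$band != 0) - 1L, c(0L, 1L, 2L))
  expect_equal(k4$band[2], 2)  # doubly degenerate c = 8

  # linearity
  set.seed(1)
  v1 <- runif(g8$n); v2 <- runif(g8$n)
  expect_equal(kernel_apply(k4, v1 + v2),
               kernel_apply(k4, v1) + kernel_apply(k4, v2))

  # misaligned spacing for irrational offsets is refused
  expect_error(build_eta_kernel(8, zgrid(100, 0.05)), "misalignment")
})

test_that("first iterates equal the documented initialization", {
  g <- zgrid(60, 0.05)
  # both routes initialize from the asymptotic first approximation a = b/P,
  # so the 1-step Toeplitz solve and the 0-step fixed point coincide
  tb1 <- solve_weights_toeplitz(2, grid = g, n_iter = 1)
  fp0 <- solve_weights_fixed_point(2, grid = g, n_iter = 0)
  expect_equal(fp0$iterations, 0L)
  expect_equal(fp0$w, tb1$w, tolerance = 1e-12)
  expect_equal(tb1$w, 1 + g$z_values * tb1$a, tolerance = 1e-12)
})

test_that("unsupported bead counts are refused with the documented failure", {
  expect_error(solve_weights_toeplitz(64), "unsupported")
  expect_error(solve_weights_toeplitz(33), "unsupported")
  expect_error(solve_weights_fixed_point(64), "unsupported")
})

test_that("quadruple-precision backend reproduces the double-precision solve", {
  g <- zgrid(80, 0.05)
  td <- solve_weights_toeplitz(3, grid = g, n_iter = 500, precision = "double")
  tq <- solve_weights_toeplitz(3, grid = g, n_iter = 500, precision = "quad")
  expect_equal(td$w, tq$w, tolerance = 1e-10)
  expect_identical(tq$precision, "quad")
})

test_that("converged small-grid solves satisfy the functional equation", {
  for (P in c(2, 4)) {
    tb <- cached_table(paste0("tb_small_", P),
                       function() solve_weights_toeplitz(P, n_iter = 4000,
                                                         z_max = 150))
    r <- residual_functional_equation(tb)
    expect_lt(max(r$residual), 5e-4)
    expect_equal(tb$w[1], 1)              # exact classical limit
    expect_true(all(tb$w > 0))
  }
})

test_that("classical weights fail the quantum target at high frequency", {
  x <- seq(0.001, 15, by = 0.01)
  unit <- ringdeconv:::new_weight_table(2L, x, rep(1, length(x)),
                                        "fixed_point", 0L)
  r <- residual_functional_equation(unit)
  # residual ~ 1 - 2/(omega' coth omega') grows toward 1
  expect_gt(max(r$residual), 0.5)
  expect_gt(r$residual[length(r$residual)], r$residual[10])
})

test_that("P = 1 closed form solves its equation to near machine precision", {
  w1 <- weight_table_p1()
  r <- residual_functional_equation(w1)
  expect_lte(max(r$residual), 1e-10)
})

test_that("centroid-excluded variant starts at the lowest internal mode", {
  tb <- solve_weights_toeplitz(4, n_iter = 2000, z_max = 150,
                               centroid_excluded = TRUE)
  expect_true(tb$centroid_excluded)
  expect_equal(min(tb$omega_red), sqrt(min(normal_mode_offsets(4))),
               tolerance = 1e-10)
  r <- residual_functional_equation(tb)
  expect_lt(max(r$residual), 5e-3)
})

test_that("weight tables interpolate and reject out-of-range probes", {
  tb <- weight_table_p1(omega_max = 5)
  expect_equal(weight_at(tb, c(0.5, 2.5)), weight_p1(c(0.5, 2.5)),
               tolerance = 1e-8)
  expect_error(weight_at(tb, 6), "outside")
})

test_that("spacing search returns commensurate spacings for small P", {
  for (P in c(2, 3, 4, 6)) {
    s <- choose_z_spacing(P)
    expect_true(s$commensurate)
    expect_lt(s$snap_error, 1e-9)
  }
  s16 <- suppressWarnings(choose_z_spacing(16))
  expect_lt(s16$snap_error, s16$spacing / 15)
})
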