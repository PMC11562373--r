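test_that("ring-polymer energies match hand evaluations", {
  h <- make_harmonic(1000)
  # collapsed ring at the minimum: everything zero
  st <- initial_state(h$model, h$mass, 4, 300)
  e <- ring_polymer_energy(st, h$model)
  expect_equal(e$kinetic, 0)
  expect_equal(e$spring, 0)
  expect_equal(e$potential, 0)

  # P = 2, one bead displaced by d in 1D: two springs of 1/2 m wP^2 d^2
  d <- 0.3
  st2 <- initial_state(h$model, h$mass, 2, 300)
  st2$x[2, 1] <- d
  e2 <- ring_polymer_energy(st2, h$model)
  expect_equal(e2$spring, h$mass * st2$omega_P^2 * d^2, tolerance = 1e-12)
  expect_equal(e2$potential, 0.5 * h$mass * h$omega^2 * d^2 / 2,  # bead average
               tolerance = 1e-12)

  # kinetic energy is quadratic in the velocities
  set.seed(4)
  st2$v[] <- rnorm(length(st2$v))
  k1 <- ring_polymer_energy(st2, h$model)$kinetic
  st2$v <- 2 * st2$v
  expect_equal(ring_polymer_energy(st2, h$model)$kinetic, 4 * k1)
})

test_that("normal-mode transform is orthogonal with a centroid zeroth mode", {
  h <- make_harmonic()
  st <- initial_state(h$model, h$mass, 8, 300)
  st$x[, 1] <- 1.7                      # uniform displacement
  q <- normal_mode_transform(st)
  expect_equal(q$q[1, 1], sqrt(8) * 1.7, tolerance = 1e-12)
  expect_equal(max(abs(q$q[-1, 1])), 0, tolerance = 1e-12)

  set.seed(8)
  st$x[] <- rnorm(length(st$x)); st$v[] <- rnorm(length(st$v))
  q <- normal_mode_transform(st)
  st2 <- st; st2$x <- q$q; st2$v <- q$qdot
  back <- normal_mode_transform(st2, inverse = TRUE)
  expect_equal(back$q, st$x, tolerance = 1e-12)
  expect_equal(back$qdot, st$v, tolerance = 1e-12)
})

test_that("free ring-polymer modes oscillate at the analytic frequencies", {
  # nearly free particle (negligible k); spectral peak of a mode-velocity
  # series against 2 omega_P sin(k pi / P), the frequencies whose squares
  # give the weight-equation offsets via omega_k^2 = c_k omega_T^2
  P <- 4
  h <- make_harmonic(1e-4)              # ~0 force constant
  st <- initial_state(h$model, h$mass, P, 300)
  set.seed(3)
  st <- sample_velocities(st)
  tr <- integrate_rpmd(st, h$model,
                       simulation_config(dt = 0.5, n_steps = 8192,
                                         temperature = 300, thermostat = "none",
                                         constrain_1d = TRUE,
                                         record_beads = TRUE))
  C <- ringdeconv:::nm_matrix(P)
  vb <- tr$bead_velocities[, seq(1, 3 * P, by = 3)]   # x components per bead
  vk <- vb %*% t(C)                     # mode velocities over time
  omegaT <- 2 / st$beta
  for (k in 2:3) {                      # first two internal modes
    V <- matrix(vk[, k], ncol = 1); attr(V, "dt") <- tr$dt
    cv <- vacf(V, "centroid", max_lag_fs = 1500, masses_per_col = 1)
    sp <- vdos(cv)
    want <- omega_au_to_cm1(free_ring_frequencies(P, st$beta)[k])
    got <- peak_position(sp, want + c(-300, 300))
    expect_lt(abs(got - want), 12)      # within ~2 bins
    # and consistency with the offsets: omega_k^2 = c_k * omega_T^2
    expect_equal(free_ring_frequencies(P, st$beta)[k]^2,
                 normal_mode_offsets(P)[k - 1] * omegaT^2, tolerance = 1e-12)
  }
})

test_that("identical seeds give bit-identical trajectories", {
  h <- make_harmonic()
  st <- initial_state(h$model, h$mass, 4, 300)
  cfg <- simulation_config(dt = 0.5, n_steps = 200, temperature = 300,
                           thermostat = "pile", seed = 77, constrain_1d = TRUE)
  t1 <- integrate_pimd(st, h$model, cfg)
  t2 <- integrate_pimd(st, h$model, cfg)
  expect_identical(t1$centroid_velocities, t2$centroid_velocities)
  expect_identical(t1$estimators, t2$estimators)
})

test_that("PIMD equipartition holds for the bead kinetic energy", {
  h <- make_harmonic(800)
  P <- 4
  st <- initial_state(h$model, h$mass, P, 300)
  set.seed(5)
  st <- sample_velocities(st)
  beta <- st$beta
  kes <- sapply(1:8, function(i) {
    tr <- integrate_pimd(st, h$model, simulation_config(
      dt = 0.5, n_steps = 6000, temperature = 300, thermostat = "pile",
      pile_tau = 50, seed = 40 + i, constrain_1d = TRUE))
    mean(tr$estimators$kinetic_cl[-(1:1000)]) / P   # per bead, 1 dof
  })
  se <- sd(kes) / sqrt(length(kes))
  expect_lt(abs(mean(kes) - P / (2 * beta)), 3 * se + 1e-12)
})

test_that("RPMD conserves energy and the harmonic centroid keeps its frequency", {
  h <- make_harmonic(1200)
  P <- 8
  st <- initial_state(h$model, h$mass, P, 300)
  set.seed(6)
  st <- sample_velocities(st)
  eq <- integrate_pimd(st, h$model, simulation_config(
    dt = 0.25, n_steps = 4000, temperature = 300, thermostat = "pile",
    pile_tau = 100, seed = 9, constrain_1d = TRUE))
  tr <- integrate_rpmd(eq$state, h$model, simulation_config(
    dt = 0.25, n_steps = 20000, temperature = 300, thermostat = "none",
    constrain_1d = TRUE))
  expect_lt(tr$energy_drift, 1e-5)
  e <- tr$estimators$conserved
  expect_lt(abs(e[length(e)] - e[1]) / abs(e[1]), 1e-2)
  # centroid decouples exactly for a harmonic potential
  cv <- vacf(tr, "centroid", max_lag_fs = 1500)
  sp <- vdos(cv)
  expect_lt(abs(peak_position(sp, c(800, 1600)) - 1200), 10)
})

test_that("global translation and rotation are removed per replica", {
  w <- water_model()
  st <- initial_state(w$model, w$masses, 4, 380.8)
  set.seed(7)
  st <- sample_velocities(st)
  # add a rigid drift and a rigid rotation to every bead
  for (j in 1:4) {
    xj <- matrix(st$x[j, ], 3, 3, byrow = TRUE)
    vj <- matrix(st$v[j, ], 3, 3, byrow = TRUE)
    vj <- sweep(vj, 2, c(1e-3, -2e-3, 5e-4), "+")
    om <- c(2e-4, 1e-4, -3e-4)
    com <- colSums(xj * w$masses) / sum(w$masses)
    r <- sweep(xj, 2, com)
    vj <- vj + cbind(om[2] * r[, 3] - om[3] * r[, 2],
                     om[3] * r[, 1] - om[1] * r[, 3],
                     om[1] * r[, 2] - om[2] * r[, 1])
    st$v[j, ] <- as.numeric(t(vj))
  }
  cl <- remove_global_motion(st)
  for (j in 1:4) {
    xj <- matrix(cl$x[j, ], 3, 3, byrow = TRUE)
    vj <- matrix(cl$v[j, ], 3, 3, byrow = TRUE)
    p <- colSums(vj * w$masses)
    expect_lt(max(abs(p)), 1e-12)
    com <- colSums(xj * w$masses) / sum(w$masses)
    r <- sweep(xj, 2, com)
    L <- colSums(w$masses * cbind(r[, 2] * vj[, 3] - r[, 3] * vj[, 2],
                                  r[, 3] * vj[, 1] - r[, 1] * vj[, 3],
                                  r[, 1] * vj[, 2] - r[, 2] * vj[, 1]))
    expect_lt(max(abs(L)), 1e-10)
  }
  # single atom in 1D: no-op
  h <- make_harmonic()
  s1 <- initial_state(h$model, h$mass, 2, 300)
  s1$v[, 1] <- c(0.1, -0.2)
  expect_equal(remove_global_motion(s1)$v[, 2:3], s1$v[, 2:3])
})

test_that("harmonic reference reproduces limits and the Hessian oracle", {
  beta <- 800; mass <- 1822.888
  # P = 1 is classical
  expect_equal(harmonic_reference(1, beta, 0.01, mass)$mean_potential,
               1 / (2 * beta), tolerance = 1e-12)
  # omega = 0: free ring
  r0 <- harmonic_reference(4, beta, 0, mass)
  expect_equal(r0$mean_potential, 0)
  expect_equal(r0$normal_mode_frequencies,
               free_ring_frequencies(4, beta), tolerance = 1e-12)
  # large P approaches the coth limit
  omega <- 4 / beta                      # beta*hbar*omega = 4
  r64 <- harmonic_reference(64, beta, omega, mass)
  expect_lt(abs(r64$mean_potential - r64$quantum_limit) / r64$quantum_limit,
            1e-3)
  # frequencies against the numerically diagonalized Hessian
  for (P in c(3, 6)) {
    r <- harmonic_reference(P, beta, omega, mass)
    expect_equal(sort(r$normal_mode_frequencies^2),
                 ring_hessian_freqs2(P, omega, P / beta), tolerance = 1e-10)
  }
  # monotone convergence in P
  vs <- sapply(c(1, 2, 4, 8, 16, 32),
               function(P) harmonic_reference(P, beta, omega, mass)$mean_potential)
  expect_true(all(diff(vs) > 0))
  expect_true(all(vs < r64$quantum_limit))
})

test_that("primitive kinetic estimator agrees with the harmonic virial", {
  h <- make_harmonic(900)
  P <- 8
  st <- initial_state(h$model, h$mass, P, 300)
  set.seed(12)
  st <- sample_velocities(st)
  prims <- vapply(1:8, function(i) {
    tr <- integrate_pimd(st, h$model, simulation_config(
      dt = 0.5, n_steps = 8000, temperature = 300, thermostat = "pile",
      pile_tau = 50, seed = 300 + i, constrain_1d = TRUE))
    c(mean(tr$estimators$kinetic_primitive[-(1:2000)]),
      mean(tr$estimators$potential[-(1:2000)]))
  }, numeric(2))
  dif <- prims[1, ] - prims[2, ]
  se <- sd(dif) / sqrt(ncol(prims))
  expect_lt(abs(mean(dif)), 3 * se + 1e-12)
})
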