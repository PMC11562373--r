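#' Ring-polymer state
#'
#' Positions and velocities of P replicas of N atoms, with physical masses
#' and the inverse temperature. The chain frequency omega_P = P/(beta hbar)
#' is derived, and bead indexing is cyclic.
#'
#' @param positions numeric array: either a P x N x 3 array or a matrix
#'   P x (3N) (bead-major layout), bohr
#' @param velocities same shape as positions, bohr per atomic time unit
#' @param masses atomic masses in electron-mass units (length N)
#' @param temperature temperature in Kelvin
#' @return object of class `rp_state`
#' @export
ring_polymer_state <- function(positions, velocities, masses, temperature) {
  x <- as_bead_matrix(positions, length(masses))
  v <- as_bead_matrix(velocities, length(masses))
  if (!all(dim(x) == dim(v)))
    stop("ring_polymer_state: positions and velocities differ in shape", call. = FALSE)
  if (any(masses <= 0)) stop("ring_polymer_state: masses must be > 0", call. = FALSE)
  P <- nrow(x)
  beta <- beta_au(temperature)
  structure(list(x = x, v = v, masses = as.numeric(masses), P = P,
                 beta = beta, temperature = temperature,
                 omega_P = P / beta),
            class = "rp_state")
}

as_bead_matrix <- function(a, natoms) {
  if (is.matrix(a)) {
    if (ncol(a) != 3 * natoms)
      stop("bead matrix must have 3*natoms columns", call. = FALSE)
    return(a)
  }
  d <- dim(a)
  if (length(d) == 3) {
    if (d[2] != natoms || d[3] != 3)
      stop("bead array must be P x natoms x 3", call. = FALSE)
    return(matrix(aperm(a, c(1, 3, 2))[, , ], d[1], 3 * natoms)[,
             as.vector(t(matrix(seq_len(3 * natoms), 3, natoms))), drop = FALSE])
  }
  if (is.numeric(a) && is.null(d)) return(matrix(a, nrow = 1))
  stop("unsupported bead layout", call. = FALSE)
}

#' @export
print.rp_state <- function(x, ...) {
  cat(sprintf("<rp_state> P = %d beads, %d atom(s), T = %.6g K (omega_P = %.4g au)\n",
              x$P, length(x$masses), x$temperature, x$omega_P))
  invisible(x)
}

#' Collapse a model's equilibrium geometry into a ring-polymer state
#'
#' All beads start at the potential minimum with zero velocities; use
#' [sample_velocities()] to draw Maxwell-Boltzmann velocities at the
#' simulation temperature P*T.
#'
#' @param model a [potential_model()]
#' @param masses atomic masses (electron masses)
#' @param P bead count
#' @param temperature Kelvin
#' @return an `rp_state`
#' @export
initial_state <- function(model, masses, P, temperature) {
  geo <- as.numeric(t(equilibrium_geometry(model)))
  x <- matrix(rep(geo, each = P), P, length(geo))
  ring_polymer_state(x, 0 * x, masses, temperature)
}

#' Draw Maxwell-Boltzmann velocities at the simulation temperature P*T
#'
#' @param state an `rp_state`
#' @return the state with fresh velocities (uses the current RNG stream)
#' @export
sample_velocities <- function(state) {
  stopifnot(inherits(state, "rp_state"))
  sd <- sqrt(state$P / (state$beta * rep(state$masses, each = 3)))
  state$v <- matrix(stats::rnorm(length(state$x)), nrow = state$P, byrow = FALSE) *
    rep(sd, each = state$P)
  state
}

#' Ring-polymer energies
#'
#' Kinetic, spring and potential energy of a state under a model. The
#' potential is the bead average; the spring term uses cyclic differences
#' with the chain frequency; `spring` is the total over beads (the quantity
#' entering the ring-polymer Hamiltonian).
#'
#' @param state an `rp_state`
#' @param model a [potential_model()]
#' @return list(kinetic, spring, potential) in Hartree
#' @export
ring_polymer_energy <- function(state, model) {
  stopifnot(inherits(state, "rp_state"), inherits(model, "potential_model"))
  e <- cpp_rp_energy(as.numeric(t(state$x)), as.numeric(t(state$v)),
                     state$masses, state$P, state$beta,
                     model$kind_id, model$par_vec)
  list(kinetic = e$kinetic, spring = e$spring, potential = e$potential)
}

#' Free ring-polymer normal-mode transform
#'
#' Orthogonal transform between bead and normal-mode coordinates; mode 0 is
#' the centroid (uniform combination). The same matrix applies to positions
#' and velocities.
#'
#' @param state an `rp_state`
#' @param inverse back-transform normal-mode input to beads
#' @return list(q, qdot): P x (3N) matrices of normal-mode coordinates and
#'   velocities (or bead coordinates when `inverse = TRUE`)
#' @export
normal_mode_transform <- function(state, inverse = FALSE) {
  stopifnot(inherits(state, "rp_state"))
  C <- nm_matrix(state$P)
  if (inverse) C <- t(C)
  list(q = C %*% state$x, qdot = C %*% state$v)
}

nm_matrix <- function(P) {
  C <- matrix(0, P, P)
  j <- 0:(P - 1)
  C[1, ] <- sqrt(1 / P)
  if (P > 1) {
    for (k in seq_len(ceiling(P / 2) - 1))
      C[k + 1, ] <- sqrt(2 / P) * cos(2 * pi * k * j / P)
    if (P %% 2 == 0) C[P / 2 + 1, ] <- sqrt(1 / P) * (-1)^j
    for (k in seq.int(floor(P / 2) + 1, P - 1))
      C[k + 1, ] <- sqrt(2 / P) * sin(2 * pi * k * j / P)
  }
  C
}

#' Free ring-polymer normal-mode frequencies (atomic units)
#' @param P bead count
#' @param beta inverse temperature (1/Hartree)
#' @return numeric vector omega_k = 2 omega_P sin(k pi / P), k = 0..P-1
#' @export
free_ring_frequencies <- function(P, beta) {
  2 * (P / beta) * sin(pi * (0:(P - 1)) / P)
}

#' Simulation configuration
#'
#' @param dt time step in fs (default 0.25)
#' @param n_steps number of steps
#' @param temperature Kelvin
#' @param thermostat "pile" or "none"
#' @param pile_tau centroid thermostat time constant in fs (default 1000)
#' @param pile_scale scale factor on the internal-mode friction 2*omega_k
#' @param seed RNG seed applied before the run (NULL: use current stream)
#' @param constrain_1d restrict motion to the x axis
#' @param fix_com fix the center of mass of every bead
#' @param record_stride store every k-th step (default 1)
#' @param record_beads keep per-bead velocities (needed for bead-level
#'   spectra)
#' @param remove_global remove each replica's rigid translation/rotation
#'   from the recorded velocities (3D runs)
#' @return object of class `sim_config`
#' @export
simulation_config <- function(dt = 0.25, n_steps, temperature,
                              thermostat = c("pile", "none"),
                              pile_tau = 1000, pile_scale = 1, seed = NULL,
                              constrain_1d = FALSE, fix_com = FALSE,
                              record_stride = 1L, record_beads = FALSE,
                              remove_global = FALSE) {
  thermostat <- match.arg(thermostat)
  if (dt <= 0) stop("simulation_config: dt must be > 0", call. = FALSE)
  if (thermostat == "pile" && pile_tau <= 0)
    stop("simulation_config: pile_tau must be > 0", call. = FALSE)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, thermostat = thermostat,
                 pile_tau = pile_tau, pile_scale = pile_scale, seed = seed,
                 constrain_1d = isTRUE(constrain_1d),
                 fix_com = isTRUE(fix_com),
                 record_stride = as.integer(record_stride),
                 record_beads = isTRUE(record_beads),
                 remove_global = isTRUE(remove_global)),
            class = "sim_config")
}

run_integrator <- function(state, model, config, thermostat_on) {
  stopifnot(inherits(state, "rp_state"), inherits(model, "potential_model"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dt_au <- config$dt * rd_constants$fs_au
  out <- cpp_rp_integrate(
    as.numeric(t(state$x)), as.numeric(t(state$v)), state$masses,
    state$P, state$beta, model$kind_id, model$par_vec,
    dt_au, config$n_steps, if (thermostat_on) 1L else 0L,
    config$pile_tau * rd_constants$fs_au, config$pile_scale,
    config$constrain_1d, config$fix_com,
    config$record_stride, config$record_beads, config$remove_global)
  nd <- 3 * length(state$masses)
  est <- as.data.frame(out$estimators)
  names(est) <- c("potential", "kinetic_cl", "spring_per_bead",
                  "kinetic_primitive", "conserved")
  st <- state
  st$x <- matrix(out$x, state$P, nd, byrow = TRUE)
  st$v <- matrix(out$v, state$P, nd, byrow = TRUE)
  traj <- structure(list(
    times = out$times / rd_constants$fs_au,
    centroid_velocities = out$centroid_velocities,
    centroid_positions = out$centroid_positions,
    bead_velocities = out$bead_velocities,
    estimators = est, dt = config$dt * config$record_stride,
    P = state$P, beta = state$beta, masses = state$masses,
    model = model, config = config, state = st), class = "rp_trajectory")
  traj
}

#' @export
print.rp_trajectory <- function(x, ...) {
  cat(sprintf("<rp_trajectory> %d frames (dt = %g fs), P = %d, %d atom(s)%s\n",
              length(x$times), x$dt, x$P, length(x$masses),
              if (!is.null(x$bead_velocities)) ", bead-resolved" else ""))
  invisible(x)
}

#' Thermostatted path-integral MD (PIMD)
#'
#' Samples the ring-polymer Boltzmann distribution at simulation temperature
#' P*T with the PILE thermostat: Langevin friction applied in the
#' normal-mode representation, 1/tau on the centroid and `pile_scale *
#' 2*omega_k` on the internal modes.
#'
#' @param state an `rp_state`
#' @param model a [potential_model()]
#' @param config a [simulation_config()] with thermostat = "pile"
#' @return an `rp_trajectory`; `$state` carries the final phase-space point
#' @export
integrate_pimd <- function(state, model, config) {
  if (config$thermostat != "pile")
    stop("integrate_pimd: config$thermostat must be 'pile'", call. = FALSE)
  run_integrator(state, model, config, thermostat_on = TRUE)
}

#' Microcanonical ring-polymer MD (RPMD)
#'
#' Thermostat-free Newtonian dynamics of the ring polymer. The conserved
#' ring-polymer energy is monitored; a relative drift beyond `drift_tol`
#' (default 1e-5) triggers a warning.
#'
#' @param state an `rp_state` (typically the endpoint of a PIMD run)
#' @param model a [potential_model()]
#' @param config a [simulation_config()] with thermostat = "none"
#' @param drift_tol relative energy-drift warning threshold
#' @return an `rp_trajectory`
#' @export
integrate_rpmd <- function(state, model, config, drift_tol = 1e-5) {
  if (config$thermostat != "none")
    stop("integrate_rpmd: config$thermostat must be 'none'", call. = FALSE)
  traj <- run_integrator(state, model, config, thermostat_on = FALSE)
  # secular drift: difference between the mean conserved energy over the
  # last and first quarters of the run (velocity-Verlet energy shows
  # bounded O(dt^2) oscillation, not drift, so endpoint differences and
  # trend fits overstate it)
  e <- traj$estimators$conserved
  nq <- max(1L, length(e) %/% 4L)
  drift <- abs(mean(e[seq.int(length(e) - nq + 1L, length(e))]) -
               mean(e[seq_len(nq)])) / max(abs(mean(e)), 1e-300)
  if (is.finite(drift) && drift > drift_tol)
    warning(sprintf("integrate_rpmd: conserved-energy drift %.3g exceeds %.1g",
                    drift, drift_tol), call. = FALSE)
  traj$energy_drift <- drift
  traj
}

#' Remove rigid translation and rotation from every replica
#'
#' Zeroes each bead's total linear momentum and (for >= 2 atoms in 3D) its
#' angular momentum about the bead's center of mass. A single atom in 1D is
#' returned unchanged.
#'
#' @param state an `rp_state`
#' @return the cleaned state
#' @export
remove_global_motion <- function(state) {
  stopifnot(inherits(state, "rp_state"))
  m <- state$masses
  natoms <- length(m)
  msum <- sum(m)
  for (j in seq_len(state$P)) {
    vj <- matrix(state$v[j, ], natoms, 3, byrow = TRUE)
    xj <- matrix(state$x[j, ], natoms, 3, byrow = TRUE)
    vcom <- colSums(vj * m) / msum
    vj <- sweep(vj, 2, vcom)
    if (natoms > 1) {
      com <- colSums(xj * m) / msum
      r <- sweep(xj, 2, com)
      # two passes drive the residual angular momentum to round-off even
      # with the regularized inertia solve (singular for linear geometries)
      for (pass in 1:2) {
        L <- colSums(m * cbind(r[, 2] * vj[, 3] - r[, 3] * vj[, 2],
                               r[, 3] * vj[, 1] - r[, 1] * vj[, 3],
                               r[, 1] * vj[, 2] - r[, 2] * vj[, 1]))
        II <- diag(sum(m * rowSums(r^2)), 3) - t(r * m) %*% r
        II <- II + diag(1e-13 * sum(diag(II)) + 1e-300, 3)
        om <- solve(II, L)
        vj <- vj - cbind(om[2] * r[, 3] - om[3] * r[, 2],
                         om[3] * r[, 1] - om[1] * r[, 3],
                         om[1] * r[, 2] - om[2] * r[, 1])
      }
    }
    state$v[j, ] <- as.numeric(t(vj))
  }
  state
}

#' Closed-form harmonic-oscillator reference for PIMD
#'
#' Analytic expectation values for a 1D harmonic oscillator sampled by a
#' P-bead ring polymer: normal-mode frequencies omega_k^2 = omega^2 +
#' 4 omega_P^2 sin^2(k pi/P), equipartition mean-square normal coordinates
#' at temperature P*T, the resulting bead-averaged potential energy, and
#' its exact quantum limit (hbar omega/4) coth(beta hbar omega / 2).
#'
#' @param P bead count >= 1
#' @param beta inverse temperature (1/Hartree)
#' @param omega oscillator angular frequency (atomic units), >= 0
#' @param mass particle mass (electron masses)
#' @return object of class `harmonic_reference` with fields `omega`,
#'   `normal_mode_frequencies`, `mean_sq_normal_coords`, `mean_potential`,
#'   `quantum_limit`
#' @export
harmonic_reference <- function(P, beta, omega, mass) {
  stopifnot(P >= 1, omega >= 0, beta > 0, mass > 0)
  omegaP <- P / beta
  k <- 0:(P - 1)
  wk2 <- omega^2 + 4 * omegaP^2 * sin(pi * k / P)^2
  q2 <- P / (beta * mass * wk2)
  q2[wk2 == 0] <- Inf                      # free centroid at omega = 0
  meanV <- if (omega == 0) 0 else (omega^2 / (2 * beta)) * sum(1 / wk2)
  qlim <- if (omega == 0) 0 else (omega / 4) / tanh(beta * omega / 2)
  structure(list(omega = omega, normal_mode_frequencies = sqrt(wk2),
                 mean_sq_normal_coords = q2, mean_potential = meanV,
                 quantum_limit = qlim, P = P, beta = beta, mass = mass),
            class = "harmonic_reference")
}

#' @export
print.harmonic_reference <- function(x, ...) {
  cat(sprintf("<harmonic_reference> P = %d, beta*hbar*omega = %.4g: <V>_P = %.6g Eh (quantum limit %.6g)\n",
              x$P, x$beta * x$omega, x$mean_potential, x$quantum_limit))
  invisible(x)
}
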