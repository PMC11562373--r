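#' Simulate an RPMD ensemble and accumulate its autocorrelations
#'
#' Runs `n_traj` independent trajectories: beads start at the potential
#' minimum, Maxwell-Boltzmann velocities at the simulation temperature P*T,
#' PILE-thermostatted equilibration, removal of each replica's rigid
#' translation/rotation (3D runs), then a microcanonical RPMD production
#' run. The mass-weighted periodograms of the centroid and bead velocities
#' are accumulated across trajectories (averaging the autocorrelations
#' before any Fourier transform), so memory stays flat in the ensemble
#' size. Child RNG seeds are `seed + trajectory index`.
#'
#' @param model a [potential_model()]
#' @param masses atomic masses (electron masses)
#' @param P bead count
#' @param temperature Kelvin
#' @param n_traj number of independent trajectories
#' @param equil_ps,production_ps equilibration / production lengths (ps)
#' @param dt time step (fs, default 0.25)
#' @param pile_tau PILE centroid time constant (fs, default 1000)
#' @param seed master seed
#' @param constrain_1d,fix_com constraint flags (see [simulation_config()])
#' @param record_beads accumulate bead-level velocities (needed for the
#'   path-integral spectrum)
#' @param record_stride store every k-th step (default 2: 0.5 fs sampling at
#'   the default time step, resolving frequencies far above the 10000 cm^-1
#'   artifact window)
#' @param progress print one line per trajectory block
#' @return object of class `rp_ensemble` carrying averaged VACFs
#'   (`vacf_centroid`, `vacf_beads`), estimator summaries and metadata
#' @export
rpmd_ensemble <- function(model, masses, P, temperature, n_traj,
                          equil_ps = 2, production_ps = 10, dt = 0.25,
                          pile_tau = 1000, seed = 1,
                          constrain_1d = FALSE, fix_com = FALSE,
                          record_beads = TRUE, record_stride = 2L,
                          progress = FALSE) {
  stopifnot(inherits(model, "potential_model"))
  n_eq <- round(equil_ps * 1000 / dt)
  n_pr <- round(production_ps * 1000 / dt)
  m3 <- rep(masses, each = 3)
  pw_c <- NULL
  pw_b <- NULL
  nfrm <- NULL
  est_means <- NULL
  drifts <- numeric(n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seed + i)
    st <- initial_state(model, masses, P, temperature)
    st <- sample_velocities(st)
    eq <- integrate_pimd(st, model, simulation_config(
      dt = dt, n_steps = n_eq, temperature = temperature,
      thermostat = "pile", pile_tau = pile_tau,
      constrain_1d = constrain_1d, fix_com = fix_com,
      record_stride = max(1L, n_eq)))
    st <- eq$state
    if (!constrain_1d) st <- remove_global_motion(st)
    tr <- suppressWarnings(integrate_rpmd(st, model, simulation_config(
      dt = dt, n_steps = n_pr, temperature = temperature,
      thermostat = "none", constrain_1d = constrain_1d, fix_com = fix_com,
      record_beads = record_beads, record_stride = record_stride,
      remove_global = !constrain_1d)))
    drifts[i] <- tr$energy_drift
    nfrm <- nrow(tr$centroid_velocities)
    pc <- vacf_power(tr$centroid_velocities, m3)
    if (is.null(pw_c)) pw_c <- pc else pw_c <- pw_c + pc
    if (record_beads) {
      pb <- vacf_power(tr$bead_velocities, rep(m3, times = P))
      if (is.null(pw_b)) pw_b <- pb else pw_b <- pw_b + pb
    }
    em <- colMeans(tr$estimators)
    if (is.null(est_means)) est_means <- em / n_traj
    else est_means <- est_means + em / n_traj
    if (progress && (i %% 25 == 0 || i == n_traj))
      message(sprintf("rpmd_ensemble: %d/%d trajectories", i, n_traj))
  }
  dt_rec <- dt * record_stride
  power_to_vacf <- function(pw) {
    L <- floor(nfrm / 2)
    ac <- Re(stats::fft(pw, inverse = TRUE))[1:(L + 1)] / length(pw)
    ac <- ac / (nfrm - 0:L)
    structure(list(lags = dt_rec * (0:L), c = ac / ac[1], dt = dt_rec,
                   c0_raw = ac[1]), class = "rd_vacf")
  }
  structure(list(
    vacf_centroid = power_to_vacf(pw_c),
    vacf_beads = if (record_beads) power_to_vacf(pw_b) else NULL,
    estimator_means = est_means, energy_drifts = drifts,
    n_traj = as.integer(n_traj), P = as.integer(P),
    temperature = temperature, beta = beta_au(temperature),
    model = model, masses = masses, dt = dt, seed = seed,
    production_ps = production_ps), class = "rp_ensemble")
}

#' @export
print.rp_ensemble <- function(x, ...) {
  cat(sprintf("<rp_ensemble> %d x %g ps RPMD, P = %d, T = %g K (max |drift| %.2g)\n",
              x$n_traj, x$production_ps, x$P, x$temperature,
              max(abs(x$energy_drifts))))
  invisible(x)
}

#' Full RPMD-to-quantum deconvolution pipeline
#'
#' Executes the six post-processing stages on an RPMD ensemble: (1) the
#' bead-level VDOS C_vv^PI from the averaged bead VACF (and the centroid
#' VDOS C_vv^RPMD for comparison); (2) change of variable to z = omega'^2;
#' (3) bounded non-negative deconvolution of the ring-polymer convolution;
#' (4) back-transform to the frequency axis (C_vv^dec); (5) multiplication
#' by the single-bead weight function to approximate the quantum VDOS
#' C_vv^q. All intermediates are returned.
#'
#' @param ens an [rpmd_ensemble()] result (bead velocities required)
#' @param cfg a [deconv_config()]
#' @param dz z-grid spacing; default from [choose_z_spacing()] for the
#'   ensemble's bead count
#' @param max_lag_fs VACF truncation used for the spectra (default 5000 fs)
#' @param window taper passed to [vdos()]
#' @return list with spectra `pi`, `rpmd`, `dec`, `q` and intermediates
#'   `g_pi`, `g_dec`, `operator`, `omega_T_cm1`
#' @export
pipeline_rpmd_to_quantum <- function(ens, cfg = deconv_config(), dz = NULL,
                                     max_lag_fs = 5000, window = "hann") {
  stopifnot(inherits(ens, "rp_ensemble"))
  if (is.null(ens$vacf_beads))
    stop("pipeline_rpmd_to_quantum: ensemble lacks bead velocities", call. = FALSE)
  wT <- omega_thermal(ens$temperature, "cm-1")
  meta <- list(P = ens$P, temperature = ens$temperature, n_traj = ens$n_traj)
  trunc_vacf <- function(cv) {
    L <- min(length(cv$c) - 1L, floor(max_lag_fs / cv$dt))
    cv$c <- cv$c[1:(L + 1)]
    cv$lags <- cv$lags[1:(L + 1)]
    cv
  }
  sp_pi <- vdos(trunc_vacf(ens$vacf_beads), window = window,
                level = "PI", meta = meta)
  sp_rpmd <- vdos(trunc_vacf(ens$vacf_centroid), window = window,
                  level = "RPMD", meta = meta)
  if (is.null(dz)) {
    sp <- suppressWarnings(choose_z_spacing(ens$P, target = 0.1))
    dz <- sp$spacing
  }
  z_max <- (cfg$artifact_max / wT)^2 + max(normal_mode_offsets(ens$P))
  grid <- zgrid(z_max, dz)
  op <- pi_convolution_operator(ens$P, grid, snap_tol_div = 2)
  g_pi <- to_z(sp_pi, wT, grid)
  g_dec <- deconvolve(g_pi, op, cfg)
  sp_dec <- from_z(g_dec)
  sp_dec$level <- "dec"
  w1 <- weight_table_p1(omega_max = max(sp_dec$omega) / wT + 1)
  sp_q <- quantum_correct(sp_dec, w1, wT)
  list(pi = sp_pi, rpmd = sp_rpmd, dec = sp_dec, q = sp_q,
       g_pi = g_pi, g_dec = g_dec, operator = op, omega_T_cm1 = wT)
}
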