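#' Synthetic fixture-spectrum specification
#'
#' Describes a synthetic classical density of states (sum of Gaussian or
#' Lorentzian peaks) and the conditions for its exact path-integral image,
#' so that every deconvolution stage is testable without any simulation.
#'
#' @param peaks peak positions (cm^-1), all within (0, artifact_max)
#' @param areas peak areas (> 0)
#' @param widths Gaussian/Lorentzian widths (cm^-1)
#' @param noise relative noise level added to the path-integral image
#'   (fraction of its maximum; 0 = exact forward convolution)
#' @param shape "gaussian" or "lorentzian"
#' @param P bead count of the forward operator
#' @param temperature Kelvin (sets omega_T)
#' @param dz z-grid spacing (dimensionless)
#' @param artifact_max upper end of the frequency grid (cm^-1)
#' @param seed RNG seed for the noise
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(peaks, areas = rep(1, length(peaks)),
                         widths = rep(40, length(peaks)), noise = 0,
                         shape = c("gaussian", "lorentzian"), P = 16,
                         temperature = 380.8, dz = 0.1,
                         artifact_max = 10000, seed = 1) {
  shape <- match.arg(shape)
  if (length(peaks) && (any(peaks <= 0) || any(peaks >= artifact_max)))
    stop("fixture_spec: peak positions must lie in (0, artifact_max)", call. = FALSE)
  if (any(areas <= 0)) stop("fixture_spec: peak areas must be > 0", call. = FALSE)
  stopifnot(length(areas) == length(peaks), length(widths) == length(peaks))
  structure(list(peaks = peaks, areas = areas, widths = widths,
                 noise = noise, shape = shape, P = as.integer(P),
                 temperature = temperature, dz = dz,
                 artifact_max = artifact_max, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic classical / path-integral spectrum pair
#'
#' The classical spectrum is the analytic peak sum; its path-integral image
#' is the exact forward application of the ring-polymer convolution
#' operator on the z grid, plus seeded Gaussian noise when requested. The
#' same seed always yields bit-identical output.
#'
#' @param fs a [fixture_spec()]
#' @return list with `cl` and `pi` spectra (`rd_spectrum`), the z-space
#'   pair `g_cl`, `g_pi`, and the `operator` used
#' @export
generate_fixture_spectrum <- function(fs) {
  stopifnot(inherits(fs, "fixture_spec"))
  wT <- omega_thermal(fs$temperature, "cm-1")
  omega <- seq(1, fs$artifact_max, by = 1)
  vals <- numeric(length(omega))
  for (i in seq_along(fs$peaks)) {
    if (fs$shape == "gaussian") {
      s <- fs$widths[i]
      vals <- vals + fs$areas[i] * stats::dnorm(omega, fs$peaks[i], s)
    } else {
      g <- fs$widths[i] / 2
      vals <- vals + fs$areas[i] * g / pi / ((omega - fs$peaks[i])^2 + g^2)
    }
  }
  meta <- list(P = fs$P, temperature = fs$temperature, synthetic = "true",
               seed = fs$seed)
  cl <- spectrum(omega, vals, level = "cl", meta = meta)
  z_max <- (fs$artifact_max / wT)^2 + max(normal_mode_offsets(fs$P))
  grid <- zgrid(z_max, fs$dz)
  op <- pi_convolution_operator(fs$P, grid, snap_tol_div = 2)
  g_cl <- to_z(cl, wT, grid)
  g_pi <- apply_pi_operator(op, g_cl)
  if (fs$noise > 0) {
    set.seed(fs$seed)
    g_pi$values <- g_pi$values +
      fs$noise * max(g_pi$values) * stats::rnorm(length(g_pi$values))
    g_pi$values <- pmax(g_pi$values, 0)
  }
  pi_sp <- from_z(g_pi)
  pi_sp$level <- "PI"
  list(cl = cl, pi = pi_sp, g_cl = g_cl, g_pi = g_pi, operator = op,
       omega_T_cm1 = wT)
}
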