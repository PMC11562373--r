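#' Physical constants and unit conversions
#'
#' All internal computation uses Hartree atomic units (hbar = m_e = e =
#' 4*pi*eps0 = 1). Constructors accept laboratory units (K, fs, cm^-1,
#' Angstrom, amu) and convert through this single table of CODATA-2018
#' values.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, Hartree / K}
#'   \item{hartree_cm1}{1 Hartree expressed in cm^-1 (i.e. E/(h c))}
#'   \item{fs_au}{atomic time units per femtosecond}
#'   \item{bohr_A}{Angstrom per bohr}
#'   \item{amu_me}{electron masses per unified atomic mass unit}
#' }
#' @export
rd_constants <- list(
  kB         = 3.166811563e-6,
  hartree_cm1 = 219474.6313632,
  fs_au      = 41.341373335183,
  bohr_A     = 0.529177210903,
  amu_me     = 1822.888486209
)

#' Inverse temperature in atomic units
#' @param temperature temperature in Kelvin
#' @return beta = 1/(kB T) in 1/Hartree
#' @export
beta_au <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (rd_constants$kB * temperature)
}

#' Thermal (reduced) frequency scale
#'
#' The frequency scale omega_T = 2/(beta hbar) that defines the reduced
#' frequency omega' = omega/omega_T and the squared reduced frequency
#' z = omega'^2 used throughout the weight-function and deconvolution
#' machinery.
#'
#' @param temperature temperature in Kelvin
#' @param units "au" (angular frequency, atomic units) or "cm-1"
#' @return omega_T in the requested units
#' @export
omega_thermal <- function(temperature, units = c("au", "cm-1")) {
  units <- match.arg(units)
  wt <- 2 / beta_au(temperature)
  if (units == "cm-1") wt <- wt * rd_constants$hartree_cm1
  wt
}

#' Convert between angular frequency (a.u.) and wavenumber (cm^-1)
#'
#' E = hbar * omega, so the conversion factor is the Hartree energy in
#' cm^-1.
#'
#' @param omega angular frequency in atomic units
#' @return wavenumber in cm^-1
#' @export
omega_au_to_cm1 <- function(omega) omega * rd_constants$hartree_cm1

#' @rdname omega_au_to_cm1
#' @param nu wavenumber in cm^-1
#' @export
cm1_to_omega_au <- function(nu) nu / rd_constants$hartree_cm1

#' @useDynLib ringdeconv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"
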