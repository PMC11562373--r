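#' Model potentials
#'
#' Constructors for the bundled few-atom model potentials. All parameters
#' are in Hartree atomic units unless a unit-suffixed argument says
#' otherwise.
#'
#' @param kind one of "harmonic1d", "morse_diatomic",
#'   "triatomic_water_harmonic", "triatomic_water_anharmonic"
#' @param parameters named list of model constants (atomic units):
#'   \describe{
#'     \item{harmonic1d}{`k` force constant (Eh/bohr^2)}
#'     \item{morse_diatomic}{`D` well depth (Eh), `a` range (1/bohr),
#'       `r0` equilibrium distance (bohr)}
#'     \item{triatomic_water_harmonic}{`kr` bond force constant, `r0` bond
#'       length, `ktheta` bend constant (Eh/rad^2), `theta0` bend angle (rad)}
#'     \item{triatomic_water_anharmonic}{`D`, `a`, `r0`, `ktheta`, `theta0`}
#'   }
#' @return object of class `potential_model`
#' @export
potential_model <- function(kind = c("harmonic1d", "morse_diatomic",
                                     "triatomic_water_harmonic",
                                     "triatomic_water_anharmonic"),
                            parameters) {
  kind <- match.arg(kind)
  req <- switch(kind,
    harmonic1d = "k",
    morse_diatomic = c("D", "a", "r0"),
    triatomic_water_harmonic = c("kr", "r0", "ktheta", "theta0"),
    triatomic_water_anharmonic = c("D", "a", "r0", "ktheta", "theta0"))
  missing <- setdiff(req, names(parameters))
  if (length(missing))
    stop("potential_model: missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  par <- unlist(parameters[req])
  stiff <- par[names(par) %in% c("k", "D", "kr", "ktheta", "a")]
  if (any(stiff <= 0))
    stop("potential_model: stiffness/depth/range parameters must be > 0", call. = FALSE)
  if ("r0" %in% names(par) && par[["r0"]] <= 0)
    stop("potential_model: equilibrium bond length must be > 0", call. = FALSE)
  structure(list(kind = kind, parameters = as.list(par),
                 kind_id = match(kind, c("harmonic1d", "morse_diatomic",
                                         "triatomic_water_harmonic",
                                         "triatomic_water_anharmonic")) - 1L,
                 par_vec = unname(par),
                 natoms = switch(kind, harmonic1d = 1L, morse_diatomic = 2L, 3L)),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model> %s (%d atom%s): %s\n", x$kind, x$natoms,
              if (x$natoms > 1) "s" else "",
              paste(names(x$parameters), signif(unlist(x$parameters), 6),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Potential energy and forces of a single bead
#'
#' @param model a [potential_model()]
#' @param x numeric vector of Cartesian coordinates (bohr), length 3*natoms
#' @return list with `V` (Hartree) and `force` (Hartree/bohr)
#' @export
potential_eval <- function(model, x) {
  stopifnot(inherits(model, "potential_model"), length(x) == 3 * model$natoms)
  cpp_bead_potential(model$kind_id, model$par_vec, as.numeric(x), model$natoms)
}

#' Equilibrium geometry of a bundled model (bohr)
#' @param model a [potential_model()]
#' @return numeric matrix natoms x 3
#' @export
equilibrium_geometry <- function(model) {
  stopifnot(inherits(model, "potential_model"))
  p <- model$parameters
  switch(model$kind,
    harmonic1d = matrix(0, 1, 3),
    morse_diatomic = rbind(c(0, 0, 0), c(p$r0, 0, 0)),
    {
      th <- p$theta0
      rbind(c(0, 0, 0),
            c(p$r0 * sin(th / 2), p$r0 * cos(th / 2), 0),
            c(-p$r0 * sin(th / 2), p$r0 * cos(th / 2), 0))
    })
}

#' Harmonic vibrational analysis of a model
#'
#' Numerical Hessian at the equilibrium geometry, mass-weighted and
#' diagonalized; returns the vibrational frequencies in cm^-1 (zeros and
#' translational/rotational modes removed by a threshold).
#'
#' @param model a [potential_model()]
#' @param masses atomic masses in electron-mass units
#' @param step finite-difference step (bohr)
#' @return numeric vector of vibrational frequencies (cm^-1), ascending
#' @export
normal_mode_frequencies <- function(model, masses, step = 1e-4) {
  x0 <- as.numeric(t(equilibrium_geometry(model)))
  nd <- length(x0)
  H <- matrix(0, nd, nd)
  for (i in seq_len(nd)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    H[i, ] <- (-potential_eval(model, xp)$force +
                potential_eval(model, xm)$force) / (2 * step)
  }
  H <- (H + t(H)) / 2
  m3 <- rep(masses, each = 3)
  Hm <- H / sqrt(outer(m3, m3))
  ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-8 * max(abs(ev))]
  sort(omega_au_to_cm1(sqrt(ev)))
}

#' Load a potential model from a key = value config file
#'
#' The bundled configs under `inst/extdata/` document their literature
#' provenance in comments; any `#` comment and blank lines are ignored.
#' Recognized keys: `kind`, the model parameters (atomic units), and
#' optionally `masses_amu` (comma-separated).
#'
#' @param path file path
#' @return list with `model` ([potential_model()]) and `masses` (electron
#'   masses, or NULL if the file does not list them)
#' @export
read_potential_config <- function(path) {
  kv <- read_config(path)
  if (is.null(kv$kind)) stop("read_potential_config: missing 'kind'", call. = FALSE)
  masses <- NULL
  if (!is.null(kv$masses_amu)) {
    masses <- as.numeric(strsplit(kv$masses_amu, ",")[[1]]) * rd_constants$amu_me
    kv$masses_amu <- NULL
  }
  kind <- kv$kind
  kv$kind <- NULL
  pars <- lapply(kv, as.numeric)
  list(model = potential_model(kind, pars), masses = masses)
}
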