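#' Spectrum container
#'
#' A vibrational density of states on an ascending frequency grid in cm^-1.
#' Raw FFT spectra may carry small numerical negatives; they are clipped at
#' zero with the clip count kept in `meta$clipped`.
#'
#' @param omega frequency grid (cm^-1, ascending)
#' @param values spectral density (>= 0 after clipping)
#' @param level tag: one of "cl", "PI", "RPMD", "dec", "q"
#' @param meta named list of provenance metadata (temperature, P, ...)
#' @return object of class `rd_spectrum`
#' @export
spectrum <- function(omega, values, level = c("cl", "PI", "RPMD", "dec", "q"),
                     meta = list()) {
  level <- match.arg(level)
  if (length(omega) != length(values))
    stop("spectrum: grid/value length mismatch", call. = FALSE)
  if (is.unsorted(omega, strictly = TRUE))
    stop("spectrum: omega must be strictly increasing", call. = FALSE)
  nclip <- sum(values < 0)
  if (nclip) values <- pmax(values, 0)
  meta$clipped <- nclip
  structure(list(omega = omega, values = values, level = level, meta = meta),
            class = "rd_spectrum")
}

#' @export
print.rd_spectrum <- function(x, ...) {
  cat(sprintf("<rd_spectrum> level %s, %d bins on [%.4g, %.4g] cm^-1, area %.4g\n",
              x$level, length(x$omega), min(x$omega), max(x$omega),
              spectrum_area(x)))
  invisible(x)
}

#' Area under a spectrum (trapezoid rule)
#' @param s an `rd_spectrum` or `rd_zspectrum`
#' @export
spectrum_area <- function(s) {
  g <- if (inherits(s, "rd_zspectrum")) list(x = s$z, y = s$values)
       else list(x = s$omega, y = s$values)
  n <- length(g$y)
  sum(diff(g$x) * (g$y[-n] + g$y[-1]) / 2)
}

#' Mass-weighted velocity autocorrelation function
#'
#' c_vv(t) = sum_i m_i <v_i(0) . v_i(t)> / sum_i m_i <v_i^2>, computed by
#' FFT with unbiased lag normalization; c_vv(0) = 1 exactly.
#'
#' @param traj an `rp_trajectory`, or a raw matrix (frames x dof) together
#'   with `masses_per_col`
#' @param which "centroid" (centroid velocities) or "beads" (all bead
#'   velocities; requires `record_beads = TRUE` during integration)
#' @param max_lag_fs maximum lag (default: half the trajectory)
#' @param masses_per_col per-column masses when `traj` is a plain matrix
#' @return object of class `rd_vacf` with fields `lags` (fs) and `c`
#' @export
vacf <- function(traj, which = c("centroid", "beads"), max_lag_fs = NULL,
                 masses_per_col = NULL) {
  which <- match.arg(which)
  if (inherits(traj, "rp_trajectory")) {
    V <- if (which == "centroid") traj$centroid_velocities else {
      if (is.null(traj$bead_velocities))
        stop("vacf: trajectory has no bead velocities (record_beads = FALSE)",
             call. = FALSE)
      traj$bead_velocities
    }
    m3 <- rep(traj$masses, each = 3)
    mcol <- if (which == "centroid") m3 else rep(m3, times = traj$P)
    dt <- traj$dt
  } else {
    V <- traj
    mcol <- masses_per_col
    dt <- attr(traj, "dt")
    if (is.null(mcol) || is.null(dt))
      stop("vacf: matrix input needs masses_per_col and a 'dt' attribute",
           call. = FALSE)
  }
  if (is.null(dim(V)) || nrow(V) < 2) stop("vacf: empty trajectory", call. = FALSE)
  n <- nrow(V)
  if (is.null(max_lag_fs)) max_lag_fs <- dt * floor(n / 2)
  L <- min(n - 1L, floor(max_lag_fs / dt))
  if (n < 2 * L)
    stop("vacf: trajectory shorter than twice the requested maximum lag", call. = FALSE)
  pw <- vacf_power(V, mcol)
  ac <- Re(stats::fft(pw, inverse = TRUE))[1:(L + 1)] / length(pw)
  ac <- ac / (n - 0:L)                   # unbiased lag counts
  structure(list(lags = dt * (0:L), c = ac / ac[1], dt = dt,
                 c0_raw = ac[1]), class = "rd_vacf")
}

# accumulated mass-weighted periodogram of a velocity block (zero-padded)
vacf_power <- function(V, mcol, block = 32L) {
  n <- nrow(V)
  pw <- numeric(2 * n)
  for (i0 in seq(1, ncol(V), by = block)) {
    i1 <- min(ncol(V), i0 + block - 1L)
    X <- rbind(as.matrix(V[, i0:i1, drop = FALSE]),
               matrix(0, n, i1 - i0 + 1L))
    ft <- stats::mvfft(X)
    pw <- pw + as.numeric(Mod(ft)^2 %*% mcol[i0:i1])
  }
  pw
}

#' @export
print.rd_vacf <- function(x, ...) {
  cat(sprintf("<rd_vacf> %d lags, dt = %g fs, c(0) = %g\n",
              length(x$lags), x$dt, x$c[1]))
  invisible(x)
}

#' Vibrational density of states from a VACF
#'
#' Even (cosine) extension of the tapered autocorrelation followed by a real
#' FFT. The density convention is C(omega) = (dt/pi) * sum_l w_l c_l
#' cos(omega t_l) (units: per cm^-1 after the frequency conversion), so the
#' area under C approximates c(0)/2 * the taper gain. Negative numerical
#' values are clipped with a logged count.
#'
#' @param cv an `rd_vacf` (or numeric VACF series with `dt` given)
#' @param dt sampling interval in fs (taken from `cv` when it is an
#'   `rd_vacf`)
#' @param window taper: "hann" (default) or "none"
#' @param zero_pad zero-padding factor for finer frequency sampling
#' @param level level tag for the resulting spectrum
#' @param meta metadata list
#' @return an `rd_spectrum` on an omega grid in cm^-1
#' @export
vdos <- function(cv, dt = NULL, window = c("hann", "none"), zero_pad = 4,
                 level = "cl", meta = list()) {
  window <- match.arg(window)
  if (inherits(cv, "rd_vacf")) {
    dt <- cv$dt
    cv <- cv$c
  }
  if (is.null(dt)) stop("vdos: dt required", call. = FALSE)
  L <- length(cv) - 1L
  w <- if (window == "hann") 0.5 * (1 + cos(pi * (0:L) / L)) else rep(1, L + 1L)
  y <- cv * w
  nfft <- 2 * L * max(1L, as.integer(zero_pad))
  ext <- numeric(nfft)
  ext[1:(L + 1)] <- y
  ext[nfft - (1:L) + 1] <- y[2:(L + 1)]    # even extension
  sp <- Re(stats::fft(ext))[1:(nfft / 2)]
  dt_au <- dt * rd_constants$fs_au
  omega_au <- 2 * pi * (0:(nfft / 2 - 1)) / (nfft * dt_au)
  spectrum(omega_au_to_cm1(omega_au)[-1], (sp * dt_au / pi)[-1],
           level = level, meta = meta)
}

#' z-space spectrum container
#'
#' Density over the squared reduced frequency z = (omega/omega_T)^2 on a
#' uniform [zgrid()]; carries the thermal frequency scale used for the
#' mapping.
#'
#' @param grid a [zgrid()]
#' @param values density g(z) (area-matched to the source spectrum)
#' @param omega_T_cm1 thermal frequency scale 2/(beta hbar) in cm^-1
#' @param level level tag
#' @param meta metadata
#' @export
zspectrum <- function(grid, values, omega_T_cm1, level = "cl", meta = list()) {
  validate_zgrid(grid)
  if (length(values) != grid$n) stop("zspectrum: length mismatch", call. = FALSE)
  structure(list(z = grid$z_values, values = values, grid = grid,
                 omega_T_cm1 = omega_T_cm1, level = level, meta = meta),
            class = "rd_zspectrum")
}

#' @export
print.rd_zspectrum <- function(x, ...) {
  cat(sprintf("<rd_zspectrum> level %s, %d bins on z in [0, %.4g] (omega_T = %.4g cm^-1), area %.4g\n",
              x$level, length(x$z), max(x$z), x$omega_T_cm1, spectrum_area(x)))
  invisible(x)
}

#' Map a spectrum to the squared-reduced-frequency variable
#'
#' Area-preserving change of variable z = (omega/omega_T)^2: the density
#' picks up the Jacobian d omega/dz and is then rebinned onto the uniform
#' target grid through its cumulative integral (total area is conserved to
#' machine precision).
#'
#' @param s an `rd_spectrum`
#' @param omega_T_cm1 thermal scale omega_T in cm^-1 (see [omega_thermal()])
#' @param grid target [zgrid()]; a resolution warning is issued when the
#'   grid is coarser than the source near its upper end
#' @return an `rd_zspectrum`
#' @export
to_z <- function(s, omega_T_cm1, grid) {
  stopifnot(inherits(s, "rd_spectrum"))
  validate_zgrid(grid)
  zsrc <- (s$omega / omega_T_cm1)^2
  # cumulative area of the source on its native grid
  nv <- length(s$values)
  cumA <- c(0, cumsum(diff(s$omega) * (s$values[-nv] + s$values[-1]) / 2))
  zmax_grid <- max(grid$z_values)
  if (max(zsrc) > zmax_grid + grid$spacing) {
    # grid does not cover the source; area beyond is dropped deliberately
    keep_to <- max(which(zsrc <= zmax_grid))
  }
  dz_src <- diff(range(zsrc)) / length(zsrc)
  if (grid$spacing > 20 * dz_src * length(zsrc) / length(grid$z_values) &&
      grid$spacing > 10 * dz_src)
    warning("to_z: target z grid much coarser than the source near its top; peaks may be under-resolved",
            call. = FALSE)
  edges <- c(grid$z_values[1], grid$z_values + grid$spacing / 2)
  edges[1] <- 0
  Fz <- stats::approx(zsrc, cumA, xout = pmin(edges, max(zsrc)),
                      yleft = 0, rule = 2)$y
  vals <- diff(Fz) / diff(edges)
  zspectrum(grid, vals, omega_T_cm1, level = s$level, meta = s$meta)
}

#' Map a z-space spectrum back to the frequency axis
#'
#' Inverse of [to_z()]: omega = omega_T sqrt(z), density times dz/d omega.
#'
#' @param g an `rd_zspectrum`
#' @return an `rd_spectrum` on the (non-uniform) image grid
#' @export
from_z <- function(g) {
  stopifnot(inherits(g, "rd_zspectrum"))
  z <- g$z
  pos <- z > 0
  omega <- g$omega_T_cm1 * sqrt(z[pos])
  vals <- g$values[pos] * 2 * sqrt(z[pos]) / g$omega_T_cm1
  spectrum(omega, vals, level = g$level, meta = g$meta)
}

#' Ring-polymer convolution operator on the z grid
#'
#' The linear map from a classical z-space density to its path-integral
#' image: each physical mode appears replicated at z + c_k for every
#' ring-polymer normal mode k (including the centroid at c_0 = 0), with
#' amplitude 1/P per copy (equipartition of the normal-mode velocities at
#' the simulation temperature P T). In matrix form this is a banded
#' lower-triangular Toeplitz matrix with unit column sums.
#'
#' @param P bead count
#' @param grid a [zgrid()] (commensurability contract as in
#'   [build_eta_kernel()])
#' @param snap_tol_div snap tolerance divisor forwarded to the kernel
#' @return object of class `pi_operator`
#' @export
pi_convolution_operator <- function(P, grid, snap_tol_div = 20) {
  kern <- build_eta_kernel(P, grid, include_centroid = TRUE,
                           snap_tol_div = snap_tol_div)
  structure(list(P = as.integer(P), kernel = kern, grid = grid),
            class = "pi_operator")
}

#' @export
print.pi_operator <- function(x, ...) {
  cat(sprintf("<pi_operator> P = %d on %d-point z grid (dz = %g)\n",
              x$P, x$grid$n, x$grid$spacing))
  invisible(x)
}

#' Apply the ring-polymer convolution operator
#'
#' @param op a [pi_convolution_operator()]
#' @param g numeric vector on the operator grid, or an `rd_zspectrum`
#' @return the path-integral image (same type as the input)
#' @export
apply_pi_operator <- function(op, g) {
  stopifnot(inherits(op, "pi_operator"))
  if (inherits(g, "rd_zspectrum")) {
    if (length(g$values) != op$grid$n)
      stop("apply_pi_operator: grid mismatch", call. = FALSE)
    out <- g
    out$values <- kernel_apply(op$kernel, g$values) / op$P
    out$level <- "PI"
    return(out)
  }
  if (length(g) != op$grid$n) stop("apply_pi_operator: grid mismatch", call. = FALSE)
  kernel_apply(op$kernel, g) / op$P
}

#' Dense matrix form of the ring-polymer convolution operator
#' @param op a [pi_convolution_operator()]
#' @param rows,cols index vectors into the z grid (defaults: full grid)
#' @return numeric matrix A with A\[i, j\] = band(i - j)/P
#' @export
pi_operator_matrix <- function(op, rows = seq_len(op$grid$n),
                               cols = seq_len(op$grid$n)) {
  band <- op$kernel$band / op$P
  A <- matrix(0, length(rows), length(cols))
  d <- outer(rows, cols, "-")
  inb <- d >= 0 & d < length(band)
  A[inb] <- band[d[inb] + 1L]
  A
}

#' Deconvolution configuration
#'
#' @param lambda_scale weight of the first-difference smoothing penalty
#'   (default 0: plain constrained least squares)
#' @param physical_max highest physical frequency (cm^-1); the deconvolved
#'   density is forced to zero above it
#' @param artifact_max highest frequency entering the objective (cm^-1);
#'   finite-run broadening above the physical range is still fitted below
#'   this cutoff
#' @param objective_min lowest frequency entering the objective (cm^-1).
#'   The default equals `physical_max`: the fit then uses only the
#'   internal-mode images above the physical range, so interference between
#'   internal and physical vibrations (resonance-distorted line shapes
#'   below `physical_max`) cannot contaminate the deconvolved density. Set
#'   to 0 to fit the full range.
#' @param lower,upper bounds per z bin (scalars or vectors); lower = 0 and
#'   upper = Inf is plain NNLS
#' @param solver "nnls"/"bvls" (accelerated projected gradient; identical
#'   algorithm, named by the active bounds) or "lawson-hanson"
#'   (active-set NNLS via pracma, practical for small grids)
#' @param max_iter,tol projected-gradient iteration controls
#' @export
deconv_config <- function(lambda_scale = 0, physical_max = 5000,
                          artifact_max = 10000, objective_min = physical_max,
                          lower = 0, upper = Inf,
                          solver = c("nnls", "bvls", "lawson-hanson"),
                          max_iter = 8000, tol = 1e-12) {
  solver <- match.arg(solver)
  if (!(physical_max > 0 && artifact_max > physical_max))
    stop("deconv_config: need 0 < physical_max < artifact_max", call. = FALSE)
  if (objective_min < 0 || objective_min >= artifact_max)
    stop("deconv_config: need 0 <= objective_min < artifact_max", call. = FALSE)
  if (lambda_scale < 0) stop("deconv_config: lambda_scale must be >= 0", call. = FALSE)
  structure(list(lambda_scale = lambda_scale, physical_max = physical_max,
                 artifact_max = artifact_max, objective_min = objective_min,
                 lower = lower, upper = upper,
                 solver = solver, max_iter = max_iter, tol = tol),
            class = "deconv_config")
}

#' Deconvolve a path-integral z-space spectrum
#'
#' Solves the bounded least-squares problem
#' min || A g - g_PI ||^2 + lambda^2 || D g ||^2 subject to
#' lower <= g <= upper, where A is the ring-polymer convolution operator and
#' D the first-difference penalty; the objective is evaluated on z bins
#' whose frequency image lies between `objective_min` (by default the top
#' of the physical range, so only internal-mode images are fitted) and
#' `artifact_max`, and g is fixed at zero above the `physical_max` image.
#' The default solver is a monotone
#' accelerated projected-gradient (FISTA-type) iteration, which converges to
#' the constrained minimizer; "lawson-hanson" cross-checks small problems
#' via the classic active-set NNLS.
#'
#' @param g_pi an `rd_zspectrum` of level "PI" (bead-level density)
#' @param op a [pi_convolution_operator()] on the same grid
#' @param cfg a [deconv_config()]
#' @return an `rd_zspectrum` of level "dec"; attributes `residual_norm`,
#'   `iterations`, `objective`
#' @export
deconvolve <- function(g_pi, op, cfg = deconv_config()) {
  stopifnot(inherits(g_pi, "rd_zspectrum"), inherits(op, "pi_operator"),
            inherits(cfg, "deconv_config"))
  if (length(g_pi$values) != op$grid$n)
    stop("deconvolve: spectrum and operator grids differ", call. = FALSE)
  wT <- g_pi$omega_T_cm1
  z <- g_pi$z
  z_phys <- (cfg$physical_max / wT)^2
  z_art <- (cfg$artifact_max / wT)^2
  z_omin <- (cfg$objective_min / wT)^2
  unk <- which(z <= z_phys)              # always the leading bins
  rows <- which(z > z_omin & z <= z_art)
  nu <- length(unk)
  if (nu == 0) stop("deconvolve: no unknown bins below physical_max", call. = FALSE)
  if (length(rows) == 0) stop("deconvolve: empty objective window", call. = FALSE)
  j0 <- rows[1] - 1L                     # row offset on the z grid
  nr <- length(rows)
  b <- g_pi$values[rows]
  lo <- rep_len(cfg$lower, nu)
  hi <- rep_len(cfg$upper, nu)
  lam <- cfg$lambda_scale

  band <- op$kernel$band / op$P
  boff <- which(band != 0) - 1L
  bval <- band[boff + 1L]
  if (max(seq_len(nu)) + max(boff) - j0 < 1 ||
      all(1L + boff - j0 > nr))
    warning("deconvolve: no unknown couples into the objective window; lower objective_min",
            call. = FALSE)
  applyA <- function(g) {       # objective rows from unknowns (bins 1..nu)
    out <- numeric(nr)
    for (i in seq_along(boff)) {
      # unknown u maps to grid row u + boff -> objective row u + boff - j0
      u <- seq_len(nu)
      rr <- u + boff[i] - j0
      ok <- rr >= 1L & rr <= nr
      if (any(ok)) out[rr[ok]] <- out[rr[ok]] + bval[i] * g[u[ok]]
    }
    out
  }
  applyAt <- function(r) {
    out <- numeric(nu)
    for (i in seq_along(boff)) {
      u <- seq_len(nu)
      rr <- u + boff[i] - j0
      ok <- rr >= 1L & rr <= nr
      if (any(ok)) out[u[ok]] <- out[u[ok]] + bval[i] * r[rr[ok]]
    }
    out
  }

  if (cfg$solver == "lawson-hanson") {
    A <- pi_operator_matrix(op, rows = rows, cols = unk)
    if (lam > 0) {
      D <- diff(diag(nu))
      A <- rbind(A, lam * D)
      b2 <- c(b, numeric(nu - 1))
    } else b2 <- b
    sol <- pracma::lsqnonneg(A, b2)
    g <- sol$x
    iters <- NA_integer_
  } else {
    applyD <- function(g) if (lam > 0) lam * diff(g) else numeric(0)
    applyDt <- function(r) {
      if (lam == 0) return(numeric(nu))
      out <- numeric(nu)
      out[1:(nu - 1)] <- -lam * r
      out[2:nu] <- out[2:nu] + lam * r
      out
    }
    applyH <- function(g) applyAt(applyA(g)) + applyDt(applyD(g))
    v <- stats::runif(nu)
    for (i in 1:30) {
      v <- applyH(v)
      nv <- sqrt(sum(v^2))
      if (nv == 0) break
      v <- v / nv
    }
    L <- max(nv, 1e-12) * 1.02
    rhs <- applyAt(b)
    proj <- function(g) pmin(pmax(g, lo), hi)
    g <- proj(numeric(nu))
    y <- g
    tt <- 1
    obj <- function(g) {
      r <- applyA(g) - b
      sum(r^2) + sum(applyD(g)^2)
    }
    ob <- obj(g)
    iters <- 0L
    for (it in seq_len(cfg$max_iter)) {
      gn <- proj(y - (applyH(y) - rhs) / L)
      on <- obj(gn)
      if (on > ob) {            # monotone restart
        gn <- proj(g - (applyH(g) - rhs) / L)
        on <- obj(gn)
        tt <- 1
      }
      tn <- (1 + sqrt(1 + 4 * tt^2)) / 2
      y <- gn + ((tt - 1) / tn) * (gn - g)
      delta <- max(abs(gn - g))
      g <- gn
      tt <- tn
      iters <- it
      if (delta < cfg$tol * max(1, max(abs(g))) && it > 10) break
      ob <- on
    }
  }

  full <- numeric(length(z))
  full[unk] <- g
  out <- zspectrum(g_pi$grid, full, wT, level = "dec", meta = g_pi$meta)
  res <- applyA(g) - b
  attr(out, "residual_norm") <- sqrt(sum(res^2))
  attr(out, "iterations") <- iters
  attr(out, "objective") <- sum(res^2) +
    if (lam > 0) sum((lam * diff(g))^2) else 0
  attr(out, "solver") <- cfg$solver
  out
}

#' Quantum harmonic correction of a spectrum
#'
#' Multiplies a (deconvolved or classical) density of states by the
#' single-bead weight function w(omega') = omega' coth(omega'), which maps
#' classical harmonic amplitudes onto their quantum expectation: low
#' frequencies are unchanged, high frequencies amplified.
#'
#' @param s an `rd_spectrum`
#' @param w1 a P = 1 `weight_table` (e.g. [weight_table_p1()]) covering the
#'   spectrum's reduced-frequency range
#' @param omega_T_cm1 thermal scale in cm^-1
#' @return an `rd_spectrum` of level "q"
#' @export
quantum_correct <- function(s, w1, omega_T_cm1) {
  stopifnot(inherits(s, "rd_spectrum"), inherits(w1, "weight_table"))
  if (w1$P != 1L) stop("quantum_correct: w1 must be a P = 1 table", call. = FALSE)
  xr <- s$omega / omega_T_cm1
  if (max(xr) > max(w1$omega_red) + 1e-9)
    stop("quantum_correct: weight table does not cover the spectrum range", call. = FALSE)
  w <- weight_at(w1, pmin(xr, max(w1$omega_red)))
  spectrum(s$omega, s$values * w, level = "q", meta = s$meta)
}

#' Gaussian smoothing of a spectrum
#'
#' Resamples onto a uniform grid and convolves with a Gaussian kernel.
#' Deconvolved densities are spiky at the z-bin scale; smoothing to a fixed
#' resolution makes their peak heights comparable with directly computed
#' spectra.
#'
#' @param s an `rd_spectrum`
#' @param sigma Gaussian width in cm^-1 (default 25)
#' @param step resampling step in cm^-1
#' @return a smoothed `rd_spectrum`
#' @export
smooth_spectrum <- function(s, sigma = 25, step = 2) {
  stopifnot(inherits(s, "rd_spectrum"))
  om <- seq(min(s$omega), max(s$omega), by = step)
  vi <- stats::approx(s$omega, s$values, om)$y
  k <- stats::dnorm(seq(-4 * sigma, 4 * sigma, by = step), 0, sigma)
  k <- k / sum(k)
  vs <- stats::filter(vi, k, sides = 2)
  vs[is.na(vs)] <- 0
  spectrum(om, as.numeric(vs), level = s$level, meta = s$meta)
}

#' Locate a spectral peak
#'
#' @param s an `rd_spectrum`
#' @param range frequency window (cm^-1) to search, default full
#' @param method "quadratic": parabola through the three bins around the
#'   maximum (sub-bin accuracy on smooth peaks); "centroid":
#'   intensity-weighted mean over the window (robust for spiky deconvolved
#'   densities)
#' @return peak position in cm^-1
#' @export
peak_position <- function(s, range = NULL,
                          method = c("quadratic", "centroid")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "rd_spectrum"))
  sel <- if (is.null(range)) seq_along(s$omega)
         else which(s$omega >= range[1] & s$omega <= range[2])
  if (length(sel) < 3) stop("peak_position: window too narrow", call. = FALSE)
  x <- s$omega[sel]
  y <- s$values[sel]
  if (method == "centroid") return(sum(x * y) / sum(y))
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(x[i])
  d <- (y[i - 1] - y[i + 1]) / 2 / (y[i - 1] - 2 * y[i] + y[i + 1])
  x[i] + d * (x[i + 1] - x[i])
}
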