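#' Uniform grid in the squared reduced frequency z = omega'^2
#'
#' The path-integral effect on vibrational frequencies becomes a pure
#' convolution when spectra are expressed in z = (omega/omega_T)^2, so all
#' Toeplitz machinery lives on a uniform z grid.
#'
#' @param z_max upper end of the grid (dimensionless), z_min is always 0
#' @param spacing constant increment Delta z (> 0)
#' @return an object of class `zgrid` with fields `z_values`, `spacing`, `n`
#' @export
zgrid <- function(z_max, spacing) {
  stopifnot(is.numeric(z_max), is.numeric(spacing), length(z_max) == 1L,
            length(spacing) == 1L)
  if (spacing <= 0) stop("zgrid: spacing must be > 0", call. = FALSE)
  n <- floor(z_max / spacing + 1e-9) + 1L
  if (n < 2L) stop("zgrid: need at least 2 points", call. = FALSE)
  g <- structure(
    list(z_values = spacing * (0:(n - 1L)), spacing = spacing, n = n),
    class = "zgrid")
  validate_zgrid(g)
  g
}

validate_zgrid <- function(g) {
  stopifnot(inherits(g, "zgrid"))
  z <- g$z_values
  if (g$n < 2L || length(z) != g$n) stop("zgrid: inconsistent length", call. = FALSE)
  if (z[1] < 0) stop("zgrid: grid must start at z >= 0", call. = FALSE)
  dz <- diff(z)
  if (any(dz <= 0)) stop("zgrid: z values must be strictly increasing", call. = FALSE)
  if (max(abs(dz - g$spacing)) > 1e-12 * max(1, g$spacing))
    stop("zgrid: spacing is not uniform", call. = FALSE)
  invisible(g)
}

#' @export
print.zgrid <- function(x, ...) {
  cat(sprintf("<zgrid> %d points, z in [%g, %g], spacing %g\n",
              x$n, x$z_values[1], x$z_values[x$n], x$spacing))
  invisible(x)
}

#' Choose a z-grid spacing commensurate with the ring-polymer offsets
#'
#' The offsets c_k = P^2 sin^2(k pi / P) are integer multiples of a common
#' spacing only for P in {2, 3, 4, 6}. For other bead counts each c_k is
#' snapped to the nearest grid multiple; the spacing is searched so that the
#' largest snap error stays below `spacing / snap_tol_div`.
#'
#' @param P bead count (>= 2)
#' @param target desired approximate spacing (dimensionless z units)
#' @param snap_tol_div snap tolerance divisor; a spacing is acceptable when
#'   max_k |c_k - round(c_k/dz)*dz| < dz / snap_tol_div
#' @return list with `spacing`, `snap_error` (largest |c_k - m_k dz|) and
#'   `commensurate` flag
#' @export
choose_z_spacing <- function(P, target = 0.05, snap_tol_div = 20) {
  ck <- normal_mode_offsets(P)
  cu <- unique(round(ck, 12))
  snap_err <- function(dz) max(abs(cu - round(cu / dz) * dz))
  # candidate spacings: divisors of the smallest and of the largest offset
  # (the latter is exactly P^2 for even P); simultaneous Diophantine
  # approximation guarantees acceptable candidates within the scan range
  mmax <- max(50L, ceiling(max(cu) / target) * 4L)
  cand <- sort(unique(c(min(cu) / seq_len(ceiling(min(cu) / target) * 4L),
                        max(cu) / seq_len(mmax))), decreasing = TRUE)
  cand <- cand[cand > 0 & cand <= 4 * target]
  best <- NULL
  ok <- NULL
  for (dz in cand) {
    e <- snap_err(dz)
    if (is.null(best) || e / dz < best$rel)
      best <- list(spacing = dz, err = e, rel = e / dz)
    if (e < dz / snap_tol_div &&
        (is.null(ok) || abs(log(dz / target)) < abs(log(ok$spacing / target))))
      ok <- list(spacing = dz, snap_error = e, commensurate = e < 1e-9 * dz)
  }
  if (!is.null(ok)) return(ok)
  warning(sprintf(
    "choose_z_spacing: no spacing near %g met the snap tolerance for P = %d; using best found (snap error %.3g)",
    target, P, best$err))
  list(spacing = best$spacing, snap_error = best$err, commensurate = FALSE)
}
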