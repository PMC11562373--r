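#' Read a flat key = value config file
#'
#' Lines are `key = value`; `#` starts a comment; blank lines ignored.
#'
#' @param path file path
#' @return named list of character values
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- list()
  for (i in seq_along(ln)) {
    m <- regmatches(ln[i], regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln[i]))[[1]]
    if (length(m) != 3)
      stop(sprintf("read_config: %s: cannot parse line %d: '%s'",
                   path, i, ln[i]), call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

header_block <- function(meta) {
  paste0("# ", names(meta), ": ", unlist(meta))
}

parse_header <- function(lines) {
  hd <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hd) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.-]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write / read a spectrum as two-column TSV
#'
#' Columns: frequency (cm^-1) and density; `#` header lines carry level and
#' provenance metadata including the frequency units. Reading a file whose
#' declared units differ from cm^-1 is a hard error, never a silent
#' conversion.
#'
#' @param s an `rd_spectrum`
#' @param path file path
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "rd_spectrum"))
  meta <- c(list(format = "ringdeconv-spectrum", units = "cm-1",
                 level = s$level),
            s$meta[vapply(s$meta, function(x)
              is.character(x) || (is.numeric(x) && length(x) == 1), TRUE)])
  writeLines(c(header_block(meta),
               sprintf("%.12g\t%.12g", s$omega, s$values)), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @return `read_spectrum` returns an `rd_spectrum`
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("read_spectrum: no such file: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  hd <- parse_header(ln)
  if (!identical(hd$units, "cm-1"))
    stop(sprintf("read_spectrum: %s declares units '%s', expected 'cm-1'",
                 path, hd$units %||% "<missing>"), call. = FALSE)
  body <- ln[!grepl("^#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop(sprintf("read_spectrum: %s: malformed data line %d", path, bad[1]),
         call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m))
    stop("read_spectrum: non-numeric data in ", path, call. = FALSE)
  lvl <- hd$level %||% "cl"
  hd$format <- NULL; hd$units <- NULL; hd$level <- NULL
  spectrum(m[, 1], m[, 2], level = lvl,
           meta = lapply(hd, function(x) {
             xx <- suppressWarnings(as.numeric(x))
             if (is.na(xx)) x else xx
           }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a weight table as two-column TSV
#'
#' Columns: reduced frequency omega' and weight w; the `#` header carries
#' the bead count, method and iteration count, matching the layout of
#' publicly deposited weight-function tables so users can diff against
#' them.
#'
#' @param tb a `weight_table`
#' @param path file path
#' @export
write_weight_table <- function(tb, path) {
  validate_weight_table(tb)
  meta <- list(format = "ringdeconv-weights", P = tb$P, method = tb$method,
               iterations = tb$iterations,
               centroid_excluded = tolower(tb$centroid_excluded))
  writeLines(c(header_block(meta),
               sprintf("%.12g\t%.12g", tb$omega_red, tb$w)), path)
  invisible(path)
}

#' @rdname write_weight_table
#' @return `read_weight_table` returns a `weight_table`
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("read_weight_table: no such file: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  hd <- parse_header(ln)
  body <- ln[!grepl("^#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop(sprintf("read_weight_table: %s: malformed data line %d", path, bad[1]),
         call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("read_weight_table: non-numeric data in ", path, call. = FALSE)
  if (is.unsorted(m[, 1], strictly = TRUE))
    stop("read_weight_table: non-monotone frequency grid in ", path, call. = FALSE)
  new_weight_table(as.integer(hd$P %||% stop("read_weight_table: header lacks P")),
                   m[, 1], m[, 2],
                   hd$method %||% "unknown",
                   as.integer(hd$iterations %||% 0),
                   identical(hd$centroid_excluded, "true"))
}

model_elements <- function(model) {
  switch(model$kind, harmonic1d = "X", morse_diatomic = c("O", "H"),
         c("O", "H", "H"))
}

#' Write a trajectory in extended-XYZ format
#'
#' One frame per recorded step carrying centroid positions (when recorded)
#' and centroid velocities in atomic units; the comment line declares the
#' properties, the time stamp and `units=atomic`. Bead-resolved snapshots
#' (from [write_state()]) are flagged by a `bead=` key instead.
#'
#' @param traj an `rp_trajectory`
#' @param path file path
#' @param elements atom labels (default: from the trajectory's model)
#' @export
write_trajectory <- function(traj, path, elements = NULL) {
  stopifnot(inherits(traj, "rp_trajectory"))
  na <- length(traj$masses)
  if (is.null(elements)) elements <- model_elements(traj$model)
  xs <- traj$centroid_positions
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in seq_along(traj$times)) {
    writeLines(as.character(na), con)
    writeLines(sprintf(
      "Properties=species:S:1:pos:R:3:vel:R:3 time=%.6f units=atomic", traj$times[fr]), con)
    v <- matrix(traj$centroid_velocities[fr, ], na, 3, byrow = TRUE)
    x <- if (!is.null(xs)) matrix(xs[fr, ], na, 3, byrow = TRUE) else matrix(0, na, 3)
    writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                       elements, x[, 1], x[, 2], x[, 3],
                       v[, 1], v[, 2], v[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_trajectory()]
#'
#' @param path file path
#' @param dt frame spacing override (fs); taken from time stamps otherwise
#' @return list with `times` (fs), `elements`, `positions` and `velocities`
#'   (frames x 3N matrices); malformed frames raise errors naming the frame
#' @export
read_trajectory <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("read_trajectory: no such file: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  i <- 1L
  fr <- 0L
  times <- numeric(0)
  pos <- list()
  vel <- list()
  elements <- NULL
  while (i <= length(ln)) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1L; next }
    fr <- fr + 1L
    na <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(na) || na < 1)
      stop(sprintf("read_trajectory: %s: bad atom count in frame %d", path, fr),
           call. = FALSE)
    if (i + 1L + na > length(ln))
      stop(sprintf("read_trajectory: %s: truncated frame %d", path, fr), call. = FALSE)
    cm <- ln[i + 1L]
    if (!grepl("units=atomic", cm))
      stop(sprintf("read_trajectory: %s: frame %d lacks 'units=atomic' (refusing unit guesswork)",
                   path, fr), call. = FALSE)
    tm <- regmatches(cm, regexec("time=([0-9eE.+-]+)", cm))[[1]]
    times[fr] <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
    rows <- strsplit(trimws(ln[i + 1L + seq_len(na)]), "\\s+")
    if (any(lengths(rows) != 7))
      stop(sprintf("read_trajectory: %s: malformed atom line in frame %d", path, fr),
           call. = FALSE)
    el <- vapply(rows, `[`, "", 1)
    num <- matrix(as.numeric(unlist(lapply(rows, `[`, -1))), na, 6, byrow = TRUE)
    if (anyNA(num))
      stop(sprintf("read_trajectory: %s: non-numeric coordinates in frame %d", path, fr),
           call. = FALSE)
    if (is.null(elements)) elements <- el
    pos[[fr]] <- as.numeric(t(num[, 1:3, drop = FALSE]))
    vel[[fr]] <- as.numeric(t(num[, 4:6, drop = FALSE]))
    i <- i + 2L + na
  }
  if (fr == 0) stop("read_trajectory: ", path, ": no frames", call. = FALSE)
  if (anyNA(times)) times <- (seq_len(fr) - 1) * (dt %||% 1)
  list(times = times, elements = elements,
       positions = do.call(rbind, pos), velocities = do.call(rbind, vel))
}

#' Write a bead-resolved ring-polymer snapshot as extended-XYZ
#'
#' One frame per bead, flagged by a `bead=` key in the comment line.
#'
#' @param state an `rp_state`
#' @param path file path
#' @param elements atom labels
#' @export
write_state <- function(state, path, elements = NULL) {
  stopifnot(inherits(state, "rp_state"))
  na <- length(state$masses)
  if (is.null(elements)) elements <- rep("X", na)
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(state$P)) {
    writeLines(as.character(na), con)
    writeLines(sprintf(
      "Properties=species:S:1:pos:R:3:vel:R:3 bead=%d units=atomic", j - 1L), con)
    x <- matrix(state$x[j, ], na, 3, byrow = TRUE)
    v <- matrix(state$v[j, ], na, 3, byrow = TRUE)
    writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                       elements, x[, 1], x[, 2], x[, 3], v[, 1], v[, 2], v[, 3]), con)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run writes exactly one manifest (JSON) next to its
#' outputs: the command, the configuration snapshot, the master seed, the
#' package version, a timestamp, and the input/output paths. Two runs with
#' equal manifests produce byte-identical numeric outputs.
#'
#' @param path output path (.json)
#' @param command command name
#' @param config named list (configuration snapshot)
#' @param seed master seed
#' @param inputs,outputs character vectors of paths
#' @export
write_manifest <- function(path, command, config, seed, inputs = character(),
                           outputs = character()) {
  jsonlite::write_json(list(
    command = command, config = config, seed = seed,
    package_version = as.character(utils::packageVersion("ringdeconv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, outputs = outputs),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
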