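# In-memory session model and CSV I/O.
#
# The log dialect is a 13-column CSV: sampling time (ms), accelerometer
# x/y/z (g), gyroscope x/y/z (deg/s), magnetometer x/y/z (gauss), and the
# pitch, roll and heading angles (deg), nominally logged at 100 Hz.

SESSION_COLUMNS <- c("t_ms", "acc_x", "acc_y", "acc_z",
                     "gyro_x", "gyro_y", "gyro_z",
                     "mag_x", "mag_y", "mag_z",
                     "pitch", "roll", "heading")

#' Construct a validated IMU session
#'
#' @param samples Data frame with the 13 canonical columns (`t_ms`, `acc_x`,
#'   `acc_y`, `acc_z`, `gyro_x`, `gyro_y`, `gyro_z`, `mag_x`, `mag_y`,
#'   `mag_z`, `pitch`, `roll`, `heading`). Columns may be supplied in that
#'   positional order without names.
#' @param fs Sampling rate in Hz; inferred from the median time step when
#'   `NULL`.
#' @param meta Named list of session metadata (pool length, swimmer id, ...).
#' @param normalize_angles Wrap heading into `[0, 360)` and roll into
#'   `[-180, 180)` instead of erroring (default `TRUE`). Pitch must lie in
#'   `[-90, 90]` either way.
#' @return An object of class `imu_session`: a list with elements `samples`
#'   (data frame), `fs`, and `meta`.
#' @export
imu_session <- function(samples, fs = NULL, meta = list(),
                        normalize_angles = TRUE) {
  samples <- as.data.frame(samples)
  if (ncol(samples) != 13L) {
    stop(sprintf("expected 13 columns, got %d", ncol(samples)))
  }
  names(samples) <- SESSION_COLUMNS
  if (nrow(samples) == 0L) stop("no samples")
  for (col in SESSION_COLUMNS) {
    v <- samples[[col]]
    if (!is.numeric(v)) stop(sprintf("column '%s' is not numeric", col))
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite values in column '%s' (first at row %d)",
                   col, which(!is.finite(v))[1L]))
    }
  }
  if (nrow(samples) > 1L && any(diff(samples$t_ms) <= 0)) {
    stop("non-monotone timestamps")
  }
  if (normalize_angles) {
    samples$heading <- wrap360(samples$heading)
    samples$roll <- wrap180(samples$roll)
  }
  if (any(abs(samples$pitch) > 90 + 1e-9)) {
    stop("pitch outside [-90, 90]")
  }
  samples$pitch <- pmin(90, pmax(-90, samples$pitch))
  if (any(samples$heading < 0 | samples$heading >= 360)) {
    stop("heading outside [0, 360)")
  }
  if (any(samples$roll < -180 | samples$roll > 180)) {
    stop("roll outside [-180, 180]")
  }
  if (is.null(fs)) {
    if (nrow(samples) < 2L) stop("cannot infer sampling rate from one sample")
    fs <- 1000 / median(diff(samples$t_ms))
  }
  if (!is.finite(fs) || fs <= 0) stop("sampling rate must be positive")
  if (nrow(samples) > 1L) {
    med_dt <- median(diff(samples$t_ms)) / 1000
    if (abs(med_dt - 1 / fs) > 0.1 / fs) {
      stop(sprintf(
        "median sample interval %.4g s inconsistent with fs = %g Hz",
        med_dt, fs))
    }
  }
  structure(list(samples = samples, fs = fs, meta = meta),
            class = "imu_session")
}

#' @export
print.imu_session <- function(x, ...) {
  dur <- diff(range(x$samples$t_ms)) / 1000
  cat(sprintf("<imu_session> %d samples, %.4g Hz, %.1f s\n",
              nrow(x$samples), x$fs, dur))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Session time axis in seconds
#' @param session An `imu_session`.
#' @return Numeric vector of sample times in seconds since log start.
#' @export
session_time <- function(session) session$samples$t_ms / 1000

#' Read a session log
#'
#' Reads the 13-column CSV dialect. An optional header row is recognized by
#' a non-numeric first field. Heading is wrapped into `[0, 360)` and roll
#' into `[-180, 180)`; pitch must already lie in `[-90, 90]`.
#'
#' @param path Path to a CSV file.
#' @param fs_hint Sampling rate in Hz; inferred from the median time step
#'   when `NULL`.
#' @param meta Optional metadata list attached to the session.
#' @return An [imu_session].
#' @export
read_session <- function(path, fs_hint = NULL, meta = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- count.fields(path, sep = ",", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (!length(nf)) stop("no samples (empty file)")
  first <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  data_rows <- if (has_header) seq_along(nf)[-1L] else seq_along(nf)
  if (!length(data_rows)) stop("no samples (header-only file)")
  bad <- data_rows[nf[data_rows] != 13L]
  if (length(bad)) {
    stop(sprintf("row %d has %d fields, expected 13", bad[1L], nf[bad[1L]]))
  }
  df <- read.csv(path, header = has_header, colClasses = "numeric")
  if (nrow(df) == 0L) stop("no samples")
  bad_num <- which(!stats::complete.cases(df))
  if (length(bad_num)) {
    stop(sprintf("non-numeric field in data row %d", bad_num[1L]))
  }
  imu_session(df, fs = fs_hint, meta = meta)
}

#' Write a session log
#'
#' Writes the 13-column CSV dialect with a header row. Values round-trip
#' through [read_session()] to within numeric print precision.
#'
#' @param session An [imu_session].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "imu_session"))
  if (nrow(session$samples) == 0L) stop("refusing to write empty session")
  write.csv(format(session$samples, digits = 15, scientific = FALSE,
                   trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check sampling uniformity
#'
#' The fixed-rate FIR filters downstream assume uniform sampling; this
#' reports any interval deviating from `1/fs` by more than `tol` of the
#' nominal step.
#'
#' @param session An [imu_session].
#' @param tol Fractional tolerance on the sample interval (default 0.1).
#' @return List with `uniform` (logical) and `gaps` (data frame of
#'   offending interval indices and their durations in seconds).
#' @export
check_uniform_sampling <- function(session, tol = 0.1) {
  stopifnot(inherits(session, "imu_session"))
  t <- session_time(session)
  if (length(t) < 2L) stop("need at least 2 samples")
  dt <- diff(t)
  target <- 1 / session$fs
  bad <- which(abs(dt - target) > tol * target)
  list(uniform = length(bad) == 0L,
       gaps = data.frame(index = bad, dt_s = dt[bad]))
}

#' Linearly resample a session onto a uniform grid
#'
#' Explicit repair for non-uniform logs; never applied automatically.
#'
#' @param session An [imu_session].
#' @param fs Target sampling rate in Hz (default: the session's nominal fs).
#' @return A uniformly sampled [imu_session].
#' @export
resample_session <- function(session, fs = session$fs) {
  t <- session_time(session)
  tg <- seq(t[1L], t[length(t)], by = 1 / fs)
  df <- data.frame(t_ms = round(tg * 1000, 6))
  for (col in SESSION_COLUMNS[-1L]) {
    x <- session$samples[[col]]
    if (col == "heading") {
      hu <- unwrap_heading(x)
      df[[col]] <- wrap360(approx(t, hu, xout = tg)$y)
    } else {
      df[[col]] <- approx(t, x, xout = tg)$y
    }
  }
  imu_session(df, fs = fs, meta = session$meta)
}

# Extract the sample index range [i1, i2] covering [t1, t2] (seconds).
session_span <- function(session, t1, t2) {
  t <- session_time(session)
  i1 <- which(t >= t1 - 1e-9)[1L]
  i2 <- rev(which(t <= t2 + 1e-9))[1L]
  if (is.na(i1) || is.na(i2) || i2 < i1) return(NULL)
  c(i1, i2)
}
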