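# Seeded synthetic swim sessions with ground truth.
#
# The generator emulates the signal features the analysis stages consume:
#  * nonsymmetrical styles (front crawl, backstroke): the lower-back roll
#    shows one rotation excursion per arm stroke, alternating sides. Each
#    excursion is a raised-cosine burst occupying a fraction (`stroke_duty`)
#    of the stroke cycle, with a neutral glide between bursts. The burst
#    structure keeps peak amplitudes well above the k-sigma gating band
#    used by the stroke counter (a pure sinusoid's extrema sit at only
#    sqrt(2) standard deviations and would be invisible to gates with
#    k >= sqrt(2)).
#  * symmetrical styles (butterfly, breaststroke): the pitch undulates
#    sinusoidally, one cycle per stroke, bounded by minima.
#  * turns: pitch excursions toward +/-90 deg with a ~180 deg heading
#    reversal; bucket/cross-over variants (backstroke) mute the pitch
#    excursion below the detection band, exercising the MAD-outlier
#    recovery path. Stops hold pitch near -90 deg for several seconds.
#  * the z accelerometer sits near -1 g for backstroke (supine) and +1 g
#    otherwise; per-axis low-frequency oscillation amplitudes reproduce the
#    qualitative energy-feature geometry (front crawl dominant in y;
#    butterfly above breaststroke in z and x).

# Default additive noise levels (the source study reports none; these are
# plausible consumer-AHRS figures, stated in the methods vignette).
DEFAULT_NOISE_SD_DEG <- 1.5
DEFAULT_NOISE_SD_G <- 0.03

#' Default generator noise levels
#' @return List with `deg` (angle noise sd, degrees) and `g` (accelerometer
#'   noise sd, g units).
#' @export
default_noise <- function() list(deg = DEFAULT_NOISE_SD_DEG,
                                 g = DEFAULT_NOISE_SD_G)

# Per-style defaults: stroke counts/rates sized for a 25 m pool lap; target
# mean energy-feature geometry in m/s^2 (pre-rounding), see vignette.
STYLE_DEFAULTS <- list(
  front_crawl  = list(n_strokes = 20L, stroke_rate = 50, roll_amplitude = 45,
                      pitch_amplitude = 0,  energy = c(2,   6, 2)),
  backstroke   = list(n_strokes = 18L, stroke_rate = 45, roll_amplitude = 40,
                      pitch_amplitude = 0,  energy = c(2,   5, 2)),
  butterfly    = list(n_strokes = 14L, stroke_rate = 40, roll_amplitude = 0,
                      pitch_amplitude = 35, energy = c(4,   2, 6)),
  breaststroke = list(n_strokes = 10L, stroke_rate = 30, roll_amplitude = 0,
                      pitch_amplitude = 30, energy = c(1.5, 1, 2))
)

#' Specify one synthetic lap
#'
#' @param style Stroke style.
#' @param n_strokes Number of strokes (nonsymmetrical styles: individual arm
#'   strokes; symmetrical styles: stroke cycles). Style-specific default.
#' @param stroke_rate Strokes per minute (same unit as `n_strokes`).
#' @param roll_amplitude Peak roll per stroke burst, degrees (nonsymmetrical).
#' @param pitch_amplitude Pitch undulation amplitude, degrees (symmetrical).
#' @param pitch_offset Baseline pitch, degrees (slightly negative: legs low).
#' @param stroke_duty Fraction of each stroke cycle occupied by the roll
#'   burst (nonsymmetrical styles), default 0.35.
#' @param lead_s Glide time prepended/appended to the stroke train, seconds.
#' @param turn_artifact Append a distorted extra pitch cycle at the lap end
#'   (symmetrical styles), emulating the continuous rotation into the turn
#'   approach; it is not a true stroke and should be rejected by the DTW
#'   template stage.
#' @return A `lap_spec` list.
#' @export
lap_spec <- function(style, n_strokes = NULL, stroke_rate = NULL,
                     roll_amplitude = NULL, pitch_amplitude = NULL,
                     pitch_offset = -5, stroke_duty = 0.35, lead_s = NULL,
                     turn_artifact = FALSE) {
  style <- match.arg(style, SWIM_STYLES)
  d <- STYLE_DEFAULTS[[style]]
  spec <- list(
    style = style,
    n_strokes = if (is.null(n_strokes)) d$n_strokes else as.integer(n_strokes),
    stroke_rate = if (is.null(stroke_rate)) d$stroke_rate else stroke_rate,
    roll_amplitude = if (is.null(roll_amplitude)) d$roll_amplitude
                     else roll_amplitude,
    pitch_amplitude = if (is.null(pitch_amplitude)) d$pitch_amplitude
                      else pitch_amplitude,
    pitch_offset = pitch_offset,
    stroke_duty = stroke_duty,
    lead_s = if (is.null(lead_s)) {
      if (style %in% SYMMETRIC_STYLES) 0.35 else 0.6
    } else lead_s,
    turn_artifact = isTRUE(turn_artifact)
  )
  if (spec$n_strokes < 0L) stop("n_strokes must be >= 0")
  if (spec$stroke_rate <= 0) stop("stroke_rate must be positive")
  if (spec$roll_amplitude < 0 || spec$pitch_amplitude < 0) {
    stop("amplitudes must be nonnegative")
  }
  if (spec$stroke_duty <= 0 || spec$stroke_duty > 1) {
    stop("stroke_duty must be in (0, 1]")
  }
  cycle_s <- 60 / spec$stroke_rate
  extra <- if (spec$turn_artifact) cycle_s else 0
  spec$duration_s <- 2 * spec$lead_s + spec$n_strokes * cycle_s + extra
  class(spec) <- "lap_spec"
  spec
}

# Raised-cosine (Hann) pulse of unit peak on [0, width], zero elsewhere.
hann_pulse <- function(t, center, width) {
  u <- t - center
  ifelse(abs(u) <= width / 2, 0.5 * (1 + cos(2 * pi * u / width)), 0)
}

g_amp_for_energy <- function(e) e * pi / (2 * GRAVITY_MS2)

#' Generate one synthetic lap
#'
#' Draws from the current RNG stream (seed it, or use [generate_session()]
#' which seeds for you).
#'
#' @param spec A [lap_spec()].
#' @param fs Sampling rate in Hz.
#' @param noise_sd_deg Additive Gaussian noise sd on angles, degrees.
#' @param noise_sd_g Additive Gaussian noise sd on accelerations, g.
#' @return List with `signals` (data frame: `t`, `pitch`, `roll`, `acc_x`,
#'   `acc_y`, `acc_z`) and `truth` (style, stroke times, polarities, cycle
#'   boundaries, artifact times, duration).
#' @export
generate_lap <- function(spec, fs = 100, noise_sd_deg = 0, noise_sd_g = 0) {
  stopifnot(inherits(spec, "lap_spec"), fs > 0)
  dur <- spec$duration_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  cyc <- 60 / spec$stroke_rate
  lead <- spec$lead_s
  ns <- spec$n_strokes
  sym <- spec$style %in% SYMMETRIC_STYLES

  pitch <- rep(spec$pitch_offset, n)
  roll <- numeric(n)
  stroke_times <- numeric(0)
  polarity <- character(0)
  cycle_bounds <- numeric(0)
  artifact_times <- numeric(0)

  if (ns > 0L) {
    if (sym) {
      span <- t >= 0 & t <= 2 * lead + ns * cyc
      pitch[span] <- spec$pitch_offset -
        spec$pitch_amplitude * cos(2 * pi * (t[span] - lead) / cyc)
      cycle_bounds <- lead + (0:ns) * cyc
      stroke_times <- lead + (seq_len(ns) - 0.5) * cyc
      if (spec$turn_artifact) {
        # distorted extra cycle: same amplitude and minima, peaky waveform
        a0 <- lead + ns * cyc
        in_art <- t > a0 & t < a0 + cyc
        u <- (t[in_art] - a0) / cyc
        pitch[in_art] <- spec$pitch_offset -
          spec$pitch_amplitude * cos(2 * pi * u)^5
        artifact_times <- a0 + 0.5 * cyc
      }
    } else {
      centers <- lead + (seq_len(ns) - 0.5) * cyc
      width <- spec$stroke_duty * cyc
      sgn <- rep_len(c(1, -1), ns)
      for (k in seq_len(ns)) {
        roll <- roll + sgn[k] * spec$roll_amplitude *
          hann_pulse(t, centers[k], width)
      }
      stroke_times <- centers
      polarity <- ifelse(sgn > 0, "max", "min")
      # gentle pitch ripple at half the stroke rate, inside the swim band
      pitch <- pitch + 3 * sin(pi * (t - lead) / cyc)
    }
  }

  e <- STYLE_DEFAULTS[[spec$style]]$energy * runif(3, 0.85, 1.15)
  amp <- g_amp_for_energy(e)
  ph <- runif(3, 0, 2 * pi)
  f_e <- 0.2  # Hz, well inside the 0.5 Hz classification passband
  az_dc <- if (spec$style == "backstroke") -1 else 1
  acc_x <- amp[1] * sin(2 * pi * f_e * t + ph[1])
  acc_y <- amp[2] * sin(2 * pi * f_e * t + ph[2])
  acc_z <- az_dc + amp[3] * sin(2 * pi * f_e * t + ph[3])

  if (noise_sd_deg > 0) {
    pitch <- pitch + rnorm(n, 0, noise_sd_deg)
    roll <- roll + rnorm(n, 0, noise_sd_deg)
  }
  if (noise_sd_g > 0) {
    acc_x <- acc_x + rnorm(n, 0, noise_sd_g)
    acc_y <- acc_y + rnorm(n, 0, noise_sd_g)
    acc_z <- acc_z + rnorm(n, 0, noise_sd_g)
  }
  pitch <- pmin(90, pmax(-90, pitch))

  list(
    signals = data.frame(t = t, pitch = pitch, roll = roll,
                         acc_x = acc_x, acc_y = acc_y, acc_z = acc_z),
    truth = list(style = spec$style, n_strokes = ns,
                 stroke_times = stroke_times, polarity = polarity,
                 cycle_bounds = cycle_bounds,
                 artifact_times = artifact_times, duration_s = dur)
  )
}

TURN_VARIANTS <- c("tumble", "open", "bucket", "crossover", "stop")

#' Generate a turn or stop angle fragment
#'
#' @param variant One of `"tumble"`, `"open"`, `"bucket"`, `"crossover"`,
#'   `"stop"`. Bucket/cross-over are backstroke wall turns whose pitch
#'   excursion stays below the detection band (recovered downstream via
#'   lap-time outliers plus heading reversal).
#' @param duration_s Event duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param turn_sign Sign of the pitch excursion for tumble/open turns.
#' @param heading_from,heading_to Heading (degrees) before/after the event;
#'   a smooth reversal ramp connects them.
#' @param pitch_base Baseline pitch, degrees.
#' @return List with `signals` (data frame `pitch`, `roll`, `heading`) and
#'   `truth` (kind, variant, apex_t, start_t, end_t relative to the
#'   fragment).
#' @export
insert_event <- function(variant, duration_s, fs = 100, turn_sign = 1,
                         heading_from = 0, heading_to = 180,
                         pitch_base = -5) {
  variant <- match.arg(variant, TURN_VARIANTS)
  if (duration_s <= 0) stop("duration must be positive")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  kind <- if (variant == "stop") "stop" else "turn"
  if (variant == "stop") {
    edge <- min(0.75, duration_s / 4)
    s <- rep(1, n)
    rise <- t < edge
    fall <- t > duration_s - edge
    s[rise] <- 0.5 * (1 - cos(pi * t[rise] / edge))
    s[fall] <- 0.5 * (1 - cos(pi * (duration_s - t[fall]) / edge))
    pitch <- pitch_base + (-88 - pitch_base) * s
    apex_t <- duration_s / 2
  } else {
    apex <- if (variant %in% c("bucket", "crossover")) 12 else 88
    pitch <- pitch_base +
      turn_sign * apex * hann_pulse(t, duration_s / 2, duration_s)
    apex_t <- duration_s / 2
  }
  ramp <- 0.5 * (1 - cos(pi * t / duration_s))
  heading <- heading_from + wrap180(heading_to - heading_from) * ramp
  list(
    signals = data.frame(pitch = pitch, roll = 0, heading = heading),
    truth = list(kind = kind, variant = variant, apex_t = apex_t,
                 start_t = 0, end_t = duration_s)
  )
}

#' Specify a synthetic session
#'
#' @param laps List of [lap_spec()] objects (order = swim order).
#' @param events Character vector of boundary event variants, length
#'   `length(laps) - 1`; default all `"tumble"`.
#' @param turn_duration_s Duration of turn events, seconds.
#' @param stop_duration_s Duration of stop events, seconds.
#' @param noise_sd_deg Additive Gaussian angle noise sd, degrees.
#' @param noise_sd_g Additive Gaussian acceleration noise sd, g.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; fixed seed implies bit-reproducible output.
#' @return A `session_spec` list.
#' @export
session_spec <- function(laps, events = NULL, turn_duration_s = 1.6,
                         stop_duration_s = 5,
                         noise_sd_deg = DEFAULT_NOISE_SD_DEG,
                         noise_sd_g = DEFAULT_NOISE_SD_G,
                         fs = 100, seed = 1L) {
  if (!length(laps)) stop("empty lap list")
  stopifnot(all(vapply(laps, inherits, logical(1), "lap_spec")))
  if (is.null(events)) events <- rep("tumble", length(laps) - 1L)
  if (length(events) != length(laps) - 1L) {
    stop("need one boundary event per adjacent lap pair")
  }
  events <- vapply(events, match.arg, character(1), choices = TURN_VARIANTS)
  structure(list(laps = laps, events = unname(events),
                 turn_duration_s = turn_duration_s,
                 stop_duration_s = stop_duration_s,
                 noise_sd_deg = noise_sd_deg, noise_sd_g = noise_sd_g,
                 fs = fs, seed = seed),
            class = "session_spec")
}

#' Generate a synthetic session with ground truth
#'
#' Concatenates laps and boundary events at the session sampling rate, adds
#' seeded Gaussian noise, and returns the aligned ground truth. The same
#' seed yields identical output.
#'
#' @param spec A [session_spec()].
#' @return List with `session` (an [imu_session]) and `truth` (lap table,
#'   event table, per-lap stroke times, per-lap artifact times).
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  fs <- spec$fs
  n_laps <- length(spec$laps)
  heading_base <- ifelse(seq_len(n_laps) %% 2L == 1L, 0, 180)

  pieces <- list()
  lap_rows <- list()
  ev_rows <- list()
  strokes <- vector("list", n_laps)
  artifacts <- vector("list", n_laps)
  offset <- 0
  for (i in seq_len(n_laps)) {
    lap <- generate_lap(spec$laps[[i]], fs = fs)
    nlap <- nrow(lap$signals)
    pieces[[length(pieces) + 1L]] <- data.frame(
      pitch = lap$signals$pitch, roll = lap$signals$roll,
      heading = rep(heading_base[i], nlap),
      acc_x = lap$signals$acc_x, acc_y = lap$signals$acc_y,
      acc_z = lap$signals$acc_z)
    lap_rows[[i]] <- data.frame(
      index = i, start_t = offset, end_t = offset + lap$truth$duration_s,
      lap_time = lap$truth$duration_s, style = lap$truth$style,
      n_strokes = lap$truth$n_strokes, stringsAsFactors = FALSE)
    strokes[[i]] <- offset + lap$truth$stroke_times
    artifacts[[i]] <- offset + lap$truth$artifact_times
    offset <- offset + nlap / fs

    if (i < n_laps) {
      variant <- spec$events[i]
      dur <- if (variant == "stop") spec$stop_duration_s
             else spec$turn_duration_s
      ev <- insert_event(variant, dur, fs = fs,
                         turn_sign = if (variant == "open") -1 else 1,
                         heading_from = heading_base[i],
                         heading_to = heading_base[i + 1L],
                         pitch_base = spec$laps[[i]]$pitch_offset)
      nev <- nrow(ev$signals)
      az_from <- if (spec$laps[[i]]$style == "backstroke") -1 else 1
      az_to <- if (spec$laps[[i + 1L]]$style == "backstroke") -1 else 1
      frac <- (seq_len(nev) - 1L) / max(1L, nev - 1L)
      pieces[[length(pieces) + 1L]] <- data.frame(
        pitch = ev$signals$pitch, roll = ev$signals$roll,
        heading = ev$signals$heading,
        acc_x = 0, acc_y = 0, acc_z = az_from + (az_to - az_from) * frac)
      ev_rows[[i]] <- data.frame(
        index = i, kind = ev$truth$kind, variant = variant,
        apex_t = offset + ev$truth$apex_t, start_t = offset,
        end_t = offset + dur, duration = dur, stringsAsFactors = FALSE)
      offset <- offset + nev / fs
    }
  }

  sig <- do.call(rbind, pieces)
  n <- nrow(sig)
  t <- (seq_len(n) - 1L) / fs

  pitch_c <- sig$pitch
  roll_c <- sig$roll
  head_c <- sig$heading
  # gyro from clean angle derivatives; magnetometer from clean heading
  gyro_x <- c(0, diff(roll_c)) * fs
  gyro_y <- c(0, diff(pitch_c)) * fs
  gyro_z <- c(0, wrap180(diff(head_c))) * fs

  sdd <- spec$noise_sd_deg
  sdg <- spec$noise_sd_g
  pitch <- pitch_c + if (sdd > 0) rnorm(n, 0, sdd) else 0
  roll <- roll_c + if (sdd > 0) rnorm(n, 0, sdd) else 0
  heading <- head_c + if (sdd > 0) rnorm(n, 0, sdd) else 0
  acc <- cbind(sig$acc_x, sig$acc_y, sig$acc_z)
  if (sdg > 0) acc <- acc + matrix(rnorm(3 * n, 0, sdg), n, 3)
  hr <- head_c * pi / 180
  mag <- cbind(0.3 * cos(hr), -0.3 * sin(hr), rep(0.35, n)) +
    matrix(rnorm(3 * n, 0, 0.01), n, 3)

  samples <- data.frame(
    t_ms = (seq_len(n) - 1L) * (1000 / fs),
    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
    gyro_x = gyro_x + rnorm(n, 0, 0.5),
    gyro_y = gyro_y + rnorm(n, 0, 0.5),
    gyro_z = gyro_z + rnorm(n, 0, 0.5),
    mag_x = mag[, 1], mag_y = mag[, 2], mag_z = mag[, 3],
    pitch = pmin(90, pmax(-90, pitch)),
    roll = wrap180(roll),
    heading = wrap360(heading))

  list(
    session = imu_session(samples, fs = fs,
                          meta = list(synthetic = TRUE, seed = spec$seed)),
    truth = list(
      laps = do.call(rbind, lap_rows),
      events = if (length(ev_rows)) do.call(rbind, ev_rows) else
        data.frame(index = integer(), kind = character(),
                   variant = character(), apex_t = numeric(),
                   start_t = numeric(), end_t = numeric(),
                   duration = numeric()),
      strokes = strokes,
      artifacts = artifacts)
  )
}
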