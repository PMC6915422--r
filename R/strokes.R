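# Per-lap stroke counting.
#
# Nonsymmetrical styles (front crawl, backstroke): every trunk-roll peak
# (maxima and minima alike) is one arm stroke. The roll is low-passed at
# 3 Hz (48-order Hamming), extrema are gated by a per-style k-sigma band
# and a minimum rotation of 20 deg.
#
# Symmetrical styles (butterfly, breaststroke): one pitch undulation per
# stroke cycle, bounded by consecutive pitch minima. Minima pass the same
# k-sigma gate; each cycle is resampled to 200 samples and compared (via
# dynamic time warping of its central 50%) against a mean-wave template so
# that distorted non-stroke segments are discarded.

#' Stroke-counting parameters
#'
#' @param k_by_style Named vector of k multipliers for the k-sigma gating
#'   band: front crawl 2, backstroke 2.36, breaststroke 0.74, butterfly
#'   1.34.
#' @param min_rotation_deg Minimum |roll| at a peak for nonsymmetrical
#'   styles, degrees (default 20).
#' @param cutoff_hz Counting filter cutoff (default 3).
#' @param filter_order Counting filter order (default 48).
#' @param min_peak_sep_s Minimum separation between same-polarity extrema,
#'   seconds (default 0.25; suppresses noise doubles).
#' @param dtw_reject Fixed DTW rejection threshold, or `NULL` (default) for
#'   the self-calibrating rule: 3 times the median cycle-to-template
#'   distance of the lap's own cycles.
#' @param resample_n Samples per normalized cycle (default 200).
#' @return A `counting_params` list.
#' @export
counting_params <- function(k_by_style = c(front_crawl = 2,
                                           backstroke = 2.36,
                                           breaststroke = 0.74,
                                           butterfly = 1.34),
                            min_rotation_deg = 20, cutoff_hz = 3,
                            filter_order = 48L, min_peak_sep_s = 0.25,
                            dtw_reject = NULL, resample_n = 200L) {
  stopifnot(all(k_by_style > 0), min_rotation_deg > 0, cutoff_hz > 0,
            filter_order > 0, min_peak_sep_s > 0, resample_n >= 4L)
  structure(list(k_by_style = k_by_style,
                 min_rotation_deg = min_rotation_deg,
                 cutoff_hz = cutoff_hz, filter_order = filter_order,
                 min_peak_sep_s = min_peak_sep_s, dtw_reject = dtw_reject,
                 resample_n = as.integer(resample_n)),
            class = "counting_params")
}

#' k-sigma band mask
#'
#' Marks samples lying outside the band `mean(A) +/- k * sd(A)` (sample
#' standard deviation). Stroke peaks are the large deflections, so extrema
#' must fall outside the band to count. A constant series has zero sd and
#' an all-`FALSE` mask.
#'
#' @param A Numeric series (at least 2 samples).
#' @param k Band multiplier.
#' @return Logical vector, `TRUE` where the sample is outside the band.
#' @export
band_mask <- function(A, k) {
  if (length(A) < 2L) stop("need at least 2 samples")
  s <- sd(A)
  abs(A - mean(A)) > k * s
}

#' Detect roll-peak strokes (nonsymmetrical styles)
#'
#' Filters the roll signal (3 Hz, 48-order Hamming low-pass), finds local
#' maxima and minima, and keeps extrema that are both outside the style's
#' k-sigma band and of magnitude at least `min_rotation_deg`. Each
#' surviving extremum (either polarity) is one stroke.
#'
#' @param roll Roll series in degrees over one lap.
#' @param fs Sampling rate in Hz.
#' @param style `"front_crawl"` or `"backstroke"`.
#' @param params A [counting_params()].
#' @return List with `events` (data frame `t`, `peak_value`, `polarity`)
#'   and `rejected` (data frame of gated-out candidate extrema).
#' @export
detect_roll_strokes <- function(roll, fs, style,
                                params = counting_params()) {
  style <- match.arg(style, c("front_crawl", "backstroke"))
  rf <- hamming_lowpass(roll, fs, params$cutoff_hz, params$filter_order)
  t <- (seq_along(rf) - 1L) / fs
  ex <- local_extrema(rf, min_sep = max(1L, round(params$min_peak_sep_s * fs)))
  if (!nrow(ex)) {
    return(list(events = data.frame(t = numeric(), peak_value = numeric(),
                                    polarity = character()),
                rejected = data.frame(t = numeric(), peak_value = numeric(),
                                      polarity = character())))
  }
  outside <- band_mask(rf, params$k_by_style[[style]])
  keep <- outside[ex$idx] & abs(ex$value) >= params$min_rotation_deg
  events <- data.frame(t = t[ex$idx[keep]], peak_value = ex$value[keep],
                       polarity = ex$kind[keep], stringsAsFactors = FALSE)
  rejected <- data.frame(t = t[ex$idx[!keep]], peak_value = ex$value[!keep],
                         polarity = ex$kind[!keep], stringsAsFactors = FALSE)
  list(events = events, rejected = rejected)
}

# Resample a cycle segment to n samples on a normalized time grid.
resample_cycle <- function(x, n) {
  if (length(x) < 2L) stop("cycle too short to resample")
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = n))$y
}

#' Detect pitch stroke cycles (symmetrical styles)
#'
#' Filters the pitch signal (3 Hz, 48-order Hamming low-pass), finds local
#' minima gated by the style's k-sigma band, and forms stroke cycles
#' between consecutive surviving minima, each resampled to 200 samples.
#'
#' @param pitch Pitch series in degrees over one lap.
#' @param fs Sampling rate in Hz.
#' @param style `"breaststroke"` or `"butterfly"`.
#' @param params A [counting_params()].
#' @return List with `cycles` (data frame `start_t`, `end_t`, `pitch_min`,
#'   `pitch_max`), `resampled` (cycles x 200 matrix), and `rejected`
#'   (data frame of band-rejected candidate minima). Fewer than two
#'   surviving minima yields zero cycles.
#' @export
detect_pitch_cycles <- function(pitch, fs, style,
                                params = counting_params()) {
  style <- match.arg(style, c("breaststroke", "butterfly"))
  pf <- hamming_lowpass(pitch, fs, params$cutoff_hz, params$filter_order)
  t <- (seq_along(pf) - 1L) / fs
  ex <- local_extrema(pf, min_sep = max(1L, round(params$min_peak_sep_s * fs)))
  mins <- ex[ex$kind == "min", , drop = FALSE]
  outside <- band_mask(pf, params$k_by_style[[style]])
  keep <- if (nrow(mins)) outside[mins$idx] else logical(0)
  rejected <- data.frame(t = t[mins$idx[!keep]],
                         peak_value = mins$value[!keep],
                         polarity = rep("min", sum(!keep)),
                         stringsAsFactors = FALSE)
  mins <- mins[keep, , drop = FALSE]
  ncyc <- max(0L, nrow(mins) - 1L)
  cycles <- data.frame(start_t = numeric(ncyc), end_t = numeric(ncyc),
                       pitch_min = numeric(ncyc), pitch_max = numeric(ncyc))
  res <- matrix(NA_real_, ncyc, params$resample_n)
  for (j in seq_len(ncyc)) {
    i1 <- mins$idx[j]; i2 <- mins$idx[j + 1L]
    seg <- pf[i1:i2]
    cycles$start_t[j] <- t[i1]
    cycles$end_t[j] <- t[i2]
    cycles$pitch_min[j] <- min(seg)
    cycles$pitch_max[j] <- max(seg)
    res[j, ] <- resample_cycle(seg, params$resample_n)
  }
  list(cycles = cycles, resampled = res, rejected = rejected)
}

#' Build the mean-wave template
#'
#' Pointwise mean, across cycles, of the central 50% of the 200-sample
#' normalized pitch cycle (samples 51-150, i.e. 25% to 75% of the segment
#' between consecutive minima).
#'
#' @param resampled Cycles x 200 matrix from [detect_pitch_cycles()].
#' @return List with `wave` (length-100 numeric) and `central_idx` (the
#'   column range used).
#' @export
build_mean_wave <- function(resampled) {
  resampled <- as.matrix(resampled)
  if (!nrow(resampled)) stop("need at least one cycle")
  n <- ncol(resampled)
  idx <- (n %/% 4 + 1L):(3L * (n %/% 4))
  list(wave = colMeans(resampled[, idx, drop = FALSE]), central_idx = idx)
}

#' Dynamic time warping distance
#'
#' Classic DTW with squared-difference local cost, symmetric steps (match,
#' insert, delete) and no warping window; returns the square root of the
#' accumulated optimal-path cost (Euclidean flavor). Identical series have
#' distance zero.
#'
#' @param a,b Nonempty numeric series.
#' @return Nonnegative scalar.
#' @export
dtw_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) stop("empty series")
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    cost <- (a[i] - b)^2
    row_prev <- D[i, ]
    row_cur <- D[i + 1L, ]
    for (j in seq_len(m)) {
      row_cur[j + 1L] <- cost[j] +
        min(row_prev[j], row_prev[j + 1L], row_cur[j])
    }
    D[i + 1L, ] <- row_cur
  }
  sqrt(D[n + 1L, m + 1L])
}

#' Reject outlier cycles against the mean-wave template
#'
#' Discards cycles whose central-50% segment is farther (DTW) from the
#' template than the rejection threshold. With the default self-calibrated
#' threshold (3 times the median distance of the lap's own cycles), an
#' all-alike corpus keeps everything while a distorted turn-approach
#' segment is discarded.
#'
#' @param resampled Cycles x 200 matrix.
#' @param template A [build_mean_wave()] result.
#' @param threshold Fixed threshold, or `NULL` for self-calibration.
#' @return List with `keep` (logical per cycle), `distances`, and
#'   `threshold` (the value actually applied).
#' @export
reject_outlier_cycles <- function(resampled, template, threshold = NULL) {
  resampled <- as.matrix(resampled)
  if (!nrow(resampled)) {
    return(list(keep = logical(0), distances = numeric(0),
                threshold = threshold %||% NA_real_))
  }
  d <- vapply(seq_len(nrow(resampled)), function(j) {
    dtw_distance(resampled[j, template$central_idx], template$wave)
  }, numeric(1))
  # the 1e-6 floor guards the degenerate all-identical case, where the
  # median distance is pure floating-point noise
  if (is.null(threshold)) threshold <- 3 * median(d) + 1e-6
  list(keep = d <= threshold, distances = d, threshold = threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count strokes in one lap
#'
#' Dispatches on style: roll-extrema counting for front crawl and
#' backstroke; pitch-cycle counting with DTW outlier rejection for
#' butterfly and breaststroke. Kept symmetric-style cycles are reported at
#' their center time.
#'
#' @param pitch,roll Lap angle series in degrees.
#' @param fs Sampling rate in Hz.
#' @param style Stroke style.
#' @param params A [counting_params()].
#' @return List with `count`, `stroke_times` (seconds from lap start),
#'   `events` (roll styles), `cycles` + `keep` + `distances` (pitch
#'   styles), and `rejected_times` (candidate detections that were gated
#'   or DTW-rejected).
#' @export
count_strokes <- function(pitch, roll, fs, style,
                          params = counting_params()) {
  style <- match.arg(style, SWIM_STYLES)
  min_len <- params$filter_order + 1L
  if (length(pitch) < min_len || length(roll) < min_len) {
    if (length(pitch) == 0L && length(roll) == 0L) {
      return(list(count = 0L, stroke_times = numeric(0),
                  rejected_times = numeric(0)))
    }
    stop("lap shorter than the counting filter")
  }
  if (style %in% SYMMETRIC_STYLES) {
    det <- detect_pitch_cycles(pitch, fs, style, params)
    if (!nrow(det$cycles)) {
      return(list(count = 0L, stroke_times = numeric(0),
                  cycles = det$cycles, keep = logical(0),
                  distances = numeric(0),
                  rejected_times = det$rejected$t))
    }
    tmpl <- build_mean_wave(det$resampled)
    rej <- reject_outlier_cycles(det$resampled, tmpl, params$dtw_reject)
    centers <- (det$cycles$start_t + det$cycles$end_t) / 2
    list(count = sum(rej$keep),
         stroke_times = centers[rej$keep],
         cycles = det$cycles, resampled = det$resampled, keep = rej$keep,
         distances = rej$distances, template = tmpl,
         rejected_times = c(det$rejected$t, centers[!rej$keep]))
  } else {
    det <- detect_roll_strokes(roll, fs, style, params)
    list(count = nrow(det$events), stroke_times = det$events$t,
         events = det$events, rejected_times = det$rejected$t)
  }
}
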