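# Turn/stop detection and lap segmentation from the pitch angle.
#
# While swimming, pitch stays inside roughly +/-20 deg. A turn drives pitch
# toward +/-90 deg briefly; a stop drives it to -90 deg and holds. Backstroke
# bucket/cross-over turns can leave no pitch excursion; those are recovered
# by flagging excessively long lap times (scaled-MAD outliers) and locating
# the heading reversal inside the flagged lap.

#' Segmentation parameters
#'
#' @param swim_band_deg Normal-swimming pitch band half-width, degrees
#'   (default 20).
#' @param apex_trigger_deg Pitch magnitude that triggers an event, degrees
#'   (default 70, i.e. "close to 90").
#' @param stop_min_s Minimum out-of-band dwell (or triggering extremum
#'   separation) for an event to be a stop rather than a turn, seconds
#'   (default 3).
#' @param refine_window_s Averaging window used to refine event boundaries,
#'   seconds (default 0.5).
#' @param mad_scale Scaled-MAD multiplier for lap-time outliers (default 3).
#' @param heading_reversal_deg Accumulated heading change that counts as a
#'   reversal, degrees (default 150).
#' @param heading_horizon_s Horizon within which the reversal must
#'   accumulate, seconds (default 5).
#' @param merge_gap_s Trigger excursions closer than this are merged into
#'   one event, seconds (default 0.25).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(swim_band_deg = 20, apex_trigger_deg = 70,
                                stop_min_s = 3, refine_window_s = 0.5,
                                mad_scale = 3, heading_reversal_deg = 150,
                                heading_horizon_s = 5, merge_gap_s = 0.25) {
  p <- list(swim_band_deg = swim_band_deg,
            apex_trigger_deg = apex_trigger_deg,
            stop_min_s = stop_min_s, refine_window_s = refine_window_s,
            mad_scale = mad_scale,
            heading_reversal_deg = heading_reversal_deg,
            heading_horizon_s = heading_horizon_s,
            merge_gap_s = merge_gap_s)
  if (any(unlist(p) <= 0)) stop("all segmentation parameters must be positive")
  if (swim_band_deg >= apex_trigger_deg) {
    stop("swim_band_deg must be below apex_trigger_deg")
  }
  class(p) <- "segmentation_params"
  p
}

#' Detect turn and stop events in a pitch series
#'
#' Each maximal excursion of |pitch| beyond the apex trigger yields one
#' event. An event is a stop when the separation between the local pitch
#' maximum and minimum governing the excursion (or, for a monotone
#' excursion, the out-of-band dwell) is at least `stop_min_s`; otherwise it
#' is a turn. Returned events carry provisional boundaries (the trigger
#' region edges); use [refine_boundaries()] for the reported start/end.
#'
#' @param pitch Pitch series in degrees, uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param params A [segmentation_params()].
#' @return Data frame of events (`kind`, `apex_t`, `start_t`, `end_t`,
#'   `apex_pitch`), ordered by apex time; zero rows means a single-lap swim.
#' @export
detect_events <- function(pitch, fs, params = segmentation_params()) {
  n <- length(pitch)
  t <- (seq_len(n) - 1L) / fs
  out <- abs(pitch) > params$apex_trigger_deg
  empty <- data.frame(kind = character(), apex_t = numeric(),
                      start_t = numeric(), end_t = numeric(),
                      apex_pitch = numeric(), stringsAsFactors = FALSE)
  if (!any(out)) return(empty)
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge trigger crossings separated by less than merge_gap_s
  gap <- round(params$merge_gap_s * fs)
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (j in 2L:nrow(runs)) {
      if (runs$start[j] - merged$end[nrow(merged)] <= gap) {
        merged$end[nrow(merged)] <- runs$end[j]
      } else {
        merged <- rbind(merged, runs[j, ])
      }
    }
    runs <- merged
  }
  ev <- lapply(seq_len(nrow(runs)), function(j) {
    i1 <- runs$start[j]; i2 <- runs$end[j]
    seg <- pitch[i1:i2]
    apex_i <- i1 - 1L + which.max(abs(seg))
    # governing extrema: within the surrounding out-of-swim-band region
    b1 <- i1
    while (b1 > 1L && abs(pitch[b1 - 1L]) > params$swim_band_deg) b1 <- b1 - 1L
    b2 <- i2
    while (b2 < n && abs(pitch[b2 + 1L]) > params$swim_band_deg) b2 <- b2 + 1L
    ex <- local_extrema(pitch[b1:b2])
    sep <- if (nrow(ex) >= 2L) {
      (max(ex$idx[ex$kind == "max"], -Inf) -
         min(ex$idx[ex$kind == "min"], Inf))
    } else NA_real_
    sep_s <- if (is.finite(sep)) abs(sep) / fs else NA_real_
    dwell_s <- (i2 - i1 + 1L) / fs
    is_stop <- (!is.na(sep_s) && sep_s >= params$stop_min_s) ||
      dwell_s >= params$stop_min_s
    data.frame(kind = if (is_stop) "stop" else "turn",
               apex_t = t[apex_i], start_t = t[i1], end_t = t[i2],
               apex_pitch = pitch[apex_i], stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  ev[order(ev$apex_t), , drop = FALSE]
}

#' Refine event boundaries by windowed mean re-entry
#'
#' Slides a window of `refine_window_s` one sample at a time before and
#' after the event apex, searching for the latest pre-apex (earliest
#' post-apex) instant at which the window-average pitch lies inside the
#' normal swimming band. Boundaries are clipped to the signal edges when
#' the band is never re-entered.
#'
#' @param pitch Pitch series in degrees.
#' @param fs Sampling rate in Hz.
#' @param event One-row event data frame (as from [detect_events()]).
#' @param params A [segmentation_params()].
#' @return The event with `start_t`/`end_t` replaced by refined values.
#' @export
refine_boundaries <- function(pitch, fs, event,
                              params = segmentation_params()) {
  n <- length(pitch)
  t <- (seq_len(n) - 1L) / fs
  w <- max(1L, round(params$refine_window_s * fs))
  apex_i <- which.min(abs(t - event$apex_t))
  band <- params$swim_band_deg

  trail <- rolling_mean_trailing(pitch, w)  # mean over (i-w, i]
  lead <- rolling_mean_leading(pitch, w)    # mean over [i, i+w)
  ok_before <- which(!is.na(trail) & abs(trail) <= band & seq_len(n) <= apex_i)
  ok_after <- which(!is.na(lead) & abs(lead) <= band & seq_len(n) >= apex_i)
  event$start_t <- if (length(ok_before)) t[max(ok_before)] else t[1L]
  event$end_t <- if (length(ok_after)) t[min(ok_after)] else t[n]
  event
}

#' Scaled median absolute deviation
#'
#' `c * median(|x_i - median(x)|)` with the normal-consistency constant
#' `c = 1.4826`.
#'
#' @param values Numeric vector (at least one value).
#' @param constant Consistency constant (default 1.4826).
#' @return Nonnegative scalar.
#' @export
scaled_mad <- function(values, constant = 1.4826) {
  if (!length(values)) stop("empty vector")
  stats::mad(values, constant = constant)
}

#' Flag excessively long lap times as outliers
#'
#' An observation is an outlier when it deviates from the median by more
#' than `mad_scale` scaled MADs. With a zero MAD (all-equal times), only
#' exact-median values are inliers.
#'
#' @param lap_times Lap durations in seconds (at least 3 for a meaningful
#'   median).
#' @param mad_scale Multiplier on the scaled MAD (default 3).
#' @return Integer vector of outlier indices.
#' @export
lap_time_outliers <- function(lap_times, mad_scale = 3) {
  m <- median(lap_times)
  s <- scaled_mad(lap_times)
  which(abs(lap_times - m) > mad_scale * s)
}

#' Recover a pitch-silent turn inside an outlier lap
#'
#' Locates a sustained heading reversal (accumulated circular change of at
#' least `heading_reversal_deg` within `heading_horizon_s`), places the
#' apex at the local pitch maximum nearest the reversal midpoint, and
#' refines boundaries. Returns `NULL` when no reversal exists (a genuinely
#' long lap).
#'
#' @param pitch,heading Full-session angle series in degrees.
#' @param fs Sampling rate in Hz.
#' @param lap One-row lap data frame (`start_t`, `end_t`) flagged as an
#'   outlier.
#' @param params A [segmentation_params()].
#' @return One-row event data frame, or `NULL`.
#' @export
recover_missed_turns <- function(pitch, heading, fs, lap,
                                 params = segmentation_params()) {
  n <- length(pitch)
  t <- (seq_len(n) - 1L) / fs
  i1 <- max(1L, which(t >= lap$start_t)[1L])
  i2 <- min(n, rev(which(t <= lap$end_t))[1L])
  if (i2 - i1 < 2L) return(NULL)
  hu <- unwrap_heading(heading[i1:i2])
  hor <- min(length(hu) - 1L, round(params$heading_horizon_s * fs))
  if (hor < 1L) return(NULL)
  delta <- abs(hu[(1L + hor):length(hu)] - hu[seq_len(length(hu) - hor)])
  if (max(delta) < params$heading_reversal_deg) return(NULL)
  # several windows can cover the full ramp; anchor on the best one, then
  # place the reversal midpoint where the heading crosses halfway
  j <- which.max(delta)
  w1 <- j; w2 <- j + hor
  half <- (hu[w1] + hu[w2]) / 2
  mid_j <- w1 - 1L + which.min(abs(hu[w1:w2] - half))
  mid_i <- i1 - 1L + mid_j
  # apex: pitch maximum close to the reversal midpoint
  a1 <- max(i1, mid_i - round(fs)); a2 <- min(i2, mid_i + round(fs))
  apex_i <- a1 - 1L + which.max(pitch[a1:a2])
  # pitch never leaves the swim band here, so the windowed-mean refinement
  # is degenerate; take the event extent from the heading transition
  # instead (10% and 90% crossings of the reversal ramp)
  span <- abs(hu[w2] - hu[w1])
  prog <- abs(hu[w1:w2] - hu[w1])
  apex_rel <- apex_i - i1 + 1L
  start_rel <- min(w1 - 1L + which(prog >= 0.1 * span)[1L], apex_rel - 1L)
  end_rel <- max(w1 - 1L + which(prog >= 0.9 * span)[1L], apex_rel + 1L)
  data.frame(kind = "turn", apex_t = t[apex_i],
             start_t = t[i1 - 1L + max(1L, start_rel)],
             end_t = t[i1 - 1L + min(i2 - i1 + 1L, end_rel)],
             apex_pitch = pitch[apex_i], stringsAsFactors = FALSE)
}

#' Cut a session into laps between events
#'
#' Laps are the maximal intervals between the session start, event
#' boundaries (end of one event to start of the next), and the session
#' end; zero-length intervals are dropped. Lap time excludes the adjoining
#' events' durations.
#'
#' @param session An [imu_session].
#' @param events Event data frame (refined boundaries), ordered by apex.
#' @return Data frame of laps (`index`, `start_t`, `end_t`, `lap_time`,
#'   `start_i`, `end_i` with a half-open sample span `[start_i, end_i)`).
#' @export
segment_laps <- function(session, events) {
  t <- session_time(session)
  n <- length(t)
  if (nrow(events) > 1L) {
    if (any(diff(events$apex_t) <= 0)) stop("events must be ordered")
    if (any(events$start_t[-1L] < head(events$end_t, -1L))) {
      stop("overlapping events")
    }
  }
  bounds_start <- c(t[1L], events$end_t)
  bounds_end <- c(events$start_t, t[n])
  laps <- data.frame(start_t = bounds_start, end_t = bounds_end)
  laps <- laps[laps$end_t - laps$start_t > 1e-9, , drop = FALSE]
  if (!nrow(laps)) {
    return(data.frame(index = integer(), start_t = numeric(),
                      end_t = numeric(), lap_time = numeric(),
                      start_i = integer(), end_i = integer()))
  }
  laps$index <- seq_len(nrow(laps))
  laps$lap_time <- laps$end_t - laps$start_t
  laps$start_i <- vapply(laps$start_t,
                         function(s) which(t >= s - 1e-9)[1L], integer(1))
  laps$end_i <- vapply(laps$end_t, function(e) {
    i <- rev(which(t <= e + 1e-9))[1L]
    i + 1L  # half-open
  }, integer(1))
  rownames(laps) <- NULL
  laps[, c("index", "start_t", "end_t", "lap_time", "start_i", "end_i")]
}

#' Segment a session into laps (full procedure)
#'
#' Runs pitch-based event detection, boundary refinement, lap cutting, and
#' then iteratively recovers pitch-silent turns inside scaled-MAD lap-time
#' outliers via heading reversal, re-segmenting after each recovery.
#'
#' @param session An [imu_session].
#' @param params A [segmentation_params()].
#' @param max_recover Maximum number of recovery passes (default 5).
#' @return List with `laps`, `events` (both data frames), and
#'   `recovered` (number of recovered turns).
#' @export
segment_session <- function(session, params = segmentation_params(),
                            max_recover = 5L) {
  pitch <- session$samples$pitch
  heading <- session$samples$heading
  fs <- session$fs
  events <- detect_events(pitch, fs, params)
  if (nrow(events)) {
    events <- do.call(rbind, lapply(seq_len(nrow(events)), function(j) {
      refine_boundaries(pitch, fs, events[j, , drop = FALSE], params)
    }))
  }
  laps <- segment_laps(session, events)
  recovered <- 0L
  repeat {
    if (recovered >= max_recover || nrow(laps) < 3L) break
    out <- lap_time_outliers(laps$lap_time, params$mad_scale)
    out <- out[laps$lap_time[out] > median(laps$lap_time)]  # long laps only
    found <- FALSE
    for (j in out) {
      ev <- recover_missed_turns(pitch, heading, fs,
                                 laps[j, , drop = FALSE], params)
      if (!is.null(ev)) {
        events <- rbind(events, ev)
        events <- events[order(events$apex_t), , drop = FALSE]
        laps <- segment_laps(session, events)
        recovered <- recovered + 1L
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  rownames(events) <- NULL
  list(laps = laps, events = events, recovered = recovered)
}
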