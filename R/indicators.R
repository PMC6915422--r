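# Per-lap performance indicators and session reports.
#
# Indicator layout follows the style's dominant motion component: trunk
# elevation applies only to the undulating (symmetrical) styles; body
# balance is an overall pitch mean for nonsymmetrical styles but per-cycle
# pitch max/min statistics for symmetrical ones; body rotation is the
# mirror image on the roll axis.

#' Stroke rate
#' @param count Strokes in the lap.
#' @param lap_time_s Lap time in seconds (excluding adjoining events).
#' @return Strokes per minute.
#' @export
stroke_rate <- function(count, lap_time_s) {
  if (lap_time_s <= 0) stop("lap time must be positive")
  60 * count / lap_time_s
}

indicator_stats <- function(values, role = "overall") {
  data.frame(role = role,
             mean = if (length(values)) mean(values) else NA_real_,
             sd = if (length(values) > 1L) sd(values) else
               if (length(values) == 1L) 0 else NA_real_,
             n = length(values), stringsAsFactors = FALSE)
}

#' Trunk elevation (symmetrical styles)
#'
#' Per stroke cycle, the difference between the maximum and minimum pitch
#' within the cycle; averaged over the lap. Not applicable to
#' nonsymmetrical styles.
#'
#' @param cycles Kept-cycle data frame (`pitch_min`, `pitch_max`) from
#'   [count_strokes()].
#' @param style Stroke style.
#' @return One-row stats data frame, or `NULL` (with attribute-free `NA`
#'   semantics) for nonsymmetrical styles.
#' @export
trunk_elevation <- function(cycles, style) {
  style <- match.arg(style, SWIM_STYLES)
  if (!(style %in% SYMMETRIC_STYLES)) return(NULL)
  if (is.null(cycles) || !nrow(cycles)) stop("need at least one kept cycle")
  indicator_stats(cycles$pitch_max - cycles$pitch_min)
}

#' Body balance (pitch posture)
#'
#' Nonsymmetrical styles: mean and sd of pitch over the lap (goal: constant
#' and near 0). Symmetrical styles: per-cycle pitch maxima and minima
#' statistics (two rows, roles `max` and `min`).
#'
#' @param pitch Lap pitch series in degrees.
#' @param style Stroke style.
#' @param cycles Kept-cycle data frame (symmetrical styles).
#' @return Stats data frame (one or two rows).
#' @export
body_balance <- function(pitch, style, cycles = NULL) {
  style <- match.arg(style, SWIM_STYLES)
  if (!length(pitch)) stop("empty lap")
  if (style %in% SYMMETRIC_STYLES) {
    if (is.null(cycles) || !nrow(cycles)) stop("need kept cycles")
    rbind(indicator_stats(cycles$pitch_max, "max"),
          indicator_stats(cycles$pitch_min, "min"))
  } else {
    indicator_stats(pitch)
  }
}

#' Body rotation (roll)
#'
#' Symmetrical styles: mean and sd of roll over the lap (should be near 0).
#' Nonsymmetrical styles: statistics of stroke-peak roll maxima (one side)
#' and minima (the other side); unequal sides flag stroke asymmetry.
#'
#' @param roll Lap roll series in degrees.
#' @param style Stroke style.
#' @param events Stroke-event data frame (`peak_value`, `polarity`) for
#'   nonsymmetrical styles.
#' @return Stats data frame (one or two rows).
#' @export
body_rotation <- function(roll, style, events = NULL) {
  style <- match.arg(style, SWIM_STYLES)
  if (!length(roll)) stop("empty lap")
  if (style %in% SYMMETRIC_STYLES) {
    indicator_stats(roll)
  } else {
    if (is.null(events)) stop("need stroke events")
    rbind(indicator_stats(events$peak_value[events$polarity == "max"], "max"),
          indicator_stats(events$peak_value[events$polarity == "min"], "min"))
  }
}

#' Detection accuracy against ground truth
#'
#' Matches detections to true event times one-to-one by nearest neighbor
#' within a tolerance window, then evaluates
#' `(TP + TN) / (TP + FP + TN + FN)`. Candidates the algorithm rejected
#' count as true negatives when they are not within tolerance of any true
#' event; rejected candidates adjacent to an already-matched truth are
#' ignored.
#'
#' @param detected Detected event times, seconds.
#' @param truth True event times, seconds.
#' @param rejected Times of candidates the algorithm rejected (default
#'   none).
#' @param tol_s Matching tolerance, seconds (default 0.3).
#' @return List with `accuracy`, `tp`, `fp`, `fn`, `tn`. Empty truth and
#'   empty detections give accuracy 1.
#' @export
detection_accuracy <- function(detected, truth, rejected = numeric(0),
                               tol_s = 0.3) {
  detected <- sort(detected); truth <- sort(truth)
  if (!length(detected) && !length(truth) && !length(rejected)) {
    return(list(accuracy = 1, tp = 0L, fp = 0L, fn = 0L, tn = 0L))
  }
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    if (!length(truth)) break
    gaps <- abs(truth - d)
    gaps[used] <- Inf
    j <- which.min(gaps)
    if (is.finite(gaps[j]) && gaps[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- sum(!used)
  tn <- if (length(rejected)) {
    sum(vapply(rejected, function(r) {
      !length(truth) || min(abs(truth - r)) > tol_s
    }, logical(1)))
  } else 0L
  denom <- tp + fp + tn + fn
  list(accuracy = if (denom == 0L) 1 else (tp + tn) / denom,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Analyze a full session
#'
#' Segments the session into laps, classifies each lap's style, counts
#' strokes, and computes the per-lap indicator set (lap time, stroke rate,
#' trunk elevation, body balance, body rotation).
#'
#' @param session An [imu_session].
#' @param model A `style_model` for the three prone styles, or `NULL` for
#'   the rule fallback.
#' @param seg_params A [segmentation_params()].
#' @param count_params A [counting_params()].
#' @return A `session_report`: list with `laps` (per-lap indicator data
#'   frame), `events`, `style_summary` (per-style aggregates in the
#'   min/max row layout), `detail` (per-lap stroke detections), and
#'   `meta`.
#' @export
analyze_session <- function(session, model = NULL,
                            seg_params = segmentation_params(),
                            count_params = counting_params()) {
  seg <- segment_session(session, seg_params)
  laps <- seg$laps
  t <- session_time(session)
  detail <- vector("list", nrow(laps))
  rows <- vector("list", nrow(laps))
  for (j in seq_len(nrow(laps))) {
    span <- laps$start_i[j]:(laps$end_i[j] - 1L)
    acc <- session$samples[span, c("acc_x", "acc_y", "acc_z")]
    pitch <- session$samples$pitch[span]
    roll <- session$samples$roll[span]
    style <- classify_lap(acc, session$fs, model)
    cnt <- count_strokes(pitch, roll, session$fs, style, count_params)
    sym <- style %in% SYMMETRIC_STYLES
    kept_cycles <- if (sym && !is.null(cnt$cycles)) {
      cnt$cycles[cnt$keep, , drop = FALSE]
    } else NULL
    te <- if (sym && !is.null(kept_cycles) && nrow(kept_cycles)) {
      trunk_elevation(kept_cycles, style)
    } else NULL
    bb <- body_balance(pitch, style, kept_cycles)
    br <- body_rotation(roll, style, cnt$events)
    pick <- function(df, role) {
      if (is.null(df)) return(c(NA_real_, NA_real_))
      r <- df[df$role == role, , drop = FALSE]
      if (!nrow(r)) c(NA_real_, NA_real_) else c(r$mean, r$sd)
    }
    rows[[j]] <- data.frame(
      index = j, style = style,
      start_t = laps$start_t[j], end_t = laps$end_t[j],
      lap_time = laps$lap_time[j],
      stroke_count = cnt$count,
      stroke_rate = stroke_rate(cnt$count, laps$lap_time[j]),
      trunk_elev_mean = pick(te, "overall")[1],
      trunk_elev_sd = pick(te, "overall")[2],
      balance_mean = pick(bb, "overall")[1],
      balance_sd = pick(bb, "overall")[2],
      balance_max_mean = pick(bb, "max")[1],
      balance_max_sd = pick(bb, "max")[2],
      balance_min_mean = pick(bb, "min")[1],
      balance_min_sd = pick(bb, "min")[2],
      rotation_mean = pick(br, "overall")[1],
      rotation_sd = pick(br, "overall")[2],
      rotation_max_mean = pick(br, "max")[1],
      rotation_max_sd = pick(br, "max")[2],
      rotation_min_mean = pick(br, "min")[1],
      rotation_min_sd = pick(br, "min")[2],
      stringsAsFactors = FALSE)
    detail[[j]] <- cnt
  }
  lap_df <- if (length(rows)) do.call(rbind, rows) else NULL
  report <- list(laps = lap_df, events = seg$events,
                 style_summary = summarize_styles(lap_df),
                 detail = detail,
                 meta = c(session$meta,
                          list(fs = session$fs,
                               n_samples = nrow(session$samples),
                               recovered_turns = seg$recovered,
                               schema = "ahrswim-report-1")))
  class(report) <- "session_report"
  report
}

#' Per-style aggregates of a lap table
#'
#' Aggregates lap indicators by style in the min/max row layout: the
#' dominant motion component gets Min and Max rows, the nondominant one a
#' single overall row.
#'
#' @param lap_df Per-lap indicator data frame (as in a `session_report`).
#' @return Data frame with columns `style`, `indicator`, `role`, `mean`,
#'   `sd`, `n_laps`, or `NULL` for an empty input.
#' @export
summarize_styles <- function(lap_df) {
  if (is.null(lap_df) || !nrow(lap_df)) return(NULL)
  blocks <- lapply(split(lap_df, lap_df$style), function(d) {
    sym <- d$style[1] %in% SYMMETRIC_STYLES
    agg <- function(x) c(mean = mean(x[is.finite(x)]),
                         sd = if (sum(is.finite(x)) > 1) sd(x[is.finite(x)])
                              else 0)
    rows <- list()
    add <- function(indicator, role, v) {
      rows[[length(rows) + 1L]] <<- data.frame(
        style = d$style[1], indicator = indicator, role = role,
        mean = v[["mean"]], sd = v[["sd"]], n_laps = nrow(d),
        stringsAsFactors = FALSE)
    }
    add("lap_time", "overall", agg(d$lap_time))
    add("stroke_count", "overall", agg(d$stroke_count))
    add("stroke_rate", "overall", agg(d$stroke_rate))
    if (sym) {
      add("trunk_elevation", "overall", agg(d$trunk_elev_mean))
      add("body_balance", "max", agg(d$balance_max_mean))
      add("body_balance", "min", agg(d$balance_min_mean))
      add("body_rotation", "overall", agg(d$rotation_mean))
    } else {
      add("body_balance", "overall", agg(d$balance_mean))
      add("body_rotation", "max", agg(d$rotation_max_mean))
      add("body_rotation", "min", agg(d$rotation_min_mean))
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Assemble a session report from precomputed lap artifacts
#'
#' Lower-level assembler used by [analyze_session()]; exposed so that lap
#' tables produced elsewhere can be bundled and serialized the same way.
#'
#' @param laps Per-lap indicator data frame (as in a `session_report`).
#' @param events Event data frame.
#' @param meta Metadata list.
#' @return A `session_report`.
#' @export
build_session_report <- function(laps, events, meta = list()) {
  if (!is.null(laps) && nrow(laps) &&
      length(unique(laps$index)) != nrow(laps)) {
    stop("duplicate lap indices")
  }
  structure(list(laps = laps, events = events,
                 style_summary = summarize_styles(laps),
                 detail = NULL,
                 meta = c(meta, list(schema = "ahrswim-report-1"))),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d laps, %d events\n",
              if (is.null(x$laps)) 0L else nrow(x$laps), nrow(x$events)))
  if (!is.null(x$laps)) {
    print(x$laps[, c("index", "style", "lap_time", "stroke_count",
                     "stroke_rate")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a session report to JSON (and optionally tidy CSV)
#'
#' @param report A `session_report`.
#' @param path JSON output path.
#' @param csv_path Optional CSV path for the per-lap table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  stopifnot(inherits(report, "session_report"))
  obj <- report[c("laps", "events", "style_summary", "meta")]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", dataframe = "rows")
  if (!is.null(csv_path)) {
    write.csv(report$laps, csv_path, row.names = FALSE)
  }
  invisible(path)
}
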