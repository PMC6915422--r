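# Angle helpers -------------------------------------------------------------

#' Wrap angles into [-180, 180)
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Wrap angles into [0, 360)
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap360 <- function(x) x %% 360

#' Unwrap a heading series
#'
#' Removes 360-degree jumps so that heading becomes a continuous series,
#' suitable for detecting sustained reversals.
#'
#' @param h Heading series in degrees.
#' @return Unwrapped (continuous) heading in degrees.
#' @export
unwrap_heading <- function(h) {
  if (length(h) < 2L) return(h)
  h[1L] + c(0, cumsum(wrap180(diff(h))))
}

# FIR filtering --------------------------------------------------------------

#' Hamming-windowed FIR low-pass filter
#'
#' Linear-phase FIR low-pass (Hamming-windowed sinc, designed with
#' [signal::fir1()]), applied with reflect padding and group-delay
#' compensation so that peaks stay time-aligned with the input. Coefficients
#' are normalized to unit DC gain.
#'
#' @param x Uniformly sampled numeric series.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; must satisfy `fs > 2 * cutoff`.
#' @param order Filter order (number of taps minus one); must be even.
#'   Default 48.
#' @return Filtered series, same length as `x`.
#' @export
hamming_lowpass <- function(x, fs, cutoff, order = 48L) {
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  if (order %% 2L != 0L) stop("filter order must be even")
  n <- length(x)
  if (n <= order) {
    stop(sprintf("series of %d samples is shorter than the %d-tap filter",
                 n, order + 1L))
  }
  b <- signal::fir1(order, cutoff / (fs / 2), type = "low",
                    window = signal::hamming(order + 1L))
  b <- b / sum(b)
  pad <- order
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- stats::filter(xp, b, method = "convolution", sides = 1)
  delay <- order %/% 2L
  as.numeric(y[pad + delay + seq_len(n)])
}

# Local extrema --------------------------------------------------------------

#' Find local maxima and minima with plateau handling
#'
#' Strict neighbor comparison after collapsing equal-valued plateaus; a
#' plateau extremum is reported at its midpoint sample. A minimum separation
#' (in samples) is enforced per polarity, keeping the more extreme value of
#' any conflicting pair.
#'
#' @param x Numeric series.
#' @param min_sep Minimum separation in samples between kept extrema of the
#'   same polarity (default 1, i.e. no constraint).
#' @return Data frame with columns `idx` (sample index), `value`, and
#'   `kind` (`"max"` or `"min"`), ordered by `idx`.
#' @export
local_extrema <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(idx = integer(), value = numeric(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  r <- rle(x)
  m <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- (starts + ends) %/% 2L
  out_idx <- integer(0)
  out_kind <- character(0)
  if (m >= 3L) {
    v <- r$values
    for (j in 2L:(m - 1L)) {
      if (v[j] > v[j - 1L] && v[j] > v[j + 1L]) {
        out_idx <- c(out_idx, mids[j]); out_kind <- c(out_kind, "max")
      } else if (v[j] < v[j - 1L] && v[j] < v[j + 1L]) {
        out_idx <- c(out_idx, mids[j]); out_kind <- c(out_kind, "min")
      }
    }
  }
  res <- data.frame(idx = out_idx, value = x[out_idx], kind = out_kind,
                    stringsAsFactors = FALSE)
  if (min_sep > 1L && nrow(res) > 1L) {
    keep <- logical(nrow(res))
    for (kind in c("max", "min")) {
      sel <- which(res$kind == kind)
      if (!length(sel)) next
      # greedily accept the most extreme candidates first
      ord <- sel[order(if (kind == "max") -res$value[sel] else res$value[sel])]
      accepted <- integer(0)
      for (i in ord) {
        if (!length(accepted) ||
            all(abs(res$idx[i] - res$idx[accepted]) >= min_sep)) {
          accepted <- c(accepted, i)
          keep[i] <- TRUE
        }
      }
    }
    res <- res[keep, , drop = FALSE]
  }
  res <- res[order(res$idx), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Rolling means --------------------------------------------------------------

# Trailing mean over a window of w samples: out[i] = mean(x[(i-w+1):i]),
# NA where the window is incomplete.
rolling_mean_trailing <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), method = "convolution", sides = 1))
}

# Leading mean: out[i] = mean(x[i:(i+w-1)]).
rolling_mean_leading <- function(x, w) {
  rev(rolling_mean_trailing(rev(x), w))
}
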