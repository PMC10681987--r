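#' Smoothed positive amplitude envelope of an audio signal
#'
#' Characterizes the amplitude modulation of a stimulus waveform the way
#' acoustic-environment figures are drawn: local maxima of the signal are
#' detected, interpolated onto the full sample grid with a cubic spline, and
#' the interpolant is smoothed with a centered moving average (adjacent
#' averaging) of `smoothing_points` samples. Negative spline excursions are
#' clipped to zero, so the result is a non-negative envelope of the same
#' length as the input.
#'
#' @param audio numeric waveform (e.g. `$samples` from [read_wav()]).
#' @param smoothing_points moving-average window length in samples
#'   (default 500).
#' @return numeric envelope, `length(audio)` samples, non-negative.
#' @export
amplitude_envelope <- function(audio, smoothing_points = 500) {
  if (!is.numeric(audio) || length(audio) == 0)
    stop("audio must be a non-empty numeric vector", call. = FALSE)
  if (smoothing_points < 1)
    stop("smoothing_points must be >= 1", call. = FALSE)
  n <- length(audio)
  # interior local maxima (plateaus take their left edge)
  d <- diff(audio)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(peaks) < 4)
    stop("fewer than 4 local maxima: cubic spline underdetermined",
         call. = FALSE)
  if (smoothing_points > length(peaks))
    stop("smoothing_points exceeds the number of extrema (", length(peaks),
         ")", call. = FALSE)
  env <- stats::spline(x = peaks, y = audio[peaks], xout = seq_len(n),
                       method = "fmm")$y
  env <- moving_average(env, smoothing_points)
  pmax(env, 0)
}

# centered moving average; edges use the partial window so output length is
# preserved
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
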