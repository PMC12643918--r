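# Artifact screening, Butterworth low-pass filtering and min-max
# normalization of analysis windows. Screening precedes filtering.

# strict local maxima; plateaus collapse to their first index.
# returns integer indices; boundary samples are never extrema.
local_extrema_idx <- function(x, find = c("max", "min")) {
  find <- match.arg(find)
  x <- as.vector(x)
  if (find == "min") x <- -x
  n <- length(x)
  if (n < 3L) return(integer())
  # run-length compress so plateaus are single candidates
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- 2:(k - 1L)
  is_max <- r$values[interior] > r$values[interior - 1L] &
    r$values[interior] > r$values[interior + 1L]
  starts[interior][is_max]
}

#' Screen a window for artifacts
#'
#' A window is rejected when it contains any zero/negative sample, or when
#' the number of qualifying peaks is below 3 or above 10. A qualifying peak
#' is a strict local maximum whose amplitude exceeds the 75th percentile of
#' the window's samples (linear-interpolation percentile).
#'
#' The peak count is taken on a lightly Savitzky-Golay-smoothed copy of the
#' window (the criterion targets pulse peaks; raw strict maxima would count
#' every noise grain), against the percentile of the raw samples.
#'
#' @param samples Numeric vector of raw window samples.
#' @param min_peaks,max_peaks Accepted range of qualifying peak counts.
#' @param percentile Amplitude percentile a peak must exceed (0-100).
#' @param smooth_window Savitzky-Golay window (samples) used for peak
#'   counting; windows not longer than it are counted unsmoothed.
#' @return A list with `accepted` (logical), `reason` (one of `"ok"`,
#'   `"nonpositive_values"`, `"too_few_peaks"`, `"too_many_peaks"`) and
#'   `n_peaks`.
#' @export
screen_window <- function(samples, min_peaks = 3L, max_peaks = 10L,
                          percentile = 75, smooth_window = 25L) {
  if (!length(samples)) abort("`samples` must be non-empty.")
  if (any(samples <= 0)) {
    return(list(accepted = FALSE, reason = "nonpositive_values",
                n_peaks = NA_integer_))
  }
  thr <- unname(quantile(samples, percentile / 100, type = 7))
  x <- if (length(samples) > smooth_window) {
    as.numeric(signal::sgolayfilt(samples, p = 3, n = smooth_window))
  } else samples
  pk <- local_extrema_idx(x, "max")
  # epsilon guards against counting pure numerical ripple on flat stretches
  eps <- 1e-9 * max(diff(range(samples)), 1e-12)
  n_pk <- sum(x[pk] > thr + eps)
  reason <- if (n_pk < min_peaks) "too_few_peaks"
  else if (n_pk > max_peaks) "too_many_peaks"
  else "ok"
  list(accepted = reason == "ok", reason = reason, n_peaks = n_pk)
}

#' Low-pass filter a window
#'
#' 4th-order Butterworth low-pass (default 16 Hz cutoff), applied zero-phase
#' (forward-backward) so landmark times are not shifted.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; must satisfy 0 < cutoff < fs/2.
#' @param order Filter order.
#' @return Filtered numeric vector, same length.
#' @export
lowpass_filter <- function(samples, fs, cutoff = 16, order = 4) {
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    abort("`cutoff` must lie strictly between 0 and fs/2 (Nyquist).")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # de-mean and reflect-pad before the forward-backward pass to suppress
  # start-up transients at the window edges
  n <- length(samples)
  mu <- mean(samples)
  x <- samples - mu
  pad <- min(n - 1L, max(3L * 8L * order, 64L))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  yp <- as.numeric(signal::filtfilt(bf, xp))
  yp[(pad + 1L):(pad + n)] + mu
}

#' Min-max normalize a window
#'
#' Rescales to `[0, 1]` as `(y - y_min) / (y_max - y_min)`. The source
#' extrema are retained as attributes `y_min` / `y_max` so feature extraction
#' can de-normalize.
#'
#' @param samples Numeric vector with at least 2 samples and max > min.
#' @return Numeric vector in `[0, 1]` with attributes `y_min`, `y_max`.
#' @export
normalize_minmax <- function(samples) {
  if (length(samples) < 2L) abort("Need at least 2 samples to normalize.")
  y_min <- min(samples); y_max <- max(samples)
  if (y_max <= y_min) {
    abort("Degenerate range: max(samples) == min(samples); window should have been screened out.")
  }
  out <- (samples - y_min) / (y_max - y_min)
  attr(out, "y_min") <- y_min
  attr(out, "y_max") <- y_max
  out
}

#' Screen, filter and normalize a window table
#'
#' Tidy wrapper applying [screen_window()], [lowpass_filter()] and
#' [normalize_minmax()] to every window produced by [cut_windows()].
#' Rejected windows keep their verdict but get no filtered/normalized data.
#'
#' @param windows Tibble from [cut_windows()].
#' @param fs Sampling rate in Hz.
#' @param cutoff,order Passed to [lowpass_filter()].
#' @param min_peaks,max_peaks,percentile Passed to [screen_window()].
#' @return The input tibble with added columns `accepted`, `reason`,
#'   `normalized` (list of numeric vectors in `[0,1]`), `y_min`, `y_max`.
#' @export
preprocess_windows <- function(windows, fs, cutoff = 16, order = 4,
                               min_peaks = 3L, max_peaks = 10L,
                               percentile = 75) {
  if (!nrow(windows)) {
    return(mutate(windows, accepted = logical(), reason = character(),
                  normalized = list(), y_min = double(), y_max = double()))
  }
  verdicts <- map(windows$samples, screen_window,
                  min_peaks = min_peaks, max_peaks = max_peaks,
                  percentile = percentile)
  proc <- map2(windows$samples, verdicts, function(x, v) {
    if (!v$accepted) return(list(normalized = NULL,
                                 y_min = NA_real_, y_max = NA_real_))
    filt <- lowpass_filter(x, fs = fs, cutoff = cutoff, order = order)
    norm <- normalize_minmax(filt)
    list(normalized = as.numeric(norm),
         y_min = attr(norm, "y_min"), y_max = attr(norm, "y_max"))
  })
  windows |>
    mutate(
      accepted   = map_lgl(verdicts, "accepted"),
      reason     = purrr::map_chr(verdicts, "reason"),
      normalized = map(proc, "normalized"),
      y_min      = map_dbl(proc, "y_min"),
      y_max      = map_dbl(proc, "y_max")
    )
}
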