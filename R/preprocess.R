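#' The five classical EEG frequency bands
#'
#' @return named list of `c(low_hz, high_hz)` for Delta (1-3), Theta (4-7),
#'   Alpha (8-12), Beta (13-30) and Gamma (31-49).
#' @export
eeg_bands <- function() {
  list(Delta = c(1, 3), Theta = c(4, 7), Alpha = c(8, 12),
       Beta = c(13, 30), Gamma = c(31, 49))
}

validate_band <- function(band, fs) {
  if (is.character(band)) band <- eeg_bands()[[match.arg(band, names(eeg_bands()))]]
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    stop("invalid band: need 0 < low < high")
  }
  if (band[2] >= fs / 2) stop("invalid band: upper edge at or above Nyquist")
  band
}

# Zero-phase order-4 Butterworth band-pass (forward-backward filtering).
bandpass_series <- function(x, fs, low, high, order = 4L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Crop a recording to a time interval
#'
#' Returns the samples in the half-open sample interval
#' `[start_s * fs, end_s * fs)`, e.g. cropping a 200-s recording to 40-200 s
#' keeps 160 s of data.
#'
#' @param rec an `eeg_recording`.
#' @param start_s,end_s interval bounds in seconds,
#'   `0 <= start_s < end_s <= duration`.
#' @return the cropped `eeg_recording`.
#' @export
crop_recording <- function(rec, start_s, end_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- ncol(rec$data) / rec$fs
  if (start_s < 0 || start_s >= end_s || end_s > dur + 1e-9) {
    stop("crop bounds out of range: need 0 <= start_s < end_s <= duration")
  }
  idx <- seq.int(floor(start_s * rec$fs) + 1L, floor(end_s * rec$fs))
  new_eeg_recording(rec$subject_id, rec$data[, idx, drop = FALSE], rec$fs,
                    rec$label, rec$band_amplitudes)
}

#' Band-pass filter a recording
#'
#' Applies a zero-phase (forward-backward) order-4 Butterworth band-pass to
#' every channel. Forward-backward filtering doubles the effective order, so
#' attenuation one octave outside the band edges comfortably exceeds 20 dB.
#'
#' @param rec an `eeg_recording`.
#' @param band band name (`"Delta"`, ..., `"Gamma"`) or `c(low_hz, high_hz)`.
#' @param order Butterworth order of the one-way filter.
#' @return the filtered `eeg_recording`.
#' @export
bandpass_recording <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- validate_band(band, rec$fs)
  data <- t(apply(rec$data, 1L, bandpass_series, fs = rec$fs,
                  low = band[1], high = band[2], order = order))
  if (nrow(rec$data) == 1L) data <- matrix(data, nrow = 1L)
  new_eeg_recording(rec$subject_id, data, rec$fs, rec$label,
                    rec$band_amplitudes)
}

#' Broadband prefilter with powerline notch
#'
#' Standard cleanup before band decomposition: a zero-phase broadband
#' band-pass (default 1-50 Hz, covering Delta through Gamma) followed by a
#' notch at the powerline frequency (default 50 Hz).
#'
#' @param rec an `eeg_recording`.
#' @param low,high broadband edges in Hz.
#' @param notch_hz powerline frequency; `NULL` disables the notch.
#' @param notch_width half-width of the stop band in Hz.
#' @return the filtered `eeg_recording`.
#' @export
broadband_prefilter <- function(rec, low = 1, high = 50, notch_hz = 50,
                                notch_width = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  validate_band(c(low, high), rec$fs)
  filt <- function(x) {
    y <- bandpass_series(x, rec$fs, low, high)
    if (!is.null(notch_hz)) {
      bf <- signal::butter(2, c(notch_hz - notch_width, notch_hz + notch_width) /
                              (rec$fs / 2), type = "stop")
      y <- signal::filtfilt(bf, y)
    }
    y
  }
  data <- t(apply(rec$data, 1L, filt))
  if (nrow(rec$data) == 1L) data <- matrix(data, nrow = 1L)
  new_eeg_recording(rec$subject_id, data, rec$fs, rec$label,
                    rec$band_amplitudes)
}

#' Collapse channels to a single analysis series
#'
#' The topological pipeline embeds one scalar series per (subject, band,
#' window). By default channels are averaged after filtering; a single
#' channel index can be selected instead.
#'
#' @param rec an `eeg_recording`.
#' @param channel `NULL` for the channel mean, or a single channel index.
#' @return numeric vector of length `n_samples`.
#' @export
collapse_channels <- function(rec, channel = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(channel)) return(colMeans(rec$data))
  stopifnot(channel >= 1, channel <= nrow(rec$data))
  rec$data[channel, ]
}

#' Segment a series into consecutive non-overlapping windows
#'
#' Splits the collapsed recording into `floor(duration / window_s)`
#' consecutive non-overlapping windows in temporal order; a trailing partial
#' window is dropped.
#'
#' @param rec an `eeg_recording` (or a numeric vector with `fs` supplied).
#' @param window_s window length in seconds (default 4).
#' @param channel passed to [collapse_channels()] when `rec` is a recording.
#' @param fs sampling rate, required when `rec` is a bare vector.
#' @return matrix `[n_windows x window_samples]`, one window per row, with
#'   attribute `window_s`.
#' @export
segment_windows <- function(rec, window_s = 4, channel = NULL, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    x <- collapse_channels(rec, channel)
    fs <- rec$fs
  } else {
    stopifnot(is.numeric(rec), !is.null(fs))
    x <- rec
  }
  wlen <- round(window_s * fs)
  n_win <- length(x) %/% wlen
  if (n_win < 1) stop("recording shorter than one window")
  m <- matrix(x[seq_len(n_win * wlen)], nrow = n_win, ncol = wlen,
              byrow = TRUE)
  structure(m, window_s = window_s, fs = fs)
}

#' Band-decompose a recording into per-band window sets
#'
#' For each requested band: band-pass the recording, collapse channels, and
#' segment into consecutive non-overlapping windows.
#'
#' @param rec an `eeg_recording`.
#' @param bands named list of band edges (default [eeg_bands()]).
#' @param window_s window length in seconds.
#' @param channel `NULL` (channel mean) or channel index.
#' @param prefilter apply [broadband_prefilter()] first?
#' @return named list (one element per band) of window matrices as returned
#'   by [segment_windows()].
#' @export
band_windows <- function(rec, bands = eeg_bands(), window_s = 4,
                         channel = NULL, prefilter = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (prefilter) rec <- broadband_prefilter(rec)
  # collapsing before filtering is exact: the zero-phase Butterworth is
  # linear, so filter(mean(channels)) == mean(filter(channels))
  x <- collapse_channels(rec, channel)
  out <- lapply(bands, function(band) {
    band <- validate_band(band, rec$fs)
    y <- bandpass_series(x, rec$fs, band[1], band[2])
    segment_windows(y, window_s = window_s, fs = rec$fs)
  })
  names(out) <- names(bands)
  out
}

# Band-integrated power of a series from its periodogram, used by tests and
# the synthetic-class diagnostics.
band_power <- function(x, fs, band) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  sum(spec[half & freq >= band[1] & freq <= band[2]])
}
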