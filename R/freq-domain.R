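# Frequency-domain analysis: single-sided amplitude spectra and spectral
# peak marking.

#' Single-sided amplitude spectrum
#'
#' Discrete Fourier transform (via [stats::fft()]) of the waveform samples
#' — full sweep or a selected time interval — with rectangular taper and
#' single-sided amplitude scaling: `2|Y_k|/N` for the interior bins,
#' `|Y_k|/N` at DC and (for even N) at Nyquist. Under this scaling a
#' sinusoid of peak amplitude A whose frequency falls exactly on a bin
#' (an integer number of cycles in the window) shows amplitude A — half
#' its peak-to-peak value — at that bin.
#'
#' Interval selection snaps to whole samples: floor for the start, ceiling
#' for the end. Optional zero padding (`zero_pad > 1`) refines the display
#' resolution only; it is off by default.
#'
#' @param wave a [waveform()].
#' @param interval optional `c(start, end)` in ms.
#' @param zero_pad integer padding factor (1 = none).
#' @return an object of class `amplitude_spectrum` with fields
#'   `frequencies` (Hz, ascending from 0), `amplitudes` (uV, >= 0),
#'   `resolution` (Hz), `window` (analyzed interval, ms), `taper`, `n`.
#' @examples
#' s <- amplitude_spectrum(generate_sine(sine_spec(1000, 10), sampling_grid()))
#' s$amplitudes[s$frequencies == 1000]  # 10 uV
#' @export
amplitude_spectrum <- function(wave, interval = NULL, zero_pad = 1) {
  stopifnot(inherits(wave, "waveform"))
  dt_ms <- wf_dt(wave)
  idx <- seq_along(wave$times)
  if (!is.null(interval)) {
    span <- wf_span(wave)
    if (interval[1L] < span[1L] - dt_ms / 2 ||
        interval[2L] > span[2L] + dt_ms / 2 ||
        interval[1L] >= interval[2L]) {
      ep_stop("epwave_range_error",
              "interval outside waveform span or empty")
    }
    i1 <- max(1L, floor((interval[1L] - wave$times[1L]) / dt_ms) + 1L)
    i2 <- min(length(idx),
              ceiling((interval[2L] - wave$times[1L]) / dt_ms) + 1L)
    idx <- i1:i2
  }
  if (length(idx) < 8L) {
    ep_stop("epwave_parameter_error",
            "need at least 8 samples for a spectrum")
  }
  y <- wave$amplitudes[idx]
  zero_pad <- max(1L, as.integer(zero_pad))
  n <- length(y) * zero_pad
  if (zero_pad > 1L) y <- c(y, numeric(n - length(y)))
  fs <- 1000 / dt_ms                      # sampling rate, Hz
  Y <- stats::fft(y)
  half <- floor(n / 2)
  k <- 0:half
  amp <- 2 * Mod(Y[k + 1L]) / n
  amp[1L] <- Mod(Y[1L]) / n               # DC
  if (n %% 2L == 0L) amp[half + 1L] <- Mod(Y[half + 1L]) / n  # Nyquist
  structure(list(frequencies = k * fs / n,
                 amplitudes = amp,
                 resolution = fs / n,
                 window = c(wave$times[idx[1L]], wave$times[idx[length(idx)]]),
                 taper = "rectangular",
                 n = n),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<amplitude spectrum: %d bins, 0..%.6g Hz, resolution %.6g Hz>\n",
              length(x$frequencies), max(x$frequencies), x$resolution))
  invisible(x)
}

#' @export
as.data.frame.amplitude_spectrum <- function(x, ...) {
  data.frame(frequency_Hz = x$frequencies, amplitude_uV = x$amplitudes)
}

spectral_peak <- function(spectrum, bin, source) {
  structure(list(frequency = spectrum$frequencies[bin],
                 amplitude = spectrum$amplitudes[bin],
                 bin_index = bin, source = source),
            class = "spectral_peak")
}

#' @export
print.spectral_peak <- function(x, ...) {
  cat(sprintf("<spectral peak: %.6g Hz, %.6g uV (bin %d, %s)>\n",
              x$frequency, x$amplitude, x$bin_index, x$source))
  invisible(x)
}

#' Automatic spectral peak marking
#'
#' Returns the `n_peaks` local maxima of largest amplitude, in ascending
#' frequency order. The DC bin is excluded from the search; peak
#' frequencies are reported as exact bin frequencies (no interpolation).
#'
#' @param spectrum an [amplitude_spectrum()].
#' @param n_peaks number of peaks requested (>= 1).
#' @return list of `spectral_peak` objects (`source = "auto"`).
#' @export
auto_mark_spectral_peaks <- function(spectrum, n_peaks = 1) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  if (n_peaks < 1L) {
    ep_stop("epwave_parameter_error", "n_peaks must be >= 1")
  }
  a <- spectrum$amplitudes
  ex <- local_extrema(a)
  cand <- ex$peaks[ex$peaks > 1L]         # exclude DC
  if (length(cand) < n_peaks) {
    ep_stop("epwave_detection_error",
            sprintf("only %d spectral maxima found, %d requested",
                    length(cand), n_peaks))
  }
  ord <- order(-a[cand], cand)            # amplitude desc, earlier bin first
  sel <- sort(cand[ord[seq_len(n_peaks)]])
  lapply(sel, function(b) spectral_peak(spectrum, b, "auto"))
}

#' Manual spectral peak marking
#'
#' Snaps a requested frequency to the nearest bin and returns that bin's
#' frequency and amplitude.
#'
#' @param spectrum an [amplitude_spectrum()].
#' @param frequency requested frequency (Hz), within the spectrum range.
#' @return a `spectral_peak` (`source = "manual"`).
#' @export
mark_spectral_peak <- function(spectrum, frequency) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  fr <- spectrum$frequencies
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      frequency < 0 || frequency > fr[length(fr)]) {
    ep_stop("epwave_range_error",
            sprintf("frequency must lie in [0, %.6g] Hz", fr[length(fr)]))
  }
  spectral_peak(spectrum, which.min(abs(fr - frequency)), "manual")
}
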