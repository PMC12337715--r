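#' Sampled waveform
#'
#' The universal substrate of the package: a uniformly sampled voltage trace,
#' times in milliseconds and amplitudes in microvolts, as recorded in an
#' evoked-potential sweep. Times must be strictly increasing and uniformly
#' spaced (relative tolerance 1e-9 by default; readers of 6-digit text
#' exports may relax this via `spacing_tol`).
#'
#' @param times numeric vector of sample times (ms), strictly increasing.
#' @param amplitudes numeric vector of voltages (uV), same length as `times`.
#' @param label free-text description.
#' @param channel channel name.
#' @param spacing_tol relative tolerance for the uniform-spacing invariant.
#' @return an object of class `waveform` with fields `times`, `amplitudes`,
#'   `label`, `channel`.
#' @export
waveform <- function(times, amplitudes, label = "", channel = "",
                     spacing_tol = 1e-9) {
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(times) < 2L) {
    ep_stop("epwave_parameter_error", "a waveform needs at least 2 samples")
  }
  if (length(times) != length(amplitudes)) {
    ep_stop("epwave_parameter_error",
            "times and amplitudes must have equal length")
  }
  if (anyNA(times) || anyNA(amplitudes)) {
    ep_stop("epwave_parameter_error", "waveform contains missing values")
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    ep_stop("epwave_parameter_error", "times must be strictly increasing")
  }
  if (max(abs(dt / dt[1L] - 1)) > spacing_tol) {
    ep_stop("epwave_parameter_error",
            sprintf("sample spacing is not uniform (relative tol %g)",
                    spacing_tol))
  }
  structure(list(times = times, amplitudes = amplitudes,
                 label = as.character(label), channel = as.character(channel)),
            class = "waveform")
}

wf_dt <- function(w) (w$times[length(w$times)] - w$times[1L]) /
  (length(w$times) - 1L)

wf_span <- function(w) range(w$times)

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform%s: %d samples, %.6g..%.6g ms, dt %.6g ms>\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              length(x$times), x$times[1L], x$times[length(x$times)],
              wf_dt(x)))
  invisible(x)
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(time_ms = x$times, amplitude_uV = x$amplitudes)
}

#' @export
length.waveform <- function(x) length(x$times)
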