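#' Sinusoid specification
#'
#' A pure test tone y(t) = A sin(2 pi f t): frequency in hertz, peak
#' amplitude in microvolts, phase fixed at zero. These are the controlled
#' inputs of the desk validation: their landmarks (peak, trough,
#' zero-crossing, areas, slope) have closed forms, so every downstream
#' measurement can be checked against an analytic oracle.
#'
#' @param frequency frequency in Hz (> 0).
#' @param amplitude peak amplitude in uV (> 0).
#' @return an object of class `sine_spec`.
#' @seealso [generate_sine()], [analytic_landmarks()]
#' @export
sine_spec <- function(frequency, amplitude = 10) {
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0) {
    ep_stop("epwave_parameter_error", "frequency must be a positive number")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude <= 0) {
    ep_stop("epwave_parameter_error", "amplitude must be a positive number")
  }
  structure(list(frequency = frequency, amplitude = amplitude),
            class = "sine_spec")
}

#' Uniform sampling grid
#'
#' Defines the time axis of generated waveforms. The default — 3072 samples
#' across a 10 ms sweep starting at 0 — mirrors a short-latency
#' evoked-potential acquisition window. Two endpoint conventions are
#' offered:
#' \describe{
#'   \item{half_open}{t_k = start + k * duration / n (endpoint excluded).
#'     Sample spacing 10/3072 ms, an integer number of cycles for 0.5/1/2
#'     kHz and exact 100 Hz spectral bins. Default.}
#'   \item{inclusive}{t_k = start + k * duration / (n - 1) (endpoint
#'     included), spacing 10/3071 ms.}
#' }
#'
#' @param start_time sweep start (ms).
#' @param duration sweep length (ms, > 0).
#' @param n_samples number of samples (>= 2).
#' @param endpoint_mode `"half_open"` (default) or `"inclusive"`.
#' @return an object of class `sampling_grid`.
#' @export
sampling_grid <- function(start_time = 0, duration = 10, n_samples = 3072,
                          endpoint_mode = c("half_open", "inclusive")) {
  endpoint_mode <- match.arg(endpoint_mode)
  if (!is.numeric(duration) || duration <= 0) {
    ep_stop("epwave_parameter_error", "duration must be positive")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) {
    ep_stop("epwave_parameter_error", "n_samples must be an integer >= 2")
  }
  structure(list(start_time = start_time, duration = duration,
                 n_samples = n_samples, endpoint_mode = endpoint_mode),
            class = "sampling_grid")
}

#' @rdname sampling_grid
#' @param grid a `sampling_grid`.
#' @return `grid_times()`: numeric vector of sample times (ms).
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "sampling_grid"))
  k <- seq_len(grid$n_samples) - 1L
  step <- switch(grid$endpoint_mode,
                 half_open = grid$duration / grid$n_samples,
                 inclusive = grid$duration / (grid$n_samples - 1L))
  grid$start_time + k * step
}

#' Generate a sampled sinusoid
#'
#' Evaluates y(t) = A sin(2 pi f t) on the grid. Time is carried in ms and
#' frequency in Hz; the unit conversion is internal.
#'
#' @param spec a [sine_spec()].
#' @param grid a [sampling_grid()].
#' @return a [waveform()] whose amplitudes are the sinusoid sampled at the
#'   grid times.
#' @examples
#' w <- generate_sine(sine_spec(500, 10), sampling_grid())
#' @export
generate_sine <- function(spec, grid = sampling_grid()) {
  stopifnot(inherits(spec, "sine_spec"))
  t_ms <- grid_times(grid)
  y <- spec$amplitude * sin(2 * pi * spec$frequency * t_ms / 1000)
  waveform(t_ms, y,
           label = sprintf("sine %g Hz, %g uV", spec$frequency,
                           spec$amplitude),
           channel = sprintf("f%g", spec$frequency))
}

#' Generate a sum of sinusoids
#'
#' Pointwise sum of the individual tones on a shared grid (the composite
#' wave used to exercise spectral peak separation).
#'
#' @param specs non-empty list of [sine_spec()] objects.
#' @param grid a [sampling_grid()].
#' @return a [waveform()].
#' @export
generate_composite <- function(specs, grid = sampling_grid()) {
  if (!is.list(specs) || length(specs) == 0L) {
    ep_stop("epwave_parameter_error",
            "specs must be a non-empty list of sine_spec objects")
  }
  waves <- lapply(specs, generate_sine, grid = grid)
  y <- Reduce(`+`, lapply(waves, `[[`, "amplitudes"))
  waveform(grid_times(grid), y,
           label = sprintf("composite of %d sinusoids", length(specs)),
           channel = "sum")
}

#' Analytic landmarks of a sinusoid
#'
#' Closed-form ground truth for the first positive peak / negative trough
#' pair of y(t) = A sin(2 pi f t):
#' \itemize{
#'   \item t_peak = 1/(4f), t_zero = 1/(2f), t_trough = 3/(4f) (converted
#'     to ms);
#'   \item absolute area between peak and trough, integral of |y|:
#'     A/(pi f) (uV.s) = 1000 A / (pi f) uV.ms;
#'   \item two-triangle approximation: (t_zero - t_peak) A/2 +
#'     (t_trough - t_zero) A/2 = 1000 A / (4 f) uV.ms;
#'   \item slope: peak-to-trough amplitude over the half period,
#'     2A / (t_trough - t_peak) = 4 A f / 1000 uV/ms.
#' }
#' The two-triangle area equals the absolute area times pi/4 for every
#' sinusoid — a fixed analytic ratio used by the test suite.
#'
#' @param spec a [sine_spec()].
#' @return an object of class `landmark_set` with fields `t_peak`,
#'   `t_trough`, `t_zero` (ms), `peak_amplitude`, `trough_amplitude`,
#'   `peak_to_trough_amplitude` (uV), `abs_area`, `two_triangle_area`
#'   (uV.ms) and `slope` (uV/ms).
#' @examples
#' analytic_landmarks(sine_spec(500, 10))  # peak 0.5 ms, area 6.366 uV.ms
#' @export
analytic_landmarks <- function(spec) {
  stopifnot(inherits(spec, "sine_spec"))
  f <- spec$frequency
  A <- spec$amplitude
  structure(list(
    spec = spec,
    t_peak = 1000 / (4 * f),
    t_trough = 3000 / (4 * f),
    t_zero = 1000 / (2 * f),
    peak_amplitude = A,
    trough_amplitude = -A,
    peak_to_trough_amplitude = 2 * A,
    abs_area = 1000 * A / (pi * f),
    two_triangle_area = 1000 * A / (4 * f),
    slope = 4 * A * f / 1000
  ), class = "landmark_set")
}

#' @rdname analytic_landmarks
#' @param landmarks a `landmark_set`.
#' @param digits display precision (decimal places).
#' @return `landmark_display()`: named numeric vector of the landmark values
#'   truncated to `digits` decimals (the convention for derived/analytic
#'   quantities, see [display_trunc()]).
#' @export
landmark_display <- function(landmarks, digits = 2) {
  stopifnot(inherits(landmarks, "landmark_set"))
  v <- c(t_peak = landmarks$t_peak,
         t_trough = landmarks$t_trough,
         t_zero = landmarks$t_zero,
         peak_amplitude = landmarks$peak_amplitude,
         trough_amplitude = landmarks$trough_amplitude,
         peak_to_trough_amplitude = landmarks$peak_to_trough_amplitude,
         abs_area = landmarks$abs_area,
         two_triangle_area = landmarks$two_triangle_area,
         slope = landmarks$slope)
  display_trunc(v, digits)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmarks of %g Hz, %g uV sinusoid>\n",
              x$spec$frequency, x$spec$amplitude))
  print(landmark_display(x, digits = 4))
  invisible(x)
}

#' Standard desk-validation fixtures
#'
#' The canonical test set: 0.5, 1 and 2 kHz tones at 10 uV on the default
#' 3072-sample / 10 ms grid, plus their sum. `phase1_specs()` returns the
#' tone specifications; `phase1_waveforms()` the generated table with
#' channels `f500`, `f1000`, `f2000` and `sum`.
#'
#' @param frequencies tone frequencies (Hz).
#' @param amplitude shared peak amplitude (uV).
#' @return `phase1_specs()`: list of [sine_spec()].
#' @export
phase1_specs <- function(frequencies = c(500, 1000, 2000), amplitude = 10) {
  lapply(frequencies, sine_spec, amplitude = amplitude)
}

#' @rdname phase1_specs
#' @param grid a [sampling_grid()].
#' @param specs list of [sine_spec()].
#' @param include_sum add the composite channel.
#' @return `phase1_waveforms()`: a [waveform_table()].
#' @export
phase1_waveforms <- function(grid = sampling_grid(), specs = phase1_specs(),
                             include_sum = TRUE) {
  waves <- lapply(specs, generate_sine, grid = grid)
  channels <- lapply(waves, `[[`, "amplitudes")
  names(channels) <- vapply(waves, `[[`, "", "channel")
  if (include_sum && length(specs) > 1L) {
    channels$sum <- Reduce(`+`, channels)
  }
  waveform_table(grid_times(grid), channels)
}
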