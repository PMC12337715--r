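# Time-domain marking and morphometry: peaks, troughs, zero-crossings,
# latencies, amplitudes, areas (integral and two-triangle), slope.

#' Waveform marker
#'
#' A labeled landmark on a waveform: a peak, a trough, or a zero-crossing,
#' with its latency (ms) and amplitude (uV). Automatic markers always sit
#' on a sample point; manual markers may be placed anywhere in the sweep.
#'
#' @param kind `"peak"`, `"trough"` or `"zero_cross"`.
#' @param time latency in ms.
#' @param amplitude voltage in uV.
#' @param source `"manual"` or `"auto"`.
#' @param label free text (e.g. "P1", "wave V").
#' @return an object of class `marker`.
#' @export
marker <- function(kind, time, amplitude, source = "manual", label = "") {
  if (!kind %in% marker_kinds) {
    ep_stop("epwave_parameter_error",
            sprintf("kind must be one of: %s",
                    paste(marker_kinds, collapse = ", ")))
  }
  if (!source %in% c("manual", "auto")) {
    ep_stop("epwave_parameter_error", "source must be 'manual' or 'auto'")
  }
  structure(list(kind = kind, time = as.numeric(time),
                 amplitude = as.numeric(amplitude), source = source,
                 label = as.character(label)),
            class = "marker")
}

#' @export
print.marker <- function(x, ...) {
  cat(sprintf("<%s marker%s: %.4f ms, %.4f uV (%s)>\n", x$kind,
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$time, x$amplitude, x$source))
  invisible(x)
}

#' Peak--trough pair
#'
#' The unit of the derived measures: a positive peak and its following
#' trough (e.g. P1/N1), optionally with the zero-crossing between them.
#'
#' @param peak a `"peak"` [marker()].
#' @param trough a `"trough"` [marker()], later than `peak`.
#' @param zero optional `"zero_cross"` [marker()] strictly between them.
#' @return an object of class `marked_pair`.
#' @export
marked_pair <- function(peak, trough, zero = NULL) {
  stopifnot(inherits(peak, "marker"), inherits(trough, "marker"))
  if (peak$kind != "peak" || trough$kind != "trough") {
    ep_stop("epwave_parameter_error", "need a peak marker and a trough marker")
  }
  if (!(peak$time < trough$time)) {
    ep_stop("epwave_parameter_error", "peak must precede trough")
  }
  if (!is.null(zero)) {
    stopifnot(inherits(zero, "marker"))
    if (zero$kind != "zero_cross" ||
        !(peak$time < zero$time && zero$time < trough$time)) {
      ep_stop("epwave_parameter_error",
              "zero marker must be a zero_cross strictly between peak and trough")
    }
  }
  structure(list(peak = peak, trough = trough, zero = zero),
            class = "marked_pair")
}

# --- local extrema -------------------------------------------------------

# Interior local maxima/minima by first-difference sign change; a plateau
# contributes its first sample. Returns indices into y.
local_extrema <- function(y) {
  n <- length(y)
  if (n < 3L) return(list(peaks = integer(0), troughs = integer(0)))
  s <- sign(diff(y))
  s_na <- s
  s_na[s_na == 0] <- NA_real_
  left <- fill_prev(s_na)   # last nonzero slope up to position i
  right <- fill_next(s_na)  # first nonzero slope at/after position i
  i <- 2:(n - 1L)
  lv <- left[i - 1L]
  rv <- right[i]
  first_of_plateau <- s[i - 1L] != 0
  peaks <- i[!is.na(lv) & !is.na(rv) & lv > 0 & rv < 0 & first_of_plateau]
  troughs <- i[!is.na(lv) & !is.na(rv) & lv < 0 & rv > 0 & first_of_plateau]
  list(peaks = peaks, troughs = troughs)
}

# Prominence of each extremum: vertical distance to the higher (for peaks)
# or lower (for troughs) of the two flanking opposite-sign extrema; with a
# single flank, that flank alone. amp/opp are amplitude vectors at the
# extremum indices, already sorted by time.
prominence <- function(idx, opp_idx, y, is_peak) {
  vapply(seq_along(idx), function(j) {
    i <- idx[j]
    before <- opp_idx[opp_idx < i]
    after <- opp_idx[opp_idx > i]
    flank <- c(if (length(before)) y[max(before)],
               if (length(after)) y[min(after)])
    if (length(flank) == 0L) return(NA_real_)
    if (is_peak) y[i] - max(flank) else min(flank) - y[i]
  }, 1)
}

#' Automatic peak--trough detection
#'
#' Finds interior local extrema by first-difference sign change (plateaus
#' count at their first sample), ranks the peaks by prominence — the
#' vertical distance to the higher of the two flanking troughs, or to the
#' single flank at the window edges — and returns the `n_pairs` most
#' prominent peaks, each paired with the most prominent trough between it
#' and the next selected peak (or the window end). Prominence comparisons
#' use a relative tie tolerance so that sub-sample jitter between
#' near-identical crests (inevitable when a periodic wave is sampled on a
#' finite grid) does not override the earlier-time tie-break: among
#' candidates within `tie_tol` of the best, the earliest wins.
#'
#' @param wave a [waveform()].
#' @param n_pairs number of pairs requested (>= 1).
#' @param search_window optional `c(start, end)` in ms restricting the scan.
#' @param tie_tol relative prominence tolerance treated as a tie
#'   (default 1e-3).
#' @return list of [marked_pair()] in temporal order; markers have
#'   `source = "auto"` and lie exactly on samples.
#' @examples
#' w <- generate_sine(sine_spec(500, 10), sampling_grid())
#' auto_mark_extrema(w, n_pairs = 1)[[1]]
#' @export
auto_mark_extrema <- function(wave, n_pairs = 1, search_window = NULL,
                              tie_tol = 1e-3) {
  stopifnot(inherits(wave, "waveform"))
  if (length(wave) < 3L) {
    ep_stop("epwave_parameter_error", "waveform has fewer than 3 samples")
  }
  if (n_pairs < 1L) {
    ep_stop("epwave_parameter_error", "n_pairs must be >= 1")
  }
  sel <- seq_along(wave$times)
  if (!is.null(search_window)) {
    sel <- which(wave$times >= search_window[1L] &
                   wave$times <= search_window[2L])
    if (length(sel) < 3L) {
      ep_stop("epwave_range_error", "search window contains < 3 samples")
    }
  }
  tt <- wave$times[sel]
  yy <- wave$amplitudes[sel]
  ex <- local_extrema(yy)
  if (length(ex$peaks) == 0L || length(ex$troughs) == 0L) {
    ep_stop("epwave_detection_error",
            "no qualifying extrema in the search window")
  }
  peak_prom <- prominence(ex$peaks, ex$troughs, yy, is_peak = TRUE)
  trough_prom <- prominence(ex$troughs, ex$peaks, yy, is_peak = FALSE)

  # peaks eligible only if a trough follows them
  eligible <- ex$peaks[vapply(ex$peaks, function(i) any(ex$troughs > i),
                              TRUE)]
  elig_prom <- peak_prom[match(eligible, ex$peaks)]
  if (length(eligible) < n_pairs) {
    ep_stop("epwave_detection_error",
            sprintf("only %d peak-trough pair(s) available, %d requested",
                    length(eligible), n_pairs))
  }
  pick_best <- function(cand_idx, cand_prom) {
    best <- max(cand_prom)
    tol <- abs(best) * tie_tol
    cand_idx[which(cand_prom >= best - tol)[1L]]  # candidates are in time order
  }
  chosen <- integer(0)
  remaining <- eligible
  rem_prom <- elig_prom
  for (k in seq_len(n_pairs)) {
    i <- pick_best(remaining, rem_prom)
    chosen <- c(chosen, i)
    keep <- remaining != i
    remaining <- remaining[keep]
    rem_prom <- rem_prom[keep]
  }
  chosen <- sort(chosen)
  bounds <- c(chosen[-1L], length(yy) + 1L)
  pairs <- vector("list", length(chosen))
  for (k in seq_along(chosen)) {
    cand <- which(ex$troughs > chosen[k] & ex$troughs < bounds[k])
    if (length(cand) == 0L) {
      ep_stop("epwave_detection_error",
              "no trough between selected peaks")
    }
    ti <- pick_best(ex$troughs[cand], trough_prom[cand])
    pk <- marker("peak", tt[chosen[k]], yy[chosen[k]], source = "auto")
    tr <- marker("trough", tt[ti], yy[ti], source = "auto")
    pairs[[k]] <- marked_pair(pk, tr)
  }
  pairs
}

#' Place a marker manually
#'
#' @param wave a [waveform()].
#' @param kind marker kind.
#' @param time requested latency (ms); must lie within the sweep.
#' @param snap `"nearest_sample"` adopts the nearest sample's time and
#'   amplitude; `"exact"` keeps the requested time and interpolates the
#'   amplitude linearly.
#' @return a [marker()] with `source = "manual"`.
#' @export
place_marker <- function(wave, kind, time,
                         snap = c("nearest_sample", "exact")) {
  stopifnot(inherits(wave, "waveform"))
  snap <- match.arg(snap)
  span <- wf_span(wave)
  if (time < span[1L] || time > span[2L]) {
    ep_stop("epwave_range_error",
            sprintf("time %.6g ms outside waveform span [%.6g, %.6g]",
                    time, span[1L], span[2L]))
  }
  if (snap == "nearest_sample") {
    i <- which.min(abs(wave$times - time))
    marker(kind, wave$times[i], wave$amplitudes[i], source = "manual")
  } else {
    a <- stats::approx(wave$times, wave$amplitudes, xout = time)$y
    marker(kind, time, a, source = "manual")
  }
}

# Samples of `wave` covering [t1, t2], with linearly interpolated values at
# the two endpoints when they fall between samples.
interval_samples <- function(wave, t1, t2) {
  inside <- which(wave$times > t1 & wave$times < t2)
  tt <- c(t1, wave$times[inside], t2)
  yy <- stats::approx(wave$times, wave$amplitudes, xout = tt)$y
  list(t = tt, y = yy)
}

#' Zero-crossing between a peak and its trough
#'
#' Locates the first time at which the linearly interpolated signal crosses
#' the baseline between the pair's peak and trough.
#'
#' @param wave a [waveform()].
#' @param pair a [marked_pair()].
#' @param baseline reference voltage (uV); 0 for the standard convention.
#' @return a `"zero_cross"` [marker()] with amplitude equal to `baseline`.
#' @export
find_zero_cross <- function(wave, pair, baseline = 0) {
  stopifnot(inherits(wave, "waveform"), inherits(pair, "marked_pair"))
  seg <- interval_samples(wave, pair$peak$time, pair$trough$time)
  y0 <- seg$y - baseline
  a <- y0[-length(y0)]
  b <- y0[-1L]
  j <- which(a * b < 0 | (a != 0 & b == 0))
  if (length(j) == 0L) {
    ep_stop("epwave_detection_error",
            "no zero crossing between peak and trough")
  }
  j <- j[1L]
  tc <- seg$t[j] + (seg$t[j + 1L] - seg$t[j]) * a[j] / (a[j] - b[j])
  marker("zero_cross", tc, baseline, source = pair$peak$source)
}

area_result <- function(method, value, interval) {
  structure(list(method = method, value = value, interval = interval),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("<area (%s): %.6g uV.ms over [%.4f, %.4f] ms>\n",
              x$method, x$value, x$interval[1L], x$interval[2L]))
  invisible(x)
}

#' Absolute area between peak and trough
#'
#' Composite-trapezoid integral of |y(t) - baseline| from the peak to the
#' trough marker, with the interval subdivided at interpolated baseline
#' crossings so the cusp of the absolute value is honored. For a sampled
#' sinusoid this converges to the closed form A/(pi f) as the grid is
#' refined.
#'
#' @param wave a [waveform()].
#' @param pair a [marked_pair()].
#' @param baseline reference voltage (uV).
#' @return an `area_result` (`method = "integral"`, value in uV.ms, >= 0).
#' @export
absolute_area <- function(wave, pair, baseline = 0) {
  stopifnot(inherits(wave, "waveform"), inherits(pair, "marked_pair"))
  t1 <- pair$peak$time
  t2 <- pair$trough$time
  if (t2 - t1 < wf_dt(wave)) {
    ep_stop("epwave_degenerate_error",
            "peak-trough interval shorter than one sample")
  }
  seg <- interval_samples(wave, t1, t2)
  y0 <- seg$y - baseline
  a <- y0[-length(y0)]
  b <- y0[-1L]
  h <- diff(seg$t)
  cross <- a * b < 0
  frac <- ifelse(cross, a / (a - b), 0)
  area <- ifelse(cross,
                 abs(a) * h * frac / 2 + abs(b) * h * (1 - frac) / 2,
                 (abs(a) + abs(b)) / 2 * h)
  area_result("integral", sum(area), c(t1, t2))
}

#' Two-triangle area approximation
#'
#' The classical clinical shortcut: the peak-to-trough area approximated by
#' two right triangles hinged at the zero-crossing,
#' (t_zero - t_peak) |A_peak| / 2 + (t_trough - t_zero) |A_trough| / 2.
#' Systematically underestimates the integral for sinusoid-like morphology
#' (ratio pi/4 for a pure sinusoid with analytic landmarks).
#'
#' @param pair a [marked_pair()] whose `zero` marker is present.
#' @param baseline reference voltage (uV).
#' @return an `area_result` (`method = "two_triangles"`, value in uV.ms).
#' @export
two_triangle_area <- function(pair, baseline = 0) {
  stopifnot(inherits(pair, "marked_pair"))
  if (is.null(pair$zero)) {
    ep_stop("epwave_parameter_error",
            "two-triangle area requires the zero-cross marker")
  }
  v <- (pair$zero$time - pair$peak$time) *
    abs(pair$peak$amplitude - baseline) / 2 +
    (pair$trough$time - pair$zero$time) *
    abs(pair$trough$amplitude - baseline) / 2
  area_result("two_triangles", v, c(pair$peak$time, pair$trough$time))
}

#' Peak-to-trough slope
#'
#' Peak-to-trough amplitude over the peak-to-trough interval:
#' (A_peak - A_trough) / (t_trough - t_peak), in uV/ms.
#'
#' @param pair a [marked_pair()].
#' @return numeric slope (uV/ms).
#' @export
slope <- function(pair) {
  stopifnot(inherits(pair, "marked_pair"))
  dt <- pair$trough$time - pair$peak$time
  if (dt <= 0) {
    ep_stop("epwave_degenerate_error", "zero peak-trough time interval")
  }
  (pair$peak$amplitude - pair$trough$amplitude) / dt
}

#' Signed interval between two markers
#'
#' @param a,b [marker()] objects.
#' @return `b$time - a$time` in ms (antisymmetric).
#' @export
interpeak_interval <- function(a, b) {
  stopifnot(inherits(a, "marker"), inherits(b, "marker"))
  b$time - a$time
}

#' All time-domain measures of a marked pair
#'
#' Convenience wrapper computing the full measure set for one pair:
#' latencies, amplitudes, peak-to-trough amplitude, interpeak interval,
#' zero-crossing, both area methods and the slope. Full-precision values
#' are kept in `$values`; `$display` carries the reporting convention
#' (latencies/amplitudes rounded half-up to 2 decimals, derived measures
#' truncated — see [display_round()]).
#'
#' @param wave a [waveform()].
#' @param pair a [marked_pair()]; the zero-crossing is located if absent.
#' @param baseline reference voltage (uV).
#' @return an object of class `measure_set`.
#' @export
measure_pair <- function(wave, pair, baseline = 0) {
  if (is.null(pair$zero)) {
    z <- find_zero_cross(wave, pair, baseline)
    pair <- marked_pair(pair$peak, pair$trough, z)
  }
  ai <- absolute_area(wave, pair, baseline)
  a2 <- two_triangle_area(pair, baseline)
  values <- c(
    peak_latency = pair$peak$time,
    trough_latency = pair$trough$time,
    zero_cross = pair$zero$time,
    peak_amplitude = pair$peak$amplitude,
    trough_amplitude = pair$trough$amplitude,
    peak_to_trough_amplitude = pair$peak$amplitude - pair$trough$amplitude,
    interpeak_interval = interpeak_interval(pair$peak, pair$trough),
    abs_area = ai$value,
    two_triangle_area = a2$value,
    slope = slope(pair)
  )
  marked <- c("peak_latency", "trough_latency", "zero_cross",
              "peak_amplitude", "trough_amplitude",
              "peak_to_trough_amplitude", "interpeak_interval")
  display <- values
  display[marked] <- display_round(values[marked])
  derived <- setdiff(names(values), marked)
  display[derived] <- display_trunc(values[derived])
  structure(list(pair = pair, values = values, display = display,
                 areas = list(integral = ai, two_triangles = a2)),
            class = "measure_set")
}

#' @export
print.measure_set <- function(x, ...) {
  df <- data.frame(measure = names(x$values),
                   value = unname(x$values),
                   display = unname(x$display))
  print(df, row.names = FALSE)
  invisible(x)
}
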