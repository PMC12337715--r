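# Marking and time-domain morphometry.

fixture <- function(f, n = 3072) {
  generate_sine(sine_spec(f, 10), sampling_grid(0, 10, n))
}

test_that("automatic marking finds the first crest/trough of each tone", {
  # grid-snapped marks display at the conventional 2-decimal values
  cases <- list(
    list(f = 500, peak = 0.50, trough = 1.50),
    list(f = 1000, peak = 0.25, trough = 0.75),
    list(f = 2000, peak = 0.12, trough = 0.37))
  for (cs in cases) {
    pair <- auto_mark_extrema(fixture(cs$f))[[1]]
    expect_equal(display_round(pair$peak$time), cs$peak)
    expect_equal(display_round(pair$trough$time), cs$trough)
    expect_equal(display_round(pair$peak$amplitude), 10)
    expect_equal(display_round(pair$trough$amplitude), -10)
    expect_identical(pair$peak$source, "auto")
    # auto markers lie exactly on samples
    w <- fixture(cs$f)
    expect_true(pair$peak$time %in% w$times)
    expect_true(pair$trough$time %in% w$times)
  }
})

test_that("detector matches the naive scan oracle on random waveforms", {
  set.seed(42)
  for (rep in 1:25) {
    w <- random_smooth_wave(n = sample(500:4000, 1), k = sample(2:4, 1))
    got <- auto_mark_extrema(w, n_pairs = 1)[[1]]
    want <- scan_best_pair(w$amplitudes)
    expect_equal(got$peak$time, w$times[want$peak])
    expect_equal(got$trough$time, w$times[want$trough])
  }
})

test_that("detector equals brute-force argmax/argmin inside a window", {
  w <- fixture(500)
  win <- c(2.0, 4.0)   # one full cycle: unique crest and trough
  pair <- auto_mark_extrema(w, search_window = win)[[1]]
  sel <- which(w$times >= win[1] & w$times <= win[2])
  expect_equal(pair$peak$time, w$times[sel][which.max(w$amplitudes[sel])])
  expect_equal(pair$trough$time, w$times[sel][which.min(w$amplitudes[sel])])
})

test_that("degenerate inputs raise detection errors", {
  flat <- waveform(0:99, rep(1, 100))
  expect_error(auto_mark_extrema(flat), class = "epwave_detection_error")
  w <- fixture(500)
  expect_error(auto_mark_extrema(w, n_pairs = 99),
               class = "epwave_detection_error")
})

test_that("plateaus are marked at their first sample", {
  y <- c(0, 1, 2, 2, 2, 1, 0, -1, -2, -2, -1, 0)
  w <- waveform(seq_along(y) - 1, y)
  pair <- auto_mark_extrema(w)[[1]]
  expect_equal(pair$peak$time, 2)    # first sample of the 2,2,2 plateau
  expect_equal(pair$trough$time, 8)
})

test_that("place_marker snaps or interpolates as requested", {
  w <- fixture(500)
  m <- place_marker(w, "peak", 0.5, snap = "nearest_sample")
  expect_true(m$time %in% w$times)
  expect_equal(display_round(m$amplitude), 10)
  # exactly on a sample the two modes agree
  t0 <- w$times[100]
  a <- place_marker(w, "peak", t0, "nearest_sample")
  b <- place_marker(w, "peak", t0, "exact")
  expect_equal(a$time, b$time)
  expect_equal(a$amplitude, b$amplitude)
  # interpolation between samples
  tm <- (w$times[10] + w$times[11]) / 2
  mi <- place_marker(w, "peak", tm, "exact")
  expect_equal(mi$amplitude,
               (w$amplitudes[10] + w$amplitudes[11]) / 2, tolerance = 1e-9)
  expect_error(place_marker(w, "peak", max(w$times) + 0.01, "exact"),
               class = "epwave_range_error")
})

test_that("zero crossings interpolate to the analytic times", {
  for (cs in list(list(f = 500, zc = 1.00), list(f = 1000, zc = 0.50),
                  list(f = 2000, zc = 0.25))) {
    w <- fixture(cs$f)
    pair <- auto_mark_extrema(w)[[1]]
    z <- find_zero_cross(w, pair)
    expect_equal(display_round(z$time), cs$zc)
    expect_equal(z$amplitude, 0)
    expect_identical(z$kind, "zero_cross")
  }
  # strictly positive interval: no crossing to find
  w <- fixture(500)
  up <- waveform(w$times, w$amplitudes + 20)
  pair <- auto_mark_extrema(up)[[1]]
  expect_error(find_zero_cross(up, pair), class = "epwave_detection_error")
})

test_that("absolute area is positive, homogeneous and converges to A/(pi f)", {
  w <- fixture(500)
  pair <- auto_mark_extrema(w)[[1]]
  a1 <- absolute_area(w, pair)
  expect_identical(a1$method, "integral")
  expect_gt(a1$value, 0)
  # homogeneity: scaling the waveform scales the area
  w2 <- waveform(w$times, 2 * w$amplitudes)
  pair2 <- marked_pair(
    marker("peak", pair$peak$time, 2 * pair$peak$amplitude),
    marker("trough", pair$trough$time, 2 * pair$trough$amplitude))
  expect_equal(absolute_area(w2, pair2)$value, 2 * a1$value)
  # refinement limit: 1e5-sample grid against the closed form
  wf <- fixture(500, n = 1e5)
  pf <- marked_pair(place_marker(wf, "peak", 0.5, "exact"),
                    place_marker(wf, "trough", 1.5, "exact"))
  closed <- analytic_landmarks(sine_spec(500, 10))$abs_area
  expect_equal(absolute_area(wf, pf)$value, closed, tolerance = 1e-6)
  # interval shorter than one sample
  degen <- marked_pair(place_marker(w, "peak", 3.0, "exact"),
                       place_marker(w, "trough", 3.0005, "exact"))
  expect_error(absolute_area(w, degen), class = "epwave_degenerate_error")
})

test_that("two-triangle area reproduces the hand-worked examples", {
  p5 <- marked_pair(marker("peak", 0.5, 10), marker("trough", 1.5, -10),
                    marker("zero_cross", 1.0, 0))
  expect_equal(two_triangle_area(p5)$value, 5)
  p2k <- marked_pair(marker("peak", 0.125, 10), marker("trough", 0.375, -10),
                     marker("zero_cross", 0.25, 0))
  expect_equal(two_triangle_area(p2k)$value, 1.25)
  flat <- marked_pair(marker("peak", 0.5, 0), marker("trough", 1.5, 0),
                      marker("zero_cross", 1.0, 0))
  expect_equal(two_triangle_area(flat)$value, 0)
  nozero <- marked_pair(marker("peak", 0.5, 10), marker("trough", 1.5, -10))
  expect_error(two_triangle_area(nozero), class = "epwave_parameter_error")
})

test_that("slope follows (A_peak - A_trough) / dt with truncation display", {
  p <- marked_pair(marker("peak", 0.25, 10), marker("trough", 0.75, -10))
  expect_equal(slope(p), 40)
  # the manual 1 kHz reading: trough placed at 0.74 ms
  pm <- marked_pair(marker("peak", 0.25, 10), marker("trough", 0.74, -10))
  expect_equal(slope(pm), 20 / 0.49)
  expect_equal(display_trunc(slope(pm)), 40.81)
  flat <- marked_pair(marker("peak", 0.25, 5), marker("trough", 0.75, 5))
  expect_equal(slope(flat), 0)
  expect_error(marked_pair(marker("peak", 0.5, 10), marker("trough", 0.5, -10)),
               class = "epwave_parameter_error")
})

test_that("interpeak intervals are signed and antisymmetric", {
  a <- marker("peak", 0.5, 10)
  b <- marker("trough", 1.5, -10)
  expect_equal(interpeak_interval(a, b), 1)
  expect_equal(interpeak_interval(a, a), 0)
  expect_equal(interpeak_interval(b, a), -interpeak_interval(a, b))
})

test_that("two area constructions differ systematically on sinusoids", {
  for (spec in fixture_specs()) {
    w <- generate_sine(spec, sampling_grid())
    ms <- measure_pair(w, auto_mark_extrema(w)[[1]])
    expect_lt(ms$values[["two_triangle_area"]], ms$values[["abs_area"]])
    # analytic ratio pi/4 holds in the closed forms
    lm <- analytic_landmarks(spec)
    expect_equal(lm$two_triangle_area / lm$abs_area, pi / 4)
  }
})

test_that("measure_pair keeps full precision and display values apart", {
  w <- fixture(1000)
  ms <- measure_pair(w, auto_mark_extrema(w)[[1]])
  expect_equal(ms$display[["trough_latency"]], 0.75)  # round half-up
  expect_lt(ms$values[["trough_latency"]], 0.75)      # raw sample time
  expect_equal(ms$values[["peak_to_trough_amplitude"]],
               ms$values[["peak_amplitude"]] - ms$values[["trough_amplitude"]])
})
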