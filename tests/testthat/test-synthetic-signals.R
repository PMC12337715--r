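# Sinusoid generation and the analytic landmark oracle.

test_that("generate_sine evaluates A sin(2 pi f t) at the grid times", {
  # 2000-point grid puts 0.5 and 1.5 ms exactly on samples
  grid <- sampling_grid(0, 10, 2000)
  w <- generate_sine(sine_spec(500, 10), grid)
  expect_equal(length(w), 2000L)
  expect_equal(w$amplitudes[w$times == 0], 0)
  expect_equal(w$amplitudes[w$times == 0.5], 10)    # quarter period crest
  expect_equal(w$amplitudes[w$times == 1.5], -10)   # three-quarter trough

  expect_error(sine_spec(-500, 10), class = "epwave_parameter_error")
  expect_error(sine_spec(500, 0), class = "epwave_parameter_error")
  expect_error(sampling_grid(duration = -1), class = "epwave_parameter_error")
  expect_error(sampling_grid(n_samples = 1), class = "epwave_parameter_error")
})

test_that("grid endpoint conventions differ only in the step", {
  half <- grid_times(sampling_grid(0, 10, 3072, "half_open"))
  incl <- grid_times(sampling_grid(0, 10, 3072, "inclusive"))
  expect_equal(diff(half)[1], 10 / 3072)
  expect_equal(diff(incl)[1], 10 / 3071)
  expect_lt(max(half), 10)
  expect_equal(max(incl), 10)
  expect_equal(half[1], 0)
})

test_that("generate_composite is the pointwise sum and is linear", {
  grid <- sampling_grid(n_samples = 512)
  specs <- fixture_specs()
  waves <- lapply(specs, generate_sine, grid = grid)
  comp <- generate_composite(specs, grid)
  expect_equal(comp$amplitudes,
               waves[[1]]$amplitudes + waves[[2]]$amplitudes +
                 waves[[3]]$amplitudes)
  # singleton sum is the wave itself; duplicated spec doubles it
  expect_equal(generate_composite(specs[1], grid)$amplitudes,
               waves[[1]]$amplitudes)
  expect_equal(generate_composite(c(specs[1], specs[1]), grid)$amplitudes,
               2 * waves[[1]]$amplitudes)
  # linearity across a partition of the spec list
  expect_equal(generate_composite(specs, grid)$amplitudes,
               generate_composite(specs[1:2], grid)$amplitudes +
                 generate_composite(specs[3], grid)$amplitudes)
  expect_error(generate_composite(list(), grid),
               class = "epwave_parameter_error")
})

test_that("analytic landmarks match their closed forms", {
  for (spec in fixture_specs()) {
    lm <- analytic_landmarks(spec)
    f <- spec$frequency
    expect_equal(lm$t_peak, 1000 / (4 * f))
    expect_equal(lm$t_zero, 1000 / (2 * f))
    expect_equal(lm$t_trough, 3000 / (4 * f))
    expect_true(lm$t_peak < lm$t_zero && lm$t_zero < lm$t_trough)
    expect_equal(lm$peak_to_trough_amplitude,
                 lm$peak_amplitude - lm$trough_amplitude)
    expect_equal(lm$abs_area, 1000 * 10 / (pi * f))
    # fixed analytic ratio between the two area constructions
    expect_equal(lm$two_triangle_area / lm$abs_area, pi / 4)
  }
})

test_that("landmark scaling follows the closed forms", {
  base <- analytic_landmarks(sine_spec(500, 10))
  dblA <- analytic_landmarks(sine_spec(500, 20))
  dblF <- analytic_landmarks(sine_spec(1000, 10))
  expect_equal(dblA$abs_area, 2 * base$abs_area)
  expect_equal(dblA$two_triangle_area, 2 * base$two_triangle_area)
  expect_equal(dblA$slope, 2 * base$slope)
  expect_equal(dblF$abs_area, base$abs_area / 2)
})

test_that("signed integral over the peak-to-trough half period vanishes", {
  # distinguishes the implemented absolute area from the signed one
  w <- generate_sine(sine_spec(500, 10), sampling_grid())
  lm <- analytic_landmarks(sine_spec(500, 10))
  inner <- w$times > lm$t_peak & w$times < lm$t_trough
  tt <- c(lm$t_peak, w$times[inner], lm$t_trough)
  yy <- approx(w$times, w$amplitudes, xout = tt)$y
  signed <- sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
  expect_lt(abs(signed), 1e-3)
  expect_gt(analytic_landmarks(sine_spec(500, 10))$abs_area, 6)
})

test_that("landmark display truncation reproduces the expected table column", {
  ref <- phase1_reference_tables()$time_domain
  exp_of <- function(label) ref$expected[ref$label == label]
  for (f in c(500, 1000, 2000)) {
    d <- landmark_display(analytic_landmarks(sine_spec(f, 10)))
    expect_equal(d[["t_peak"]], exp_of(sprintf("%d Hz peak 1 latency (ms)", f)))
    expect_equal(d[["t_trough"]],
                 exp_of(sprintf("%d Hz trough 1 latency (ms)", f)))
    expect_equal(d[["t_zero"]], exp_of(sprintf("%d Hz zero-cross (ms)", f)))
    expect_equal(d[["abs_area"]],
                 exp_of(sprintf("%d Hz area under the curve (uV.ms)", f)))
    expect_equal(d[["two_triangle_area"]],
                 exp_of(sprintf("%d Hz area of two triangles (uV.ms)", f)))
    expect_equal(d[["slope"]], exp_of(sprintf("%d Hz slope (uV/ms)", f)))
  }
})
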