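# End-to-end desk validation: generate the standard sinusoid fixtures,
# mark them automatically, measure, transform, and compare everything
# against the analytic expectations (and against the bundled reference
# examiner readings).

#' Bundled reference examiner readings
#'
#' The printed measurement columns of a three-examiner validation session
#' on the standard sinusoid fixtures (two trained human examiners plus an
#' automatic marker treated as examiner 3), shipped as plain-text tables.
#' They serve as the benchmark input of the agreement harness: each row is
#' one compared value; the time-domain table splits into 11 marking rows
#' (latencies, amplitudes, zero-crossings) and 9 calculation rows (areas,
#' slopes); the frequency-domain table has 12 rows of spectral peak
#' frequencies and amplitudes.
#'
#' @return list with data frames `time_domain` and `freq_domain`
#'   (columns: label, group, expected, examiner1, examiner2, examiner3).
#' @export
phase1_reference_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "epwave", mustWork = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE)
  list(time_domain = rd("reference_time_domain.csv"),
       freq_domain = rd("reference_freq_domain.csv"))
}

reference_report <- function(df, zero_policy = "skip") {
  expected <- measurement_vector(df$label, df$expected)
  raters <- list(examiner1 = measurement_vector(df$label, df$examiner1),
                 examiner2 = measurement_vector(df$label, df$examiner2),
                 examiner3 = measurement_vector(df$label, df$examiner3))
  groups <- split(df$label, df$group)
  build_phase1_report(expected, raters, groups, zero_policy = zero_policy)
}

#' Desk-validation run configuration
#'
#' Collects every knob of [run_phase1_validation()]: grid parameters, the
#' stimulus set, detection and spectral options, the per-measure-class
#' tolerances against the analytic expectations, output and logging. The
#' pipeline is fully deterministic; `seed` is accepted for interface
#' stability but unused.
#'
#' Default tolerances (absolute, vs. the analytic value): latencies and
#' zero-crossings 0.005 ms (exact at 2-decimal display), amplitudes 0.01
#' uV, areas 0.05 uV.ms, slopes 0.5 uV/ms, spectral frequency 0.5 Hz,
#' spectral amplitude 0.01 uV. They bound the grid-snapping error of the
#' 3072-sample sweep, not examiner variability.
#'
#' @param out_dir directory for report files, or `NULL` for none.
#' @param frequencies stimulus frequencies (Hz).
#' @param amplitude stimulus peak amplitude (uV).
#' @param start_time,duration,n_samples,endpoint_mode see [sampling_grid()].
#' @param n_pairs pairs marked per waveform.
#' @param baseline zero-cross baseline (uV).
#' @param tie_tol detector tie tolerance, see [auto_mark_extrema()].
#' @param fft_interval optional time interval for the spectra (ms).
#' @param zero_pad spectral zero-padding factor.
#' @param tolerances named list overriding individual default tolerances.
#' @param dialect output [csv_dialect()].
#' @param include_reference also compare the bundled examiner readings.
#' @param log_level one of debug/info/warn/error.
#' @param seed reserved; the pipeline has no stochastic stage.
#' @return an object of class `phase1_config`.
#' @export
phase1_config <- function(out_dir = NULL,
                          frequencies = c(500, 1000, 2000),
                          amplitude = 10,
                          start_time = 0, duration = 10, n_samples = 3072,
                          endpoint_mode = "half_open",
                          n_pairs = 1, baseline = 0, tie_tol = 1e-3,
                          fft_interval = NULL, zero_pad = 1,
                          tolerances = list(),
                          dialect = csv_dialect(),
                          include_reference = TRUE,
                          log_level = "warn",
                          seed = NULL) {
  tol <- list(latency = 0.005, zero_cross = 0.005, amplitude = 0.01,
              area = 0.05, triangle = 0.05, slope = 0.5,
              fft_frequency = 0.5, fft_amplitude = 0.01)
  tol[names(tolerances)] <- tolerances
  structure(list(out_dir = out_dir, frequencies = frequencies,
                 amplitude = amplitude, start_time = start_time,
                 duration = duration, n_samples = n_samples,
                 endpoint_mode = endpoint_mode, n_pairs = n_pairs,
                 baseline = baseline, tie_tol = tie_tol,
                 fft_interval = fft_interval, zero_pad = zero_pad,
                 tolerances = tol, dialect = dialect,
                 include_reference = include_reference,
                 log_level = log_level, seed = seed),
            class = "phase1_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop(structure(
        class = c("epwave_stage_error", "epwave_error", "error", "condition"),
        list(message = sprintf("[stage: %s] %s", stage, conditionMessage(e)),
             call = NULL, stage = stage)))
    }),
    message = function(m) invokeRestart("muffleMessage"))
}

#' Run the end-to-end desk validation
#'
#' Generates the configured sinusoids and their sum, auto-marks the first
#' peak--trough pair and zero-crossing of each tone, computes the full
#' time-domain measure set, transforms each channel to a single-sided
#' amplitude spectrum and marks the spectral peaks, then compares every
#' observed display value against its analytic expectation with the
#' agreement harness. When `include_reference` is set, the bundled
#' examiner readings are run through the same harness. Stage failures
#' raise a classed condition naming the stage; tolerance failures do not
#' raise, they set `passed = FALSE`.
#'
#' @param config a [phase1_config()].
#' @return an object of class `phase1_validation`: `$measures` (per-tone
#'   [measure_pair()] results), `$spectra`, `$observed` / `$expected`
#'   measurement vectors, `$pipeline_report` (agreement of the automatic
#'   pipeline vs. analytic values), `$reference_report` (bundled examiner
#'   readings, if requested), `$checks` (per-measure tolerance table),
#'   `$passed`, `$files`.
#' @export
run_phase1_validation <- function(config = phase1_config()) {
  stopifnot(inherits(config, "phase1_config"))
  old <- options(epwave.log_level = config$log_level)
  on.exit(options(old), add = TRUE)
  freqs <- config$frequencies

  grid <- with_stage("simulate", {
    sampling_grid(config$start_time, config$duration, config$n_samples,
                  config$endpoint_mode)
  })
  specs <- with_stage("simulate", {
    lapply(freqs, sine_spec, amplitude = config$amplitude)
  })
  table <- with_stage("simulate", phase1_waveforms(grid, specs))
  ep_log("info", sprintf("generated %d tones + sum on %d samples",
                         length(freqs), config$n_samples))

  fs <- 1000 * config$n_samples / config$duration  # Hz
  measures <- with_stage("detect", {
    if (max(freqs) * 2 >= fs) {
      ep_stop("epwave_detection_error",
              sprintf(paste0("sampling rate %.6g Hz cannot resolve extrema ",
                             "of the %g Hz component (Nyquist %.6g Hz)"),
                      fs, max(freqs), fs / 2))
    }
    lapply(seq_along(freqs), function(i) {
      w <- table_waveform(table, sprintf("f%g", freqs[i]))
      pair <- auto_mark_extrema(w, n_pairs = config$n_pairs,
                                tie_tol = config$tie_tol)[[1L]]
      measure_pair(w, pair, baseline = config$baseline)
    })
  })
  names(measures) <- sprintf("f%g", freqs)

  spectra <- with_stage("fft", {
    out <- lapply(names(table$channels), function(ch) {
      amplitude_spectrum(table_waveform(table, ch),
                         interval = config$fft_interval,
                         zero_pad = config$zero_pad)
    })
    names(out) <- names(table$channels)
    out
  })
  spec_peaks <- with_stage("fft", {
    out <- lapply(seq_along(freqs), function(i) {
      auto_mark_spectral_peaks(spectra[[sprintf("f%g", freqs[i])]], 1L)[[1L]]
    })
    names(out) <- sprintf("f%g", freqs)
    if (!is.null(spectra$sum)) {
      out$sum <- auto_mark_spectral_peaks(spectra$sum, length(freqs))
    }
    out
  })

  cmp <- with_stage("compare", {
    phase1_comparison(freqs, config$amplitude, measures, spec_peaks,
                      config$tolerances)
  })

  reference <- NULL
  if (config$include_reference) {
    reference <- with_stage("compare", {
      tabs <- phase1_reference_tables()
      list(time_domain = reference_report(tabs$time_domain),
           freq_domain = reference_report(tabs$freq_domain))
    })
  }

  files <- character(0)
  if (!is.null(config$out_dir)) {
    files <- with_stage("report", {
      write_phase1_outputs(config, table, measures, spectra, cmp, reference)
    })
  }

  structure(list(grid = grid, table = table, measures = measures,
                 spectra = spectra, spec_peaks = spec_peaks,
                 observed = cmp$observed, expected = cmp$expected,
                 pipeline_report = cmp$report, checks = cmp$checks,
                 reference_report = reference,
                 passed = all(cmp$checks$pass), files = files),
            class = "phase1_validation")
}

# Build the table-layout measurement vectors for the automatic pipeline and
# compare them to the analytic expectations. The agreement report mirrors
# the printed-table convention (display values, one row per compared value);
# the tolerance checks bound the raw measurement error, so they compare the
# full-precision quantities.
phase1_comparison <- function(freqs, amplitude, measures, spec_peaks,
                              tol) {
  lm <- lapply(freqs, function(f) analytic_landmarks(sine_spec(f, amplitude)))

  lab <- character(0); grp <- character(0); cls <- character(0)
  obs <- numeric(0); expv <- numeric(0)
  obs_d <- numeric(0); exp_d <- numeric(0)
  add <- function(label, group, class, o, e, od, ed) {
    lab <<- c(lab, label); grp <<- c(grp, group); cls <<- c(cls, class)
    obs <<- c(obs, o); expv <<- c(expv, e)
    obs_d <<- c(obs_d, od); exp_d <<- c(exp_d, ed)
  }
  val <- function(i, field) measures[[i]]$values[[field]]
  dsp <- function(i, field) measures[[i]]$display[[field]]
  for (i in seq_along(freqs)) {
    add(sprintf("%g Hz peak 1 latency (ms)", freqs[i]), "marking", "latency",
        val(i, "peak_latency"), lm[[i]]$t_peak,
        dsp(i, "peak_latency"), display_trunc(lm[[i]]$t_peak))
  }
  add("all frequencies peak 1 amplitude (uV)", "marking", "amplitude",
      val(1L, "peak_amplitude"), amplitude,
      dsp(1L, "peak_amplitude"), amplitude)
  for (i in seq_along(freqs)) {
    add(sprintf("%g Hz trough 1 latency (ms)", freqs[i]), "marking",
        "latency",
        val(i, "trough_latency"), lm[[i]]$t_trough,
        dsp(i, "trough_latency"), display_trunc(lm[[i]]$t_trough))
  }
  add("all frequencies trough 1 amplitude (uV)", "marking", "amplitude",
      val(1L, "trough_amplitude"), -amplitude,
      dsp(1L, "trough_amplitude"), -amplitude)
  for (i in seq_along(freqs)) {
    add(sprintf("%g Hz zero-cross (ms)", freqs[i]), "marking", "zero_cross",
        val(i, "zero_cross"), lm[[i]]$t_zero,
        dsp(i, "zero_cross"), display_trunc(lm[[i]]$t_zero))
  }
  for (i in seq_along(freqs)) {
    add(sprintf("%g Hz area under the curve (uV.ms)", freqs[i]),
        "calculation", "area",
        val(i, "abs_area"), lm[[i]]$abs_area,
        dsp(i, "abs_area"), display_trunc(lm[[i]]$abs_area))
  }
  for (i in seq_along(freqs)) {
    add(sprintf("%g Hz area of two triangles (uV.ms)", freqs[i]),
        "calculation", "triangle",
        val(i, "two_triangle_area"), lm[[i]]$two_triangle_area,
        dsp(i, "two_triangle_area"), display_trunc(lm[[i]]$two_triangle_area))
  }
  for (i in seq_along(freqs)) {
    add(sprintf("%g Hz slope (uV/ms)", freqs[i]), "calculation", "slope",
        val(i, "slope"), lm[[i]]$slope,
        dsp(i, "slope"), display_trunc(lm[[i]]$slope))
  }
  for (i in seq_along(freqs)) {
    pk <- spec_peaks[[sprintf("f%g", freqs[i])]]
    add(sprintf("%g Hz FFT frequency (Hz)", freqs[i]), "fft",
        "fft_frequency", pk$frequency, freqs[i], pk$frequency, freqs[i])
    add(sprintf("%g Hz FFT amplitude (uV)", freqs[i]), "fft",
        "fft_amplitude", pk$amplitude, amplitude,
        display_round(pk$amplitude), amplitude)
  }
  if (!is.null(spec_peaks$sum)) {
    sorted <- sort(freqs)
    for (i in seq_along(spec_peaks$sum)) {
      pk <- spec_peaks$sum[[i]]
      add(sprintf("sum FFT peak %d frequency (Hz)", i), "fft",
          "fft_frequency", pk$frequency, sorted[i], pk$frequency, sorted[i])
      add(sprintf("sum FFT peak %d amplitude (uV)", i), "fft",
          "fft_amplitude", pk$amplitude, amplitude,
          display_round(pk$amplitude), amplitude)
    }
  }

  observed <- measurement_vector(lab, obs_d)
  expected <- measurement_vector(lab, exp_d)
  groups <- split(lab, grp)
  report <- build_phase1_report(expected, list(automatic = observed), groups)
  tol_vec <- unname(unlist(tol[cls]))
  checks <- data.frame(label = lab, group = grp, class = cls,
                       observed = obs, expected = expv,
                       observed_display = obs_d, expected_display = exp_d,
                       tolerance = tol_vec,
                       pass = abs(obs - expv) <= tol_vec,
                       stringsAsFactors = FALSE)
  list(observed = observed, expected = expected, report = report,
       checks = checks)
}

write_phase1_outputs <- function(config, table, measures, spectra, cmp,
                                 reference) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  files <- c(waveforms = p("waveforms.csv"),
             markers = p("markers.csv"),
             measures = p("measures.csv"),
             checks = p("checks.csv"),
             agreement = p("agreement_summary.csv"))
  write_waveform_table(table, files[["waveforms"]], config$dialect)
  mk <- list()
  for (nm in names(measures)) {
    pr <- measures[[nm]]$pair
    for (m in list(pr$peak, pr$zero, pr$trough)) {
      m$channel <- nm
      mk[[length(mk) + 1L]] <- m
    }
  }
  write_markers(mk, files[["markers"]])
  rows <- do.call(rbind, lapply(names(measures), function(nm) {
    ms <- measures[[nm]]
    data.frame(channel = nm, measure = names(ms$values),
               value = unname(ms$values), display = unname(ms$display),
               stringsAsFactors = FALSE)
  }))
  write_df_csv(rows, files[["measures"]])
  write_df_csv(cmp$checks, files[["checks"]])
  summ <- cmp$report$summary
  summ$source <- "pipeline"
  if (!is.null(reference)) {
    for (nm in names(reference)) {
      s <- reference[[nm]]$summary
      s$source <- paste0("reference_", nm)
      summ <- rbind(summ, s)
    }
  }
  write_df_csv(summ, files[["agreement"]])
  files
}

# Deterministic data-frame writer (fixed formatting, no locale dependence).
write_df_csv <- function(df, dest) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]], 10)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(as.list(df)), sep = ",")))
  writeLines(lines, dest, useBytes = TRUE)
  invisible(dest)
}

#' @export
print.phase1_validation <- function(x, ...) {
  cat(sprintf("<phase1 validation: %s>\n",
              if (x$passed) "PASSED" else "FAILED"))
  print(x$pipeline_report)
  if (!is.null(x$reference_report)) {
    cat("\nreference examiner readings (time domain):\n")
    print(x$reference_report$time_domain)
  }
  if (any(!x$checks$pass)) {
    cat("\nfailed checks:\n")
    print(x$checks[!x$checks$pass, ], row.names = FALSE)
  }
  invisible(x)
}
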