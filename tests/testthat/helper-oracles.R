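# Independent oracles used by the property tests. These are deliberately
# naive (plain loops, no shared code with the package internals).

# Strict local extrema by pointwise comparison.
scan_extrema <- function(y) {
  peaks <- integer(0)
  troughs <- integer(0)
  for (i in 2:(length(y) - 1L)) {
    if (y[i] > y[i - 1L] && y[i] > y[i + 1L]) peaks <- c(peaks, i)
    if (y[i] < y[i - 1L] && y[i] < y[i + 1L]) troughs <- c(troughs, i)
  }
  list(peaks = peaks, troughs = troughs)
}

# Most prominent peak (flanking-trough prominence, earliest within a
# relative tie tolerance), then the most prominent trough after it.
scan_best_pair <- function(y, tie_tol = 1e-3) {
  ex <- scan_extrema(y)
  prom_of <- function(i, own, other, is_peak) {
    lt <- other[other < i]
    rt <- other[other > i]
    fl <- c(if (length(lt)) y[max(lt)], if (length(rt)) y[min(rt)])
    if (is_peak) y[i] - max(fl) else min(fl) - y[i]
  }
  elig <- ex$peaks[vapply(ex$peaks, function(i) any(ex$troughs > i), TRUE)]
  pprom <- vapply(elig, prom_of, 1, own = ex$peaks, other = ex$troughs,
                  is_peak = TRUE)
  best <- max(pprom)
  pk <- elig[which(pprom >= best - abs(best) * tie_tol)[1L]]
  tc <- ex$troughs[ex$troughs > pk]
  tprom <- vapply(tc, prom_of, 1, own = ex$troughs, other = ex$peaks,
                  is_peak = FALSE)
  tbest <- max(tprom)
  tr <- tc[which(tprom >= tbest - abs(tbest) * tie_tol)[1L]]
  list(peak = pk, trough = tr)
}

# Smooth pseudo-EP trace: a few random sinusoids on a 10 ms sweep.
random_smooth_wave <- function(n = 2048, k = 3) {
  t <- (0:(n - 1L)) * 10 / n
  y <- numeric(n)
  for (j in seq_len(k)) {
    y <- y + stats::runif(1, 1, 10) *
      sin(2 * pi * stats::runif(1, 0.2, 1.2) * t + stats::runif(1, 0, 2 * pi))
  }
  waveform(t, y)
}

# ICC(A,1) through R's own ANOVA decomposition.
icc_oracle <- function(mat) {
  df <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1L]]
  rn <- trimws(rownames(tab))
  msr <- tab[rn == "subj", "Mean Sq"]
  msc <- tab[rn == "rater", "Mean Sq"]
  mse <- tab[rn == "Residuals", "Mean Sq"]
  n <- nrow(mat)
  k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# The three standard tones at 10 uV.
fixture_specs <- function() lapply(c(500, 1000, 2000), sine_spec, amplitude = 10)

mv <- function(labels, values) measurement_vector(labels, values)
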