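# Internal helpers: classed conditions, display rounding, logging.

ep_stop <- function(subclass, msg) {
  stop(structure(
    class = c(subclass, "epwave_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Last-observation-carried-forward over NA; base-R, vectorised.
fill_prev <- function(v) {
  i <- seq_along(v)
  i[is.na(v)] <- 0L
  i <- cummax(i)
  out <- rep(NA_real_, length(v))
  ok <- i > 0L
  out[ok] <- v[i[ok]]
  out
}

fill_next <- function(v) rev(fill_prev(rev(v)))

#' Display rounding for reported measures
#'
#' Clinical evoked-potential reports quote latencies and amplitudes at two
#' decimals. Marked (measured) values are rounded half-up on the magnitude;
#' derived quantities (areas, slopes, analytic landmarks) are truncated
#' toward zero. Both rules reproduce the conventional printed values: a
#' grid-snapped trough latency of 0.748698 ms displays as 0.75, while the
#' analytic 2 kHz peak latency 0.125 ms and the 500 Hz absolute area
#' 6.3662 uV.ms display as 0.12 and 6.36. A 1e-9 guard absorbs binary
#' representation error before the floor.
#'
#' @param x numeric vector.
#' @param digits decimal places retained (default 2).
#' @return numeric vector at the requested precision.
#' @examples
#' display_round(0.748698)  # 0.75
#' display_trunc(6.366198)  # 6.36
#' @export
display_round <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @rdname display_round
#' @export
display_trunc <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

# Leveled logging to stderr; reports never share this stream.
ep_log <- function(level = c("debug", "info", "warn", "error"), msg) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  threshold <- getOption("epwave.log_level", "warn")
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[%s] %s", level, msg))
  }
  invisible(NULL)
}

fmt_num <- function(x, sigdig = 6) {
  sprintf(paste0("%.", sigdig, "g"), x)
}
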