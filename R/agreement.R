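# Agreement harness: observed-vs-expected deviation metrics (MAD, MAPE,
# Pearson r) and inter-rater ICC, the descriptive validation layer used to
# compare examiner or automatic readings against analytic ground truth.

#' Measurement vector
#'
#' A labeled vector of measurement values; units may differ between labels
#' (a label carries its unit in the name, e.g. "500 Hz peak 1 latency
#' (ms)"), so the metrics below are descriptive rather than dimensional.
#'
#' @param labels character vector of unique measure names.
#' @param values numeric vector, same length.
#' @return an object of class `measurement_vector`.
#' @export
measurement_vector <- function(labels, values) {
  labels <- as.character(labels)
  values <- as.numeric(values)
  if (length(labels) != length(values) || length(labels) == 0L) {
    ep_stop("epwave_parameter_error",
            "labels and values must be non-empty and of equal length")
  }
  if (anyDuplicated(labels)) {
    ep_stop("epwave_parameter_error", "labels must be unique")
  }
  structure(list(labels = labels, values = values),
            class = "measurement_vector")
}

#' @export
print.measurement_vector <- function(x, ...) {
  print(stats::setNames(x$values, x$labels))
  invisible(x)
}

check_aligned <- function(observed, expected) {
  stopifnot(inherits(observed, "measurement_vector"),
            inherits(expected, "measurement_vector"))
  if (!identical(observed$labels, expected$labels)) {
    ep_stop("epwave_alignment_error",
            "observed and expected labels differ (same labels, same order required)")
  }
}

#' Mean absolute deviation
#'
#' Mean of |observed - expected| over the shared labels.
#'
#' @param observed,expected [measurement_vector()] objects with identical
#'   labels in identical order.
#' @return non-negative scalar.
#' @export
mean_abs_deviation <- function(observed, expected) {
  check_aligned(observed, expected)
  mean(abs(observed$values - expected$values))
}

#' Mean absolute fractional error (MAPE)
#'
#' Mean of |observed - expected| / |expected|, stored as a dimensionless
#' fraction. (Published agreement tables sometimes print this fraction with
#' a percent sign; multiply by 100 for a true percentage.)
#'
#' @inheritParams mean_abs_deviation
#' @param zero_policy `"error"` rejects zero expected values; `"skip"`
#'   drops them from the mean.
#' @return non-negative scalar (fraction).
#' @export
mean_abs_pct_error <- function(observed, expected,
                               zero_policy = c("error", "skip")) {
  check_aligned(observed, expected)
  zero_policy <- match.arg(zero_policy)
  keep <- expected$values != 0
  if (!all(keep)) {
    if (zero_policy == "error") {
      ep_stop("epwave_domain_error",
              "expected values contain 0 (set zero_policy = 'skip')")
    }
    ep_log("warn", sprintf("MAPE: skipping %d zero-expected label(s)",
                           sum(!keep)))
  }
  mean(abs(observed$values[keep] - expected$values[keep]) /
         abs(expected$values[keep]))
}

#' Pearson correlation between observed and expected
#'
#' @inheritParams mean_abs_deviation
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(observed, expected) {
  check_aligned(observed, expected)
  if (length(observed$values) < 3L) {
    ep_stop("epwave_parameter_error", "Pearson r needs n >= 3")
  }
  if (stats::sd(observed$values) == 0 || stats::sd(expected$values) == 0) {
    ep_stop("epwave_degenerate_error",
            "zero variance: correlation undefined")
  }
  stats::cor(observed$values, expected$values)
}

#' Intraclass correlation (two-way, absolute agreement, single measure)
#'
#' ICC(A,1) from the standard two-way mean-squares decomposition with
#' subjects (labels) as rows and raters as columns:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares, n the number of subjects and k the number of
#' raters. Absolute agreement: a constant offset between raters is
#' penalized. Equals 1 iff the raters are identical (on non-degenerate
#' data).
#'
#' @param raters list (>= 2) of [measurement_vector()] objects with
#'   identical labels in identical order (>= 2 labels).
#' @return scalar ICC.
#' @export
icc_agreement <- function(raters) {
  if (!is.list(raters) || length(raters) < 2L) {
    ep_stop("epwave_parameter_error", "need at least two raters")
  }
  for (r in raters[-1L]) check_aligned(r, raters[[1L]])
  x <- do.call(cbind, lapply(raters, `[[`, "values"))
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L) {
    ep_stop("epwave_parameter_error", "need at least two subjects")
  }
  gm <- mean(x)
  rm <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((x - outer(rm, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Agreement report for one observed vector
#'
#' Per-label absolute deviations plus the summary metrics.
#'
#' @inheritParams mean_abs_deviation
#' @param zero_policy passed to [mean_abs_pct_error()].
#' @return an object of class `agreement_report` with fields `deviations`
#'   (named numeric), `mad`, `mape`, `pearson_r`, `n`.
#' @export
agreement_report <- function(observed, expected, zero_policy = "skip") {
  check_aligned(observed, expected)
  dev <- abs(observed$values - expected$values)
  names(dev) <- observed$labels
  r <- tryCatch(pearson_r(observed, expected), epwave_error = function(e) NA_real_)
  structure(list(deviations = dev,
                 mad = mean(dev),
                 mape = mean_abs_pct_error(observed, expected, zero_policy),
                 pearson_r = r,
                 n = length(dev)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement: n=%d, MAD=%.4f, MAPE=%.4f (x100 = %.4f%%), r=%s>\n",
    x$n, x$mad, x$mape, 100 * x$mape,
    if (is.na(x$pearson_r)) "NA" else sprintf("%.4f", x$pearson_r)))
  invisible(x)
}

#' Grouped multi-rater comparison report
#'
#' The full desk-validation comparison: each rater's vector is compared
#' against the expected values within each label group (e.g. the marking
#' rows versus the calculation rows of a printed comparison table, one row
#' per printed value), and an inter-rater ICC is computed per group. Groups
#' must partition the labels; empty groups are dropped with a warning.
#'
#' @param expected a [measurement_vector()] of theoretical values.
#' @param raters named list of [measurement_vector()] objects, aligned with
#'   `expected`.
#' @param groups named list of character vectors partitioning the labels.
#' @param zero_policy passed to [mean_abs_pct_error()].
#' @return an object of class `phase1_report`: `$summary` data frame
#'   (group, rater, n, mad, mape, pearson_r), `$reports` nested list of
#'   [agreement_report()] objects, `$icc` named numeric per group.
#' @export
build_phase1_report <- function(expected, raters, groups,
                                zero_policy = "skip") {
  stopifnot(inherits(expected, "measurement_vector"), is.list(raters))
  if (is.null(names(raters)) || any(!nzchar(names(raters)))) {
    names(raters) <- paste0("rater", seq_along(raters))
  }
  for (r in raters) check_aligned(r, expected)
  if (!is.list(groups) || is.null(names(groups))) {
    ep_stop("epwave_parameter_error", "groups must be a named list of labels")
  }
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    ep_log("warn", sprintf("dropping empty group(s): %s",
                           paste(names(groups)[empty], collapse = ", ")))
    warning("empty group(s) excluded from report: ",
            paste(names(groups)[empty], collapse = ", "), call. = FALSE)
    groups <- groups[!empty]
  }
  all_lab <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_lab)) {
    ep_stop("epwave_parameter_error", "groups overlap")
  }
  if (!setequal(all_lab, expected$labels)) {
    ep_stop("epwave_parameter_error",
            "groups must cover every label exactly once")
  }
  subset_mv <- function(mv, labs) {
    idx <- match(labs, mv$labels)
    measurement_vector(mv$labels[idx], mv$values[idx])
  }
  reports <- list()
  rows <- list()
  icc <- numeric(0)
  for (g in names(groups)) {
    labs <- intersect(expected$labels, groups[[g]])  # keep table order
    exp_g <- subset_mv(expected, labs)
    rat_g <- lapply(raters, subset_mv, labs = labs)
    reports[[g]] <- lapply(rat_g, agreement_report, expected = exp_g,
                           zero_policy = zero_policy)
    icc[g] <- if (length(labs) >= 2L) {
      tryCatch(icc_agreement(rat_g), epwave_error = function(e) NA_real_)
    } else NA_real_
    for (r in names(rat_g)) {
      rep_ <- reports[[g]][[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, rater = r, n = rep_$n, mad = rep_$mad,
        mape = rep_$mape, pearson_r = rep_$pearson_r,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 reports = reports, icc = icc),
            class = "phase1_report")
}

#' @export
print.phase1_report <- function(x, digits = 4, ...) {
  df <- x$summary
  df$mad <- round(df$mad, digits)
  df$mape <- round(df$mape, digits)
  df$pearson_r <- round(df$pearson_r, digits)
  print(df, row.names = FALSE)
  if (length(x$icc)) {
    cat("inter-rater ICC(A,1) per group:\n")
    print(round(x$icc, digits))
  }
  invisible(x)
}
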