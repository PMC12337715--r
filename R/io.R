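# Delimited-text I/O for waveform tables and marker sidecars.
#
# Clinical systems export sweeps as plain text tables — time in the first
# column, one or more voltage channels after it — but the dialect varies
# with the export locale: comma/semicolon/tab separators and period or
# comma decimal marks are all seen in practice. The reader sniffs the
# dialect from the head of the file unless one is given.

#' Multi-channel waveform table
#'
#' One shared time axis plus named voltage channels, the in-memory image of
#' a delimited text export. Channel names must be unique and every channel
#' must match the time axis length.
#'
#' @param times numeric vector of sample times (ms), strictly increasing and
#'   uniformly spaced.
#' @param channels named list of numeric vectors (uV).
#' @param spacing_tol relative tolerance on uniform spacing (readers of
#'   low-precision text may relax it).
#' @return an object of class `waveform_table`.
#' @export
waveform_table <- function(times, channels, spacing_tol = 1e-9) {
  if (!is.list(channels) || length(channels) == 0L) {
    ep_stop("epwave_format_error", "waveform table needs at least one channel")
  }
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    ep_stop("epwave_format_error", "channel names must be unique and non-empty")
  }
  # validate the axis once through the waveform constructor
  probe <- waveform(times, channels[[1L]], spacing_tol = spacing_tol)
  for (j in seq_along(channels)) {
    if (length(channels[[j]]) != length(times)) {
      ep_stop("epwave_format_error",
              sprintf("channel '%s' length differs from time axis", nm[j]))
    }
  }
  structure(list(times = probe$times,
                 channels = lapply(channels, as.numeric)),
            class = "waveform_table")
}

#' @export
print.waveform_table <- function(x, ...) {
  cat(sprintf("<waveform_table: %d samples x %d channels (%s)>\n",
              length(x$times), length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.waveform_table <- function(x, ...) {
  cbind(data.frame(time_ms = x$times), as.data.frame(x$channels))
}

#' @rdname waveform_table
#' @param table a `waveform_table`.
#' @param channel channel name (default: first channel).
#' @return `table_waveform()`: the selected channel as a [waveform()].
#' @export
table_waveform <- function(table, channel = NULL) {
  stopifnot(inherits(table, "waveform_table"))
  if (is.null(channel)) channel <- names(table$channels)[1L]
  if (!channel %in% names(table$channels)) {
    ep_stop("epwave_parameter_error",
            sprintf("no channel '%s' (have: %s)", channel,
                    paste(names(table$channels), collapse = ", ")))
  }
  waveform(table$times, table$channels[[channel]], channel = channel,
           spacing_tol = 1e-5)
}

#' CSV dialect
#'
#' @param sep field separator: `","`, `";"` or `"\t"`.
#' @param dec decimal mark: `"."` or `","`; must differ from `sep`.
#' @param header logical, header row present.
#' @param encoding text encoding.
#' @return an object of class `csv_dialect`.
#' @export
csv_dialect <- function(sep = ",", dec = ".", header = TRUE,
                        encoding = "UTF-8") {
  if (!sep %in% c(",", ";", "\t")) {
    ep_stop("epwave_parameter_error", "sep must be ',', ';' or tab")
  }
  if (!dec %in% c(".", ",")) {
    ep_stop("epwave_parameter_error", "dec must be '.' or ','")
  }
  if (identical(sep, dec)) {
    ep_stop("epwave_parameter_error", "separator and decimal mark must differ")
  }
  structure(list(sep = sep, dec = dec, header = isTRUE(header),
                 encoding = encoding),
            class = "csv_dialect")
}

# Lines beginning with '#' are comments throughout the text formats.
read_data_lines <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n"))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], numbers = which(keep))
}

#' Sniff a CSV dialect
#'
#' Inspects up to ten data lines. Semicolon and tab separators take
#' precedence over the comma (a file whose fields carry decimal commas
#' necessarily uses one of the former); the decimal mark is then inferred
#' from the fields, and a header is assumed when the first line does not
#' parse as numbers.
#'
#' @param source path, connection or character vector of lines.
#' @return a [csv_dialect()].
#' @export
sniff_dialect <- function(source) {
  dl <- read_data_lines(source)
  head_lines <- utils::head(dl$lines, 10L)
  if (length(head_lines) == 0L) {
    ep_stop("epwave_format_error", "empty input: cannot sniff dialect")
  }
  counts <- function(ch) {
    vapply(head_lines, function(l) lengths(regmatches(
      l, gregexpr(ch, l, fixed = TRUE))), 1L, USE.NAMES = FALSE)
  }
  consistent <- function(ch) {
    cnt <- counts(ch)
    if (all(cnt == cnt[1L]) && cnt[1L] > 0L) cnt[1L] else 0L
  }
  sep <- if (consistent(";") > 0L) ";"
  else if (consistent("\t") > 0L) "\t"
  else if (consistent(",") > 0L) ","
  else ep_stop("epwave_format_error", "could not determine field separator")
  body <- paste(head_lines[-1L], collapse = sep)
  if (length(head_lines) == 1L) body <- head_lines
  dec <- if (sep != "," && grepl(",", body, fixed = TRUE)) "," else "."
  fields <- strsplit(head_lines[1L], sep, fixed = TRUE)[[1L]]
  nums <- suppressWarnings(as.numeric(chartr(dec, ".", fields)))
  csv_dialect(sep = sep, dec = dec, header = anyNA(nums))
}

parse_fields <- function(line, dialect) {
  strsplit(line, dialect$sep, fixed = TRUE)[[1L]]
}

parse_numeric <- function(fields, dialect) {
  suppressWarnings(as.numeric(chartr(dialect$dec, ".", fields)))
}

#' Read a waveform table
#'
#' Parses a delimited text table: first column time (ms), remaining columns
#' channels (uV). Comment lines start with `#`. Ragged rows, non-numeric
#' cells and non-increasing time raise a format error naming the offending
#' line.
#'
#' @param source path, connection or character vector of lines.
#' @param dialect a [csv_dialect()] or `"auto"` to sniff.
#' @return a [waveform_table()].
#' @export
read_waveform_table <- function(source, dialect = "auto") {
  if (identical(dialect, "auto")) dialect <- sniff_dialect(source)
  stopifnot(inherits(dialect, "csv_dialect"))
  dl <- read_data_lines(source)
  if (length(dl$lines) == 0L) {
    ep_stop("epwave_format_error", "empty input")
  }
  lines <- dl$lines
  numbers <- dl$numbers
  col_names <- NULL
  if (dialect$header) {
    col_names <- parse_fields(lines[1L], dialect)
    lines <- lines[-1L]
    numbers <- numbers[-1L]
  }
  if (length(lines) == 0L) {
    ep_stop("epwave_format_error", "no data rows")
  }
  rows <- lapply(lines, parse_fields, dialect = dialect)
  ncols <- lengths(rows)
  if (any(ncols != ncols[1L])) {
    bad <- which(ncols != ncols[1L])[1L]
    ep_stop("epwave_format_error",
            sprintf("ragged row at line %d (%d fields, expected %d)",
                    numbers[bad], ncols[bad], ncols[1L]))
  }
  if (ncols[1L] < 2L) {
    ep_stop("epwave_format_error", "need a time column plus >= 1 channel")
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncols[1L])
  for (i in seq_along(rows)) {
    vals <- parse_numeric(rows[[i]], dialect)
    if (anyNA(vals)) {
      ep_stop("epwave_format_error",
              sprintf("non-numeric cell at line %d", numbers[i]))
    }
    mat[i, ] <- vals
  }
  tm <- mat[, 1L]
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1L] + 1L
    ep_stop("epwave_format_error",
            sprintf("non-increasing time at line %d", numbers[bad]))
  }
  if (is.null(col_names)) {
    col_names <- c("t", paste0("ch", seq_len(ncols[1L] - 1L)))
  }
  channels <- lapply(seq_len(ncols[1L] - 1L), function(j) mat[, j + 1L])
  names(channels) <- col_names[-1L]
  # text precision limits how uniform the parsed axis can be
  waveform_table(tm, channels, spacing_tol = 1e-5)
}

#' Write a waveform table
#'
#' Deterministic, bit-stable output: channels at 7 significant digits, the
#' time axis at 15 (so the uniform-spacing invariant survives a round
#' trip). Decimal commas are emitted when the dialect asks for them.
#'
#' @param table a [waveform_table()].
#' @param dest file path.
#' @param dialect a [csv_dialect()].
#' @return `dest`, invisibly.
#' @export
write_waveform_table <- function(table, dest, dialect = csv_dialect()) {
  stopifnot(inherits(dialect, "csv_dialect"))
  if (!inherits(table, "waveform_table") || length(table$channels) == 0L) {
    ep_stop("epwave_format_error", "nothing to write: empty waveform table")
  }
  cols <- c(list(fmt_num(table$times, 15)),
            lapply(table$channels, fmt_num, sigdig = 7))
  if (dialect$dec == ",") cols <- lapply(cols, chartr, old = ".", new = ",")
  body <- do.call(paste, c(cols, sep = dialect$sep))
  header <- if (dialect$header) {
    paste(c("t", names(table$channels)), collapse = dialect$sep)
  }
  ok <- tryCatch({
    writeLines(c(header, body), dest, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    ep_stop("epwave_io_error", sprintf("cannot write to '%s'", dest))
  }
  invisible(dest)
}

marker_kinds <- c("peak", "trough", "zero_cross")

#' Read / write marker sidecar files
#'
#' Markers persist as comma-separated text with the fixed column order
#' `channel,kind,time_ms,amplitude_uV,source,label` and locale-independent
#' numbers. An empty file (or header only) yields an empty list; an unknown
#' kind token is a format error. The reader does not validate marker times
#' against any waveform — that is the caller's concern.
#'
#' @param source path or character vector of lines.
#' @return `read_markers()`: list of [marker()] objects (attribute
#'   `channel` retained per marker).
#' @export
read_markers <- function(source) {
  dl <- read_data_lines(source)
  lines <- dl$lines
  if (length(lines) > 0L && startsWith(lines[1L], "channel,")) {
    lines <- lines[-1L]
    dl$numbers <- dl$numbers[-1L]
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(f) < 5L) {
      ep_stop("epwave_format_error",
              sprintf("marker row at line %d has %d fields, expected >= 5",
                      dl$numbers[i], length(f)))
    }
    if (!f[2L] %in% marker_kinds) {
      ep_stop("epwave_format_error",
              sprintf("unknown marker kind '%s' at line %d", f[2L],
                      dl$numbers[i]))
    }
    tv <- suppressWarnings(as.numeric(f[3L:4L]))
    if (anyNA(tv)) {
      ep_stop("epwave_format_error",
              sprintf("non-numeric marker value at line %d", dl$numbers[i]))
    }
    m <- marker(f[2L], tv[1L], tv[2L], source = f[5L],
                label = if (length(f) >= 6L) f[6L] else "")
    m$channel <- f[1L]
    out[[i]] <- m
  }
  out
}

#' @rdname read_markers
#' @param markers list of [marker()] objects.
#' @param dest file path.
#' @return `write_markers()`: `dest`, invisibly.
#' @export
write_markers <- function(markers, dest) {
  rows <- vapply(markers, function(m) {
    paste(c(if (is.null(m$channel)) "" else m$channel,
            m$kind, fmt_num(m$time, 15), fmt_num(m$amplitude, 15),
            m$source, m$label), collapse = ",")
  }, "")
  ok <- tryCatch({
    writeLines(c("channel,kind,time_ms,amplitude_uV,source,label", rows),
               dest, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ep_stop("epwave_io_error", sprintf("cannot write to '%s'", dest))
  invisible(dest)
}
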