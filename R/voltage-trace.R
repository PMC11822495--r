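#' Construct a voltage trace
#'
#' A voltage trace is the universal currency of the package: a uniformly
#' sampled voltage time series stored as a tibble with columns `time`
#' (seconds, strictly increasing with constant step) and `voltage` (volts).
#' The sampling interval and a free-text label travel along as attributes,
#' but every function in the package recovers the interval from the `time`
#' column when the attribute has been stripped by data-frame surgery, so
#' ordinary dplyr pipelines on the columns are safe.
#'
#' @param time Numeric vector of sample times in seconds. Must be strictly
#'   increasing with a uniform step (relative jitter below 1e-9).
#' @param voltage Numeric vector of voltages in volts, same length as `time`.
#' @param label Free-text label describing the trace (e.g. the drive system).
#' @return A tibble of class `voltage_trace` with columns `time` and
#'   `voltage`.
#' @examples
#' tr <- voltage_trace(seq(0, 1, 0.01), sin(seq(0, 1, 0.01) * 2 * pi))
#' trace_dt(tr)
#' @export
voltage_trace <- function(time, voltage, label = "") {
  if (length(time) != length(voltage)) {
    stop("`time` and `voltage` must have the same length", call. = FALSE)
  }
  if (length(time) < 2) {
    stop("a voltage trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(time)) || !all(is.finite(voltage))) {
    bad <- which(!is.finite(voltage) | !is.finite(time))[1]
    stop("non-finite value in trace at row ", bad, call. = FALSE)
  }
  steps <- diff(time)
  dt <- steps[1]
  if (dt <= 0 || any(steps <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (max(abs(steps - dt)) >= 1e-9 * dt) {
    stop(
      "`time` is not uniformly sampled; resample to a fixed step before use",
      call. = FALSE
    )
  }
  new_voltage_trace(time, voltage, dt = dt, label = label)
}

new_voltage_trace <- function(time, voltage, dt, label = "") {
  tibble::new_tibble(
    list(time = as.double(time), voltage = as.double(voltage)),
    nrow = length(time),
    dt = dt, label = label,
    class = "voltage_trace"
  )
}

#' @rdname voltage_trace
#' @param x Object to convert or test.
#' @param ... Passed on to methods.
#' @export
as_voltage_trace <- function(x, ...) UseMethod("as_voltage_trace")

#' @export
as_voltage_trace.voltage_trace <- function(x, ...) x

#' @export
as_voltage_trace.data.frame <- function(x, label = "", ...) {
  cols <- intersect(c("time", "voltage"), names(x))
  if (length(cols) == 2) {
    voltage_trace(x$time, x$voltage, label = label)
  } else if (ncol(x) >= 2) {
    voltage_trace(x[[1]], x[[2]], label = label)
  } else {
    stop("need `time` and `voltage` columns", call. = FALSE)
  }
}

#' @rdname voltage_trace
#' @export
is_voltage_trace <- function(x) inherits(x, "voltage_trace")

#' @rdname voltage_trace
#' @export
trace_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) dt <- stats::median(diff(x$time))
  dt
}

#' @rdname voltage_trace
#' @export
trace_label <- function(x) {
  lab <- attr(x, "label")
  if (is.null(lab)) "" else lab
}

#' @rdname voltage_trace
#' @export
trace_duration <- function(x) {
  nrow(x) * trace_dt(x)
}

#' @exportS3Method pillar::tbl_sum
tbl_sum.voltage_trace <- function(x, ...) {
  c(
    "Voltage trace" = sprintf(
      "%d samples, dt = %g s%s", nrow(x), trace_dt(x),
      if (nzchar(trace_label(x))) paste0(", ", trace_label(x)) else ""
    )
  )
}

# internal: coerce + validate a trace argument
check_trace <- function(x, arg = "trace") {
  if (!is_voltage_trace(x)) x <- as_voltage_trace(x)
  x
}

#' Read and write voltage traces as CSV
#'
#' The on-disk dialect is a two-column CSV with header `time_s,voltage_V`,
#' UTF-8, `.` decimal separator. An optional first line starting with `#`
#' carries a JSON object of generator metadata which round-trips through the
#' trace's `"spec"` attribute. Unicode minus and en-dash signs (as printed in
#' instrument exports) are normalised to ASCII on read. Headerless
#' two-column TSV files are autodetected.
#'
#' @param trace A [voltage_trace()].
#' @param path File path.
#' @param spec Optional named list of metadata written as a `#`-prefixed JSON
#'   header line.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   [voltage_trace()].
#' @export
write_trace <- function(trace, path, spec = attr(trace, "spec")) {
  trace <- check_trace(trace)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(spec)) {
    writeLines(
      paste0("# ", jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA)),
      con
    )
  }
  writeLines("time_s,voltage_V", con)
  writeLines(
    paste(
      formatC(trace$time, format = "g", digits = 17),
      formatC(trace$voltage, format = "g", digits = 17),
      sep = ","
    ),
    con
  )
  invisible(path)
}

#' @rdname write_trace
#' @param label Label for the trace; defaults to the file name.
#' @export
read_trace <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty trace file: ", path, call. = FALSE)
  spec <- NULL
  offset <- 0
  if (startsWith(lines[1], "#")) {
    hdr <- sub("^#\\s*", "", lines[1])
    spec <- tryCatch(
      jsonlite::fromJSON(hdr, simplifyVector = TRUE),
      error = function(e) NULL
    )
    lines <- lines[-1]
    offset <- 1
  }
  # normalise unicode minus / en-dash to ASCII hyphen-minus
  lines <- gsub("−|–", "-", lines)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  has_header <- grepl("[A-Za-z]", lines[1])
  if (has_header) {
    lines <- lines[-1]
    offset <- offset + 1
  }
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, sep, fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    bad <- which(nfield < 2)[1]
    stop("malformed row at line ", bad + offset, " of ", path, call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(tm) || anyNA(v) || !all(is.finite(v))) {
    bad <- which(is.na(tm) | is.na(v) | !is.finite(v))[1]
    stop(
      "non-numeric or non-finite value at line ", bad + offset, " of ", path,
      call. = FALSE
    )
  }
  tr <- voltage_trace(tm, v, label = label)
  attr(tr, "spec") <- spec
  tr
}
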