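#' Uniformly sampled pressure trace
#'
#' A `pa_trace` is the unit of all signal processing in pafocus: one record
#' of the oscilloscope, i.e. a vector of pressure samples on a uniform time
#' grid `t0 + (0:(n-1)) * dt`.
#'
#' @param samples Numeric vector of pressure values (arbitrary units).
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `pa_trace`.
#' @examples
#' tr <- pa_trace(sin(seq(0, 1, length.out = 64)), dt = 5e-9)
#' trace_duration(tr)
#' @export
pa_trace <- function(samples, dt, t0 = 0) {
  samples <- as.double(samples)
  if (length(samples) < 1L || anyNA(samples)) {
    stop("'samples' must be a non-empty numeric vector without NA", call. = FALSE)
  }
  stop_if_not_scalar_pos(dt, "dt")
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  structure(list(samples = samples, dt = as.double(dt), t0 = as.double(t0)),
            class = "pa_trace")
}

#' @export
print.pa_trace <- function(x, ...) {
  cat(sprintf("<pa_trace> %d samples, dt = %.3g s, t0 = %.6g s, span [%.6g, %.6g] s\n",
              length(x$samples), x$dt, x$t0, x$t0,
              x$t0 + (length(x$samples) - 1) * x$dt))
  invisible(x)
}

#' @export
length.pa_trace <- function(x) length(x$samples)

#' Time axis of a trace
#' @param trace A [pa_trace].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "pa_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) * trace$dt
}

#' Duration of a trace
#' @param trace A [pa_trace].
#' @return Record duration `length * dt` in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "pa_trace"))
  length(trace$samples) * trace$dt
}

# Integer sample indices covered by a [start, end] time window.
# Arithmetic (no time-axis allocation): this sits on the optimizer's hot path.
window_index <- function(trace, window) {
  if (!(length(window) == 2L && window[1] < window[2])) {
    stop("'window' must be (start, end) with start < end", call. = FALSE)
  }
  n <- length(trace$samples)
  lo <- max(1L, as.integer(ceiling((window[1] - trace$t0) / trace$dt - 1e-9)) + 1L)
  hi <- min(n, as.integer(floor((window[2] - trace$t0) / trace$dt + 1e-9)) + 1L)
  if (hi - lo < 1L) {
    stop("time window does not cover at least two samples of the trace", call. = FALSE)
  }
  lo:hi
}

#' Read a trace from two-column delimited text
#'
#' The on-disk format is plain text: `#`-prefixed header lines carrying
#' `dt`, `t0` and optional free-form metadata, followed by two
#' whitespace-separated columns `time_s amplitude`. Round-trips through
#' [write_trace()] are lossless to better than 1e-12 relative.
#'
#' @param path Path to the trace file.
#' @return A [pa_trace].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- regmatches(hdr, regexec(paste0("^#\\s*", key, "\\s*=\\s*(\\S+)"), hdr))
    vals <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    as.double(vals[1])
  }
  dt <- get_field("dt")
  t0 <- get_field("t0")
  if (is.na(dt)) stop(sprintf("'%s': missing '# dt = ...' header line", path), call. = FALSE)
  if (is.na(t0)) t0 <- 0
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop(sprintf("'%s': no data rows", path), call. = FALSE)
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("'%s': malformed data row at line %d", path,
                 which(!grepl("^#", lines) & nzchar(trimws(lines)))[bad[1]]), call. = FALSE)
  }
  amp <- vapply(parts, function(p) as.double(p[2]), 0)
  if (anyNA(amp)) stop(sprintf("'%s': non-numeric amplitude value", path), call. = FALSE)
  pa_trace(amp, dt = dt, t0 = t0)
}

#' Write a trace to two-column delimited text
#'
#' @param trace A [pa_trace].
#' @param path Output path.
#' @param metadata Optional named character/numeric vector written as extra
#'   `# key = value` header lines (e.g. a seed).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, metadata = NULL) {
  stopifnot(inherits(trace, "pa_trace"))
  hdr <- c(sprintf("# dt = %.15g", trace$dt), sprintf("# t0 = %.15g", trace$t0))
  if (!is.null(metadata)) {
    hdr <- c(hdr, sprintf("# %s = %s", names(metadata), as.character(metadata)))
  }
  tt <- trace_time(trace)
  rows <- sprintf("%.15g\t%.15g", tt, trace$samples)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
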