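#' Construct a fluorescence / contraction trace
#'
#' A trace is a uniformly sampled time series from one optical channel:
#' action potential (`AP`), calcium (`Ca`), contraction (`Co`) or the
#' motion-artifact / membrane-label channel (`MA`). It is stored as a
#' tibble with columns `time_s` and `value`, carrying the sampling rate and
#' channel label as attributes.
#'
#' @param value Numeric vector of samples (at least 2).
#' @param fps Sampling rate in samples per second (> 0).
#' @param channel Channel label: `"AP"`, `"Ca"`, `"Co"` or `"MA"`.
#' @param t0 Time of the first sample in seconds.
#' @return A `ttm_trace` tibble.
#' @examples
#' tr <- ttm_trace(sin(seq(0, 2 * pi, length.out = 100)), fps = 100, channel = "Ca")
#' trace_fps(tr)
#' @export
ttm_trace <- function(value, fps, channel = c("AP", "Ca", "Co", "MA"),
                      t0 = 0) {
  channel <- match.arg(channel)
  value <- as.numeric(value)
  if (length(value) < 2) {
    .ttm_stop("A trace needs at least 2 samples.", "ttm_error_input")
  }
  if (!is.finite(fps) || fps <= 0) {
    .ttm_stop("Sampling rate must be a positive number.", "ttm_error_input")
  }
  out <- tibble(time_s = t0 + (seq_along(value) - 1) / fps, value = value)
  attr(out, "fps") <- fps
  attr(out, "channel") <- channel
  class(out) <- c("ttm_trace", class(out))
  out
}

#' @rdname ttm_trace
#' @param x A `ttm_trace`.
#' @export
trace_fps <- function(x) attr(x, "fps")

#' @rdname ttm_trace
#' @export
trace_channel <- function(x) attr(x, "channel")

# Rebuild a trace from an existing one with new sample values (and
# optionally a new channel), preserving rate and time origin.
retrace <- function(x, value, channel = trace_channel(x)) {
  ttm_trace(value, fps = trace_fps(x), channel = channel,
            t0 = x$time_s[1])
}

#' @export
print.ttm_trace <- function(x, ...) {
  cat(sprintf("<ttm_trace> channel=%s fps=%.4g n=%d duration=%.3fs\n",
              trace_channel(x), trace_fps(x), nrow(x),
              nrow(x) / trace_fps(x)))
  NextMethod()
}

#' Read and write trace CSV files
#'
#' Traces are exchanged as plain CSV with columns `time_s` and `value`,
#' preceded by comment header lines `# channel=` and `# fps=` so a file is
#' self-describing.
#'
#' @param x A `ttm_trace`.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` returns a `ttm_trace`.
#' @export
write_trace_csv <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    paste0("# channel=", trace_channel(x)),
    paste0("# fps=", format(trace_fps(x), digits = 15))
  ), con)
  readr::write_csv(as_tibble(x), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(ln) != 1) {
      .ttm_stop(paste0("Trace file lacks a '# ", key, "=' header: ", path),
                "ttm_error_schema")
    }
    sub(paste0("^#\\s*", key, "="), "", ln)
  }
  channel <- get_field("channel")
  fps <- as.numeric(get_field("fps"))
  tbl <- readr::read_csv(path, comment = "#",
                         col_types = readr::cols_only(
                           time_s = "d", value = "d"))
  ttm_trace(tbl$value, fps = fps, channel = channel, t0 = tbl$time_s[1])
}

#' Plot a trace
#'
#' @param object A `ttm_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ttm_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)",
                  title = paste0(trace_channel(object), " trace")) +
    ggplot2::theme_minimal()
}
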