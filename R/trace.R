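#' Uniformly sampled time series
#'
#' Light container for the traces the package passes around: stimulus
#' (contrast), calcium (c.u.), glutamate / release (v.u./s). A trace stores
#' its grid spacing \code{dt}, start time \code{t0}, values and a kind tag.
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @param dt Grid spacing [s], > 0.
#' @param t0 Time of the first sample [s].
#' @param kind One of "stimulus", "calcium", "glutamate", "release".
#' @return An object of class \code{syn_trace}.
#' @export
syn_trace <- function(values, dt, t0 = 0,
                      kind = c("stimulus", "calcium", "glutamate", "release")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 2) stop("syn_trace: need at least 2 samples")
  if (any(!is.finite(values))) stop("syn_trace: values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("syn_trace: dt must be > 0")
  structure(list(values = values, dt = dt, t0 = t0, kind = kind),
            class = "syn_trace")
}

#' @export
print.syn_trace <- function(x, ...) {
  cat(sprintf("<syn_trace: %s> %d samples, dt=%.6g s (%.4g Hz), t=[%.3g, %.3g] s\n",
              x$kind, length(x$values), x$dt, 1 / x$dt, x$t0,
              x$t0 + (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' @export
length.syn_trace <- function(x) length(x$values)

#' Time grid of a trace
#' @param x A \code{syn_trace}.
#' @return Numeric vector of sample times [s].
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "syn_trace"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
as.data.frame.syn_trace <- function(x, ...) {
  data.frame(time_s = trace_time(x), value = x$values)
}

# internal: same values, new container
trace_like <- function(x, values, kind = x$kind) {
  syn_trace(values, dt = x$dt, t0 = x$t0, kind = kind)
}

#' Resample a trace onto a new uniform grid by linear interpolation
#'
#' @param x A \code{syn_trace}.
#' @param dt New grid spacing [s].
#' @return A \code{syn_trace} on the new grid spanning the same interval.
#' @export
resample_trace <- function(x, dt) {
  stopifnot(inherits(x, "syn_trace"))
  tt <- trace_time(x)
  tnew <- seq(x$t0, tt[length(tt)], by = dt)
  syn_trace(stats::approx(tt, x$values, xout = tnew, rule = 2)$y,
            dt = dt, t0 = x$t0, kind = x$kind)
}

#' Read and write traces as two-column CSV with a JSON sidecar
#'
#' The CSV holds \code{time_s,value}; the sidecar \code{<path>.json} records
#' kind, dt and t0 so the uniform grid survives a round trip exactly.
#'
#' @param x A \code{syn_trace}.
#' @param path CSV path.
#' @return \code{read_trace_csv} returns the \code{syn_trace}.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "syn_trace"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(list(kind = x$kind, dt = x$dt, t0 = x$t0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    syn_trace(d$value, dt = meta$dt, t0 = meta$t0, kind = meta$kind)
  } else {
    dt <- stats::median(diff(d$time_s))
    syn_trace(d$value, dt = dt, t0 = d$time_s[1])
  }
}
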