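#' Double-exponential calcium kernel
#'
#' The low-pass stage of the light-to-calcium cascade:
#' \code{g(t) = exp(-t/tau_decay) - exp(-t/tau_rise)} for t >= 0, normalised
#' to unit area on the discrete grid. The rise constant is fixed at 30 ms;
#' the decay constant is the tunable calcium kinetics parameter. Support is
#' truncated at \code{8 * tau_decay}.
#'
#' @param tau_decay Decay constant [s], > 0.
#' @param dt Grid spacing [s].
#' @param tau_rise Rise constant [s]; default 0.030.
#' @return An object of class \code{syn_kernel}: list with \code{values}
#'   (samples at t = 0, dt, 2 dt, ...), \code{dt}, and metadata.
#' @export
make_double_exp_kernel <- function(tau_decay, dt, tau_rise = 0.030) {
  if (!is.finite(tau_decay) || tau_decay <= 0)
    stop("make_double_exp_kernel: tau_decay must be > 0")
  if (dt <= 0) stop("make_double_exp_kernel: dt must be > 0")
  t_max <- 8 * max(tau_decay, tau_rise)
  tt <- seq(0, t_max, by = dt)
  if (abs(tau_decay - tau_rise) < 1e-9 * tau_rise) {
    v <- tt * exp(-tt / tau_rise)   # alpha-function limit
  } else {
    v <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  }
  v <- pmax(v, 0)
  v <- v / (sum(v) * dt)
  structure(list(values = v, dt = dt, kind = "double_exponential",
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "syn_kernel")
}

#' Biphasic phototransduction kernel
#'
#' Band-pass front end of the cascade: a fast lobe minus a slower lobe, each
#' a gamma-shaped bump \code{t * exp(-t / tau)} normalised to unit area, so
#' the difference integrates to zero (no DC response). With the cone OFF
#' polarity (\code{sign = -1}, the default) a light decrement drives the
#' output up, so calcium rises at light offset.
#'
#' @param dt Grid spacing [s].
#' @param tau_fast,tau_slow Lobe time constants [s]; defaults 0.060 / 0.180.
#' @param amplitude Overall gain applied to the difference-of-lobes shape.
#' @param sign +1 or -1 output polarity; default -1 (OFF cone).
#' @return A \code{syn_kernel} with (discretely) zero net area.
#' @export
make_biphasic_kernel <- function(dt, tau_fast = 0.060, tau_slow = 0.180,
                                 amplitude = 1, sign = -1) {
  stopifnot(dt > 0, tau_fast > 0, tau_slow > tau_fast, sign %in% c(-1, 1))
  t_max <- 8 * tau_slow
  tt <- seq(0, t_max, by = dt)
  lobe <- function(tau) {
    g <- tt * exp(-tt / tau)
    g / (sum(g) * dt)
  }
  v <- sign * amplitude * (lobe(tau_fast) - lobe(tau_slow))
  structure(list(values = v, dt = dt, kind = "biphasic",
                 tau_fast = tau_fast, tau_slow = tau_slow,
                 amplitude = amplitude, sign = sign),
            class = "syn_kernel")
}

#' @export
print.syn_kernel <- function(x, ...) {
  cat(sprintf("<syn_kernel: %s> %d taps, dt=%.4g s, area=%.4g\n", x$kind,
              length(x$values), x$dt, sum(x$values) * x$dt))
  invisible(x)
}

# internal: causal discrete convolution y[n] = sum_k kernel[k] x[n-k] dt,
# zero-order hold; the input is padded on the left with its first value
# (steady pre-stimulus background), so output and input grids coincide.
convolve_causal <- function(x, kernel_values, dt) {
  nk <- length(kernel_values)
  xp <- c(rep(x[1], nk - 1), x)
  y <- stats::filter(xp, kernel_values, method = "convolution", sides = 1)
  as.numeric(y[nk:(nk + length(x) - 1)]) * dt
}

#' Linear-nonlinear light-to-calcium cascade
#'
#' Maps a contrast stimulus \code{s(t)} to a calcium trace via
#' \code{Ca(t) = kappa2 * exp(kappa1 * s(t))}: convolution with the biphasic
#' kernel \code{kappa1}, pointwise exponentiation, then convolution with the
#' double-exponential kernel \code{kappa2}. An optional affine output stage
#' sets the arbitrary c.u. scale: with \code{range} given, the result is
#' rescaled so its min/max span that interval; otherwise
#' \code{gain * Ca + offset} is returned.
#'
#' @param stimulus A \code{\link{syn_trace}} (kind "stimulus").
#' @param kappa1 Biphasic \code{syn_kernel} on the stimulus grid.
#' @param kappa2 Double-exponential \code{syn_kernel} on the stimulus grid.
#' @param gain,offset Affine output stage (ignored when \code{range} given).
#' @param range Optional length-2 target range, e.g. \code{c(0, 1)}.
#' @return A \code{syn_trace} of kind "calcium" on the stimulus grid.
#' @export
light_to_calcium <- function(stimulus, kappa1, kappa2, gain = 1, offset = 0,
                             range = NULL) {
  stopifnot(inherits(stimulus, "syn_trace"), inherits(kappa1, "syn_kernel"),
            inherits(kappa2, "syn_kernel"))
  if (abs(kappa1$dt - stimulus$dt) > 1e-12 ||
      abs(kappa2$dt - stimulus$dt) > 1e-12)
    stop("light_to_calcium: kernel dt must match the stimulus grid")
  drive <- convolve_causal(stimulus$values, kappa1$values, stimulus$dt)
  ca <- convolve_causal(exp(drive), kappa2$values, stimulus$dt)
  if (!is.null(range)) {
    lo <- min(ca); hi <- max(ca)
    if (hi - lo < .Machine$double.eps)
      stop("light_to_calcium: flat response, cannot rescale to range")
    ca <- (ca - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
  } else {
    ca <- gain * ca + offset
  }
  trace_like(stimulus, ca, kind = "calcium")
}
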