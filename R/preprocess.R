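#' Remove a linear baseline drift
#'
#' Fits an ordinary least-squares line to the whole trace and subtracts the
#' trend while preserving the mean (slow photobleaching of the calcium
#' indicator shows up as a linear baseline decay).
#'
#' @param trace A \code{\link{syn_trace}} with at least 10 samples.
#' @return The detrended \code{syn_trace}.
#' @export
baseline_correct_linear <- function(trace) {
  stopifnot(inherits(trace, "syn_trace"))
  x <- trace$values
  if (length(x) < 10) stop("baseline_correct_linear: need >= 10 samples")
  if (stats::sd(x) == 0) return(trace)
  tt <- trace_time(trace)
  b <- stats::cov(tt, x) / stats::var(tt)
  trace_like(trace, x - b * (tt - mean(tt)))
}

#' Rescale a trace by z-scoring against bright-interval statistics
#'
#' During UV-bright stimulation the (UV-sensitive OFF) cone's calcium
#' channels are closed, so fluctuations within those intervals reflect
#' recording plus vesicle noise. Z-scoring every trace against the mean and
#' standard deviation of its own bright intervals puts recordings with
#' different indicator expression on one common scale.
#'
#' @param trace A \code{\link{syn_trace}}.
#' @param bright_intervals Two-column matrix of [start, end) times [s],
#'   one row per bright interval.
#' @return The standardised \code{syn_trace}: bright-sample mean 0, sd 1.
#' @export
zscore_to_bright <- function(trace, bright_intervals) {
  stopifnot(inherits(trace, "syn_trace"))
  m <- interval_mask(trace, bright_intervals)
  if (sum(m) < 20) stop("zscore_to_bright: need >= 20 bright samples")
  mu <- mean(trace$values[m])
  sg <- stats::sd(trace$values[m])
  if (sg == 0) stop("zscore_to_bright: zero variance in bright intervals (flat recording)")
  trace_like(trace, (trace$values - mu) / sg)
}

# internal: logical mask of samples falling in any [start, end) interval
interval_mask <- function(trace, intervals) {
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  tt <- trace_time(trace)
  m <- rep(FALSE, length(tt))
  for (r in seq_len(nrow(intervals)))
    m <- m | (tt >= intervals[r, 1] & tt < intervals[r, 2])
  m
}

#' Low-pass denoise with a zero-phase Butterworth filter
#'
#' Order-3 Butterworth, applied forward and backward (\code{signal::filtfilt})
#' so no phase lag is introduced between the paired calcium and glutamate
#' traces; the price is a squared magnitude response (about -6 dB at the
#' nominal cutoff instead of -3 dB).
#'
#' @param trace A \code{\link{syn_trace}}.
#' @param cutoff_hz Cutoff frequency [Hz]; must be below Nyquist.
#' @param order Filter order of each pass; default 3.
#' @return The filtered \code{syn_trace}.
#' @export
denoise_butterworth <- function(trace, cutoff_hz = 5, order = 3) {
  stopifnot(inherits(trace, "syn_trace"))
  fs <- 1 / trace$dt
  if (cutoff_hz >= fs / 2)
    stop("denoise_butterworth: cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of filtfilt
  x <- trace$values
  np <- min(length(x) - 1, max(12L, round(8 * fs / cutoff_hz)))
  left <- 2 * x[1] - x[(np + 1):2]
  right <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  trace_like(trace, y[(np + 1):(np + length(x))])
}

#' Single-exponential indicator impulse response
#'
#' Default kernel ascribed to the red calcium indicator (jRGeco-type): a
#' unit-area exponential decay with time constant \code{tau}, truncated at
#' \code{8 tau}. The true indicator kernel is not pinned down by the
#' recordings themselves; the time constant is exposed so a measured kernel
#' can be substituted.
#'
#' @param tau Decay time constant [s].
#' @param dt Grid spacing [s].
#' @return A \code{syn_kernel}.
#' @export
make_indicator_kernel <- function(tau, dt) {
  stopifnot(tau > 0, dt > 0)
  tt <- seq(0, 8 * tau, by = dt)
  v <- exp(-tt / tau)
  v <- v / (sum(v) * dt)
  structure(list(values = v, dt = dt, kind = "indicator", tau = tau),
            class = "syn_kernel")
}

#' Wiener deconvolution of the indicator kernel
#'
#' Undoes the temporal blur of the fluorescent indicator in the frequency
#' domain with the Wiener filter \code{G = conj(H) / (|H|^2 + 1/SNR(f))},
#' where \code{H} is the kernel transfer function and the signal-to-noise
#' profile is piecewise constant: \code{snr_low} below \code{f_break} and
#' \code{snr_high} above it. Pass \code{snr_low = snr_high = Inf} for exact
#' inverse filtering of noiseless data.
#'
#' @param trace A \code{\link{syn_trace}} (indicator-space fluorescence).
#' @param kernel Unit-area \code{syn_kernel} on the trace grid.
#' @param snr_low,snr_high SNR below/above the crossover; defaults 10 and
#'   1/20.
#' @param f_break Crossover frequency [Hz]; default 1.
#' @return The deconvolved \code{syn_trace} (kind "calcium").
#' @export
wiener_deconvolve_indicator <- function(trace, kernel, snr_low = 10,
                                        snr_high = 1 / 20, f_break = 1) {
  stopifnot(inherits(trace, "syn_trace"), inherits(kernel, "syn_kernel"))
  if (all(kernel$values == 0)) stop("wiener_deconvolve_indicator: kernel is all zeros")
  if (abs(kernel$dt - trace$dt) > 1e-12)
    stop("wiener_deconvolve_indicator: kernel dt must match the trace grid")
  n <- length(trace$values)
  if (n < length(kernel$values))
    stop("wiener_deconvolve_indicator: trace shorter than kernel support")
  nfft <- stats::nextn(n + length(kernel$values), 2)
  H <- stats::fft(c(kernel$values * kernel$dt, rep(0, nfft - length(kernel$values))))
  f <- (seq_len(nfft) - 1) / (nfft * trace$dt)
  f <- pmin(f, 1 / trace$dt - f)  # two-sided frequency magnitude
  snr <- ifelse(f < f_break, snr_low, snr_high)
  denom <- Mod(H)^2 + 1 / snr
  G <- Conj(H) / denom
  if (any(!is.finite(G))) stop("wiener_deconvolve_indicator: singular filter")
  Y <- stats::fft(c(trace$values, rep(0, nfft - n)))
  x <- Re(stats::fft(G * Y, inverse = TRUE)) / nfft
  trace_like(trace, x[seq_len(n)], kind = "calcium")
}

#' Shift a trace so its minimum is zero
#'
#' The model's output is a non-negative release rate; the processed glutamate
#' trace is shifted by its minimum so the target lives on the same half-line.
#'
#' @param trace A \code{\link{syn_trace}}.
#' @return The shifted \code{syn_trace} with \code{min == 0}.
#' @export
shift_nonnegative <- function(trace) {
  stopifnot(inherits(trace, "syn_trace"))
  trace_like(trace, trace$values - min(trace$values))
}

# internal: fit c + a * exp(-t/tau) by variable projection -- for each tau the
# remaining (c, a) problem is linear; tau is found on a log grid then refined
# by golden-section search. Deterministic, no start values needed.
expfit_varpro <- function(tt, yy, tau_grid = NULL) {
  tt <- tt - tt[1]
  if (is.null(tau_grid)) {
    span <- max(tt[length(tt)], .Machine$double.eps)
    tau_grid <- exp(seq(log(span / 50), log(span * 20), length.out = 30))
  }
  rss_ca <- function(tau) {
    b <- exp(-tt / tau)
    X <- cbind(1, b)
    fit <- stats::lm.fit(X, yy)
    list(rss = sum(fit$residuals^2), c = fit$coefficients[1],
         a = fit$coefficients[2])
  }
  rss <- vapply(tau_grid, function(tau) rss_ca(tau)$rss, numeric(1))
  j <- which.min(rss)
  lo <- tau_grid[max(1, j - 1)]; hi <- tau_grid[min(length(tau_grid), j + 1)]
  opt <- stats::optimize(function(ltau) rss_ca(exp(ltau))$rss,
                         c(log(lo), log(hi)), tol = 1e-8)
  tau <- exp(opt$minimum)
  cf <- rss_ca(tau)
  list(c = unname(cf$c), a = unname(cf$a), tau = tau, rss = cf$rss)
}

#' Quantify rise and decay kinetics of a calcium event
#'
#' Smooths the trace with a 100 ms sliding average, fits
#' \code{c + a exp(-t/tau)} separately to the rise (window start to peak) and
#' decay (peak to window end) segments, and reports the response delay as the
#' first time the smoothed trace exceeds three standard deviations of the
#' trace.
#'
#' @param trace A \code{\link{syn_trace}} (z-scored calcium).
#' @param event_window Length-2 numeric, [start, end] time [s] of the event.
#' @return List with \code{rise} and \code{decay} fits (each \code{c},
#'   \code{a}, \code{tau}, \code{rss}, \code{is_rise}), and \code{delay} [s]
#'   (NA with \code{delay_defined = FALSE} if the 3-sd threshold is never
#'   crossed).
#' @export
fit_rise_decay <- function(trace, event_window) {
  stopifnot(inherits(trace, "syn_trace"), length(event_window) == 2)
  w <- max(1L, round(0.1 / trace$dt))
  sm <- as.numeric(stats::filter(trace$values, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- trace$values[is.na(sm)]
  tt <- trace_time(trace)
  thr <- 3 * stats::sd(trace$values)
  idx <- which(tt >= event_window[1] & tt <= event_window[2])
  if (length(idx) < 8) stop("fit_rise_decay: event window too short")
  seg_t <- tt[idx]; seg <- sm[idx]
  pk <- which.max(seg)
  fit_seg <- function(i0, i1) {
    f <- expfit_varpro(seg_t[i0:i1], seg[i0:i1])
    f$is_rise <- f$a < 0   # c + a exp(-t/tau) rises when a < 0
    f
  }
  rise <- if (pk >= 4) fit_seg(1, pk) else NULL
  decay <- if (pk <= length(seg) - 3) fit_seg(pk, length(seg)) else NULL
  cross <- which(sm > thr & tt >= event_window[1])
  delay_defined <- length(cross) > 0
  list(rise = rise, decay = decay,
       delay = if (delay_defined) tt[cross[1]] - event_window[1] else NA_real_,
       delay_defined = delay_defined)
}

#' Full preprocessing chain for a synthetic or recorded trace pair
#'
#' Applies, in order: linear baseline correction (calcium only), bright-
#' interval z-scoring (both), zero-phase Butterworth denoising (both), Wiener
#' deconvolution of the calcium indicator kernel, a min-shift of the
#' glutamate trace to non-negative values, and resampling of both traces to a
#' common uniform model grid.
#'
#' @param calcium_f,glutamate_f Raw fluorescence \code{\link{syn_trace}}s on
#'   the acquisition grid.
#' @param annotations Protocol annotations as returned by
#'   \code{\link{make_flash_protocol}} (bright intervals are used).
#' @param indicator_tau Calcium indicator decay constant [s]; default 0.25.
#' @param cutoff_hz Butterworth cutoff [Hz]; default 5.
#' @param model_dt Target grid spacing [s]; default 0.01 (100 Hz).
#' @param snr_low,snr_high Wiener SNR profile; see
#'   \code{\link{wiener_deconvolve_indicator}}.
#' @return List with \code{calcium} (deconvolved input trace, model grid) and
#'   \code{glutamate} (non-negative target trace, model grid).
#' @export
preprocess_recording <- function(calcium_f, glutamate_f, annotations,
                                 indicator_tau = 0.25, cutoff_hz = 5,
                                 model_dt = 0.01, snr_low = 10,
                                 snr_high = 1 / 20) {
  bright <- annotations$bright
  ca <- baseline_correct_linear(calcium_f)
  ca <- zscore_to_bright(ca, bright)
  glu <- zscore_to_bright(glutamate_f, bright)
  ca <- denoise_butterworth(ca, cutoff_hz)
  glu <- denoise_butterworth(glu, cutoff_hz)
  kern <- make_indicator_kernel(indicator_tau, ca$dt)
  ca <- wiener_deconvolve_indicator(ca, kern, snr_low, snr_high)
  glu <- shift_nonnegative(glu)
  list(calcium = resample_trace(ca, model_dt),
       glutamate = {
         g <- resample_trace(glu, model_dt)
         g$kind <- "glutamate"
         g
       })
}
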