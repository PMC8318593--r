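#' Maximal activation, sustain and transience of flash responses
#'
#' For each dark period of the flash protocol, the maximal activation is the
#' 90th percentile of the trace over the first second after dark onset and
#' the sustained level is the 50th percentile over the last second of the
#' dark period (percentiles, not extrema, to be robust to noise). The
#' transience index is \code{(max - sustain)/max}: 0 for a fully sustained
#' response, approaching 1 for a fully transient one.
#'
#' @param trace A \code{\link{syn_trace}} (release or z-scored recording).
#' @param dark_onsets Numeric vector of dark-period onset times [s].
#' @param dark_duration Dark-period length [s]; default 3.
#' @return A data.frame with one row per dark period (\code{max},
#'   \code{sustain}, \code{transience}, \code{defined}) plus attributes
#'   \code{first} (first flash) and \code{mean_later} (mean over subsequent
#'   flashes). \code{transience} is NA (flagged) where \code{max <= 0}.
#' @export
max_sustain_transience <- function(trace, dark_onsets, dark_duration = 3) {
  stopifnot(inherits(trace, "syn_trace"))
  tt <- trace_time(trace)
  rows <- lapply(dark_onsets, function(t0) {
    i_max <- tt >= t0 & tt < t0 + 1
    i_sus <- tt >= t0 + dark_duration - 1 & tt < t0 + dark_duration
    if (!any(i_max) || !any(i_sus))
      stop("max_sustain_transience: window outside the trace")
    mx <- unname(stats::quantile(trace$values[i_max], 0.9))
    su <- unname(stats::quantile(trace$values[i_sus], 0.5))
    data.frame(max = mx, sustain = su,
               transience = if (mx > 0) (mx - su) / mx else NA_real_,
               defined = mx > 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "first") <- out[1, , drop = FALSE]
  if (nrow(out) > 1)
    attr(out, "mean_later") <- colMeans(out[-1, c("max", "sustain",
                                                  "transience")])
  out
}

# internal: piecewise-constant (zero-order hold) noise stimulus on a fine grid
zoh_noise_stimulus <- function(duration, update_hz, dt, draw_fn) {
  n_steps <- ceiling(duration * update_hz)
  levels <- draw_fn(n_steps)
  tt <- seq(0, duration - dt / 2, by = dt)
  idx <- pmin(floor(tt * update_hz) + 1, n_steps)
  syn_trace(levels[idx], dt = dt, t0 = 0, kind = "stimulus")
}

# internal: run the full light -> calcium -> release cascade for a stimulus
simulate_cascade <- function(stimulus, params, tau_decay = 0.3,
                             ca_range = c(0, 1)) {
  k1 <- make_biphasic_kernel(stimulus$dt)
  k2 <- make_double_exp_kernel(tau_decay, stimulus$dt)
  ca <- light_to_calcium(stimulus, k1, k2, range = ca_range)
  simulate_release(params, ca)
}

#' Off- and on-event detection indices
#'
#' Probes how well a synapse configuration signals a brief contrast event
#' buried in noise. The stimulus is 150 s of Gaussian noise (mean 0.5, sd
#' 0.3) updated at 2 Hz; after 120 s a 500 ms event of amplitude plus or
#' minus four noise standard deviations is inserted. The off index is
#' \code{(max(x) - mean(x)) / sd(x)} of the release over [60 s, 150 s] for
#' the dark (-4 sd) event; the on index is \code{|min(x) - mean(x)| / sd(x)}
#' for the bright (+4 sd) event.
#'
#' @param params A \code{\link{ribbon_params}} object.
#' @param tau_decay Calcium kernel decay constant [s].
#' @param seed Integer seed for the stimulus realisation.
#' @param dt Simulation grid [s]; default 0.01.
#' @param n_reps Number of stimulus realisations to average (default 1, as a
#'   single realisation per seed).
#' @return List with \code{I_off}, \code{I_on} and \code{defined} (FALSE when
#'   the output variance vanishes, e.g. a zero-release synapse).
#' @export
detection_indices <- function(params, tau_decay = 0.3, seed = 1, dt = 0.01,
                              n_reps = 1) {
  run_one <- function(rep_seed) {
    set.seed(rep_seed)
    base <- zoh_noise_stimulus(150, 2, dt, function(n) stats::rnorm(n, 0.5, 0.3))
    event_idx <- which(trace_time(base) >= 120 & trace_time(base) < 120.5)
    res <- lapply(c(off = -1, on = +1), function(sgn) {
      stim <- base
      stim$values[event_idx] <- stim$values[event_idx] + sgn * 4 * 0.3
      traj <- simulate_cascade(stim, params, tau_decay)
      x <- traj$e[trace_time(traj$release) >= 60]
      sdx <- stats::sd(x)
      if (sdx < 1e-12) return(c(NA_real_, FALSE))
      val <- if (sgn < 0) (max(x) - mean(x)) / sdx else abs(min(x) - mean(x)) / sdx
      c(val, TRUE)
    })
    list(I_off = res$off[1], I_on = res$on[1],
         defined = res$off[2] > 0 && res$on[2] > 0)
  }
  runs <- lapply(seed + seq_len(n_reps) - 1, run_one)
  list(I_off = mean(vapply(runs, `[[`, numeric(1), "I_off")),
       I_on = mean(vapply(runs, `[[`, numeric(1), "I_on")),
       defined = all(vapply(runs, `[[`, logical(1), "defined")))
}

#' Welch power spectral density estimate
#'
#' Splits the series into overlapping Hann-windowed segments, averages the
#' segment periodograms, and returns a one-sided density estimate.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate [Hz].
#' @param seg_len Segment length [s]; default 10.
#' @param overlap Fractional overlap; default 0.5.
#' @return List with \code{freq} [Hz] and \code{power} (density, one-sided).
#' @export
welch_psd <- function(x, fs, seg_len = 10, overlap = 0.5) {
  nper <- round(seg_len * fs)
  if (length(x) < nper)
    stop("welch_psd: series shorter than one Welch segment")
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hann
  U <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2 / (U * fs)
  }
  p <- acc / length(starts)
  nh <- floor(nper / 2) + 1
  p1 <- p[seq_len(nh)]
  p1[2:(nh - 1)] <- 2 * p1[2:(nh - 1)]   # fold negative frequencies
  list(freq = (seq_len(nh) - 1) * fs / nper, power = p1)
}

#' High-frequency index of the synaptic transfer
#'
#' Drives the cascade with 100 s of uniform noise updated at 20 Hz,
#' normalises the release output to unit standard deviation, estimates its
#' power spectrum with Welch's method, and sums \code{power * frequency}
#' over all frequencies below 25 Hz. Larger values mean the synapse passes
#' more of its output power at high frequencies.
#'
#' @inheritParams detection_indices
#' @return List with \code{HFi} and \code{defined}.
#' @export
high_frequency_index <- function(params, tau_decay = 0.3, seed = 1,
                                 dt = 0.01) {
  set.seed(seed)
  stim <- zoh_noise_stimulus(100, 20, dt, function(n) stats::runif(n))
  traj <- simulate_cascade(stim, params, tau_decay)
  x <- traj$e
  sdx <- stats::sd(x)
  if (sdx < 1e-12) return(list(HFi = NA_real_, defined = FALSE))
  ps <- welch_psd((x - mean(x)) / sdx, fs = 1 / dt)
  keep <- ps$freq < 25
  list(HFi = sum(ps$power[keep] * ps$freq[keep]), defined = TRUE)
}
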