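#' Flash stimulus protocol with interval annotations
#'
#' The standard recording protocol: an adaptation period at 50% contrast,
#' followed by repeated full-contrast UV flashes of 3 s light ON then 3 s
#' light OFF (dark). Release in the OFF cone rises during the dark periods.
#'
#' @param n_flashes Number of ON/OFF flash pairs; default 3.
#' @param dt Grid spacing [s]; default 0.01.
#' @param adaptation Adaptation length [s]; default 5.
#' @param on_s,off_s Bright / dark segment lengths [s]; defaults 3 and 3.
#' @param contrasts Stimulus levels \code{c(adapt, bright, dark)}; default
#'   \code{c(0.5, 1, 0)}.
#' @return List with \code{stimulus} (a \code{\link{syn_trace}}) and
#'   \code{annotations}: matrices \code{adaptation}, \code{bright},
#'   \code{dark} of [start, end) times, plus \code{dark_onsets}.
#' @examples
#' p <- make_flash_protocol(3)
#' p$annotations$dark_onsets   # 8, 14, 20 s
#' @export
make_flash_protocol <- function(n_flashes = 3, dt = 0.01, adaptation = 5,
                                on_s = 3, off_s = 3,
                                contrasts = c(0.5, 1, 0)) {
  stopifnot(n_flashes >= 1)
  total <- adaptation + n_flashes * (on_s + off_s)
  tt <- seq(0, total - dt / 2, by = dt)
  v <- rep(contrasts[1], length(tt))
  bright <- dark <- matrix(NA_real_, n_flashes, 2)
  for (j in seq_len(n_flashes)) {
    b0 <- adaptation + (j - 1) * (on_s + off_s)
    bright[j, ] <- c(b0, b0 + on_s)
    dark[j, ] <- c(b0 + on_s, b0 + on_s + off_s)
    v[tt >= bright[j, 1] & tt < bright[j, 2]] <- contrasts[2]
    v[tt >= dark[j, 1] & tt < dark[j, 2]] <- contrasts[3]
  }
  list(stimulus = syn_trace(v, dt = dt, t0 = 0, kind = "stimulus"),
       annotations = list(adaptation = matrix(c(0, adaptation), 1),
                          bright = bright, dark = dark,
                          dark_onsets = dark[, 1], duration = total))
}

#' Preset synapse configurations for three eye regions
#'
#' Illustrative parameter bundles emulating the qualitative regional tuning
#' of larval zebrafish UV cones: the acute zone ("az") with the largest
#' readily releasable pool, the nasal region with the smallest RRP but
#' strong refill (sustained signalling), and the dorsal region tuned to be
#' the most transient. These are design presets for synthetic studies, not
#' fitted values.
#'
#' @param zone One of "az", "nasal", "dorsal".
#' @return A \code{\link{simplified_params}} object.
#' @export
zone_preset <- function(zone = c("az", "nasal", "dorsal")) {
  zone <- match.arg(zone)
  switch(zone,
    az     = simplified_params(IP_max = 14, RRP_max = 6, e_tilde_max = 0.55,
                               x0 = 0.50, tau_decay = 0.30),
    nasal  = simplified_params(IP_max = 20, RRP_max = 2, e_tilde_max = 0.35,
                               x0 = 0.40, tau_decay = 0.30),
    dorsal = simplified_params(IP_max = 8, RRP_max = 4, e_tilde_max = 0.95,
                               x0 = 0.60, tau_decay = 0.30))
}

#' Define a synthetic recording study
#'
#' Fixes the stimulus protocol, ground-truth kinetic parameters and the
#' observation model (indicator kernels, noise, drift, affine scale) for a
#' batch of reproducible synthetic recordings.
#'
#' @param params Ground-truth \code{\link{ribbon_params}} (or a
#'   \code{simplified_params}, expanded automatically).
#' @param n_flashes Flashes in the protocol; default 3.
#' @param dt Model grid [s]; default 0.01.
#' @param tau_decay Calcium kernel decay [s]; default 0.3.
#' @param fs_acq Acquisition sampling rate [Hz]; default 15.6.
#' @param noise_sd Additive white Gaussian noise sd in fluorescence units;
#'   default 0.1.
#' @param drift_slope Linear baseline drift [fluorescence units/s]; default
#'   -0.01 (slow bleaching).
#' @param ca_scale,ca_offset,glu_scale,glu_offset Affine observation stages.
#' @param ca_indicator_tau,glu_indicator_tau Indicator decay constants [s];
#'   defaults 0.25 (red calcium indicator) and 0.06 (glutamate indicator).
#' @return An object of class \code{synthetic_study}.
#' @export
synthetic_study <- function(params, n_flashes = 3, dt = 0.01,
                            tau_decay = 0.3, fs_acq = 15.6, noise_sd = 0.1,
                            drift_slope = -0.01, ca_scale = 1.5,
                            ca_offset = 2, glu_scale = 0.8, glu_offset = 1,
                            ca_indicator_tau = 0.25,
                            glu_indicator_tau = 0.06) {
  if (inherits(params, "simplified_params")) params <- expand_simplified(params)
  stopifnot(inherits(params, "ribbon_params"))
  if (noise_sd < 0) stop("synthetic_study: noise_sd must be >= 0")
  structure(list(params = params, n_flashes = n_flashes, dt = dt,
                 tau_decay = tau_decay, fs_acq = fs_acq, noise_sd = noise_sd,
                 drift_slope = drift_slope, ca_scale = ca_scale,
                 ca_offset = ca_offset, glu_scale = glu_scale,
                 glu_offset = glu_offset,
                 ca_indicator_tau = ca_indicator_tau,
                 glu_indicator_tau = glu_indicator_tau),
            class = "synthetic_study")
}

#' Generate one synthetic dual-colour recording
#'
#' Composes the forward model: flash stimulus -> light-to-calcium cascade
#' (ground-truth calcium) -> pool-cascade simulation (ground-truth release)
#' -> observation stage per channel (indicator-kernel convolution, affine
#' scale/offset, linear drift, additive white Gaussian noise, resampling to
#' the acquisition rate). The ground truth is returned losslessly alongside
#' the noisy fluorescence.
#'
#' @param study A \code{\link{synthetic_study}}.
#' @param seed Integer seed; together with the study config it fully
#'   determines the output.
#' @return List with \code{stimulus}, \code{annotations}, \code{truth}
#'   (calcium, release, trajectory, params), and \code{observed}
#'   (calcium_f, glutamate_f fluorescence traces at the acquisition rate).
#' @export
generate_recording <- function(study, seed = 1) {
  stopifnot(inherits(study, "synthetic_study"))
  proto <- make_flash_protocol(study$n_flashes, dt = study$dt)
  k1 <- make_biphasic_kernel(study$dt)
  k2 <- make_double_exp_kernel(study$tau_decay, study$dt)
  ca <- light_to_calcium(proto$stimulus, k1, k2, range = c(0, 1))
  traj <- simulate_release(study$params, ca)
  set.seed(seed)
  observe <- function(signal, kernel_tau, scale, offset) {
    kern <- make_indicator_kernel(kernel_tau, study$dt)
    f <- convolve_causal(signal$values, kern$values, study$dt)
    f <- scale * f + offset + study$drift_slope * trace_time(signal)
    obs <- syn_trace(f, dt = study$dt, t0 = 0, kind = signal$kind)
    obs <- resample_trace(obs, 1 / study$fs_acq)
    obs$values <- obs$values + stats::rnorm(length(obs$values), 0,
                                            study$noise_sd)
    obs
  }
  list(stimulus = proto$stimulus, annotations = proto$annotations,
       truth = list(calcium = ca, release = traj$release, trajectory = traj,
                    params = study$params),
       observed = list(calcium_f = observe(ca, study$ca_indicator_tau,
                                           study$ca_scale, study$ca_offset),
                       glutamate_f = observe(traj$release,
                                             study$glu_indicator_tau,
                                             study$glu_scale,
                                             study$glu_offset)),
       seed = seed)
}
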