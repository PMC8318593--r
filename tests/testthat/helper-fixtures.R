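# Shared fixtures, all built in code.

default_params <- function() {
  ribbon_params(r_max = 2.5, i_max = 2.5, e_max = 10, k = 14, x0 = 0.5,
                IP_max = 13.8, RRP_max = 4)
}

# flash protocol plus its calcium input on the standard 100 Hz model grid
flash_fixture <- function(n_flashes = 3, tau_decay = 0.3) {
  proto <- make_flash_protocol(n_flashes)
  ca <- light_to_calcium(proto$stimulus,
                         make_biphasic_kernel(proto$stimulus$dt),
                         make_double_exp_kernel(tau_decay, proto$stimulus$dt),
                         range = c(0, 1))
  list(proto = proto, calcium = ca)
}

# study conditions for the parameter-recovery experiments: a known ground
# truth off the prior modes, 20 noisy trials at 5% peak observation noise,
# the trial average as the target (as recordings are trial-averaged before
# fitting) and feature normalisation across the trials
recovery_target <- function(fix, theta_star, n_trials = 20,
                            noise_frac = 0.05, seed = 99) {
  pstar <- draw_to_params(theta_star)
  rel <- simulate_release(pstar, fix$calcium)$release
  set.seed(seed)
  noise_sd <- noise_frac * max(rel$values)
  trials <- lapply(seq_len(n_trials), function(r)
    pmax(rel$values + stats::rnorm(length(rel$values), 0, noise_sd), 0))
  reps <- t(sapply(trials, function(v)
    extract_features(syn_trace(v, dt = rel$dt, kind = "release"),
                     fix$proto$annotations)))
  avg <- syn_trace(Reduce(`+`, trials) / n_trials, dt = rel$dt,
                   kind = "release")
  list(params = pstar, release = rel, average = avg,
       target = extract_features(avg, fix$proto$annotations),
       normalisation = feature_normalisation(reps))
}

# independent fixed-step forward-Euler integration of the cascade, plain R
euler_release <- function(params, calcium, y0, dt_euler = 1e-4) {
  tfine <- seq(calcium$t0, max(trace_time(calcium)), by = dt_euler)
  cafine <- stats::approx(trace_time(calcium), calcium$values,
                          xout = tfine)$y
  RP <- y0[1]; IP <- y0[2]; RRP <- y0[3]; Exo <- y0[4]
  e_out <- numeric(length(tfine))
  for (ii in seq_along(tfine)) {
    f <- 1 / (1 + exp(-params$k * (cafine[ii] - params$x0)))
    r <- params$r_max * (1 - IP / params$IP_max) * RP / params$RP_max
    i <- params$i_max * (1 - RRP / params$RRP_max) * IP / params$IP_max
    e <- params$e_max * f * RRP / params$RRP_max
    d <- params$d_max * Exo
    e_out[ii] <- e
    RP <- RP + dt_euler * (d - r); IP <- IP + dt_euler * (r - i)
    RRP <- RRP + dt_euler * (i - e); Exo <- Exo + dt_euler * (e - d)
  }
  list(time = tfine, e = e_out)
}
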