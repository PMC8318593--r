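test_that("linear baseline correction removes exactly a linear trend", {
  tt <- seq(0, 39.95, by = 0.05)   # whole number of 0.5 Hz periods
  line <- syn_trace(2 + 0.05 * tt, dt = 0.05)
  out <- baseline_correct_linear(line)
  expect_equal(out$values, rep(mean(line$values), length(tt)), tolerance = 1e-9)
  set.seed(1)
  sig <- sin(2 * pi * 0.5 * tt) + rnorm(length(tt), 0, 0.02)
  drifted <- syn_trace(sig + 0.01 * tt, dt = 0.05)
  rec <- baseline_correct_linear(drifted)
  expect_gt(stats::cor(rec$values, sig), 0.999)
  expect_equal(mean(rec$values), mean(drifted$values))  # mean preserved
  # idempotent on drift-free input
  clean <- baseline_correct_linear(syn_trace(sig, dt = 0.05))
  expect_equal(baseline_correct_linear(clean)$values, clean$values,
               tolerance = 1e-12)
})

test_that("bright-interval z-scoring standardises exactly and is affine invariant", {
  set.seed(2)
  tr <- syn_trace(rnorm(500, 3, 2), dt = 0.064)
  bright <- rbind(c(5, 10), c(15, 20))
  z <- zscore_to_bright(tr, bright)
  m <- trace_time(z) >= 5 & trace_time(z) < 10 |
    trace_time(z) >= 15 & trace_time(z) < 20
  expect_lt(abs(mean(z$values[m])), 1e-9)
  expect_lt(abs(stats::sd(z$values[m]) - 1), 1e-9)
  # z-scoring an affine-transformed copy gives the same output
  tr2 <- syn_trace(4.2 * tr$values - 7, dt = 0.064)
  expect_equal(zscore_to_bright(tr2, bright)$values, z$values,
               tolerance = 1e-9)
  # already standardised input is unchanged
  expect_equal(zscore_to_bright(z, bright)$values, z$values, tolerance = 1e-9)
  expect_error(zscore_to_bright(syn_trace(rep(1, 500), dt = 0.064), bright),
               "flat")
})

test_that("Butterworth denoising passes the band and rejects above cutoff", {
  fs <- 100; tt <- seq(0, 20, by = 1 / fs)
  s1 <- syn_trace(sin(2 * pi * 1 * tt), dt = 1 / fs)
  out1 <- denoise_butterworth(s1, 5)
  mid <- 500:1500
  att1 <- max(abs(out1$values[mid])) / 1
  expect_gt(att1, 0.98)   # < 2% attenuation at 1 Hz
  s10 <- syn_trace(sin(2 * pi * 10 * tt), dt = 1 / fs)
  out10 <- denoise_butterworth(s10, 5)
  # two zero-phase passes of order 3: |H|^2 = 1/(1+(f/fc)^6) -> ~1/65 at 2x fc
  expect_lt(max(abs(out10$values[mid])), 0.03)
  const <- syn_trace(rep(2.5, 300), dt = 1 / fs)
  expect_equal(denoise_butterworth(const, 5)$values, const$values,
               tolerance = 1e-9)
  expect_error(denoise_butterworth(syn_trace(tt, dt = 0.2), 5), "Nyquist")
})

test_that("Wiener deconvolution inverts the indicator blur", {
  dt <- 0.01
  set.seed(3)
  truth <- denoise_butterworth(syn_trace(rnorm(2000), dt = dt), 2)$values
  truth[1:100] <- truth[1:100] * seq(0, 1, length.out = 100)  # quiet start
  kern <- make_indicator_kernel(0.25, dt)
  blurred <- ribbonsyn:::convolve_causal(truth, kern$values, dt)
  # noiseless, infinite SNR: exact inverse filtering
  clean <- wiener_deconvolve_indicator(syn_trace(blurred, dt = dt), kern,
                                       snr_low = Inf, snr_high = Inf)
  core <- 101:1900
  expect_lt(max(abs(clean$values[core] - truth[core])), 1e-6)
  # matched-noise round trip: high coherence below 1 Hz
  noisy <- blurred + rnorm(length(blurred), 0, 0.05 * stats::sd(blurred))
  dec <- wiener_deconvolve_indicator(syn_trace(noisy, dt = dt), kern)
  lowpass <- function(v) denoise_butterworth(syn_trace(v, dt = dt), 1)$values
  expect_gt(stats::cor(lowpass(dec$values[core]), lowpass(truth[core])), 0.9)
  zerok <- kern; zerok$values <- 0 * zerok$values
  expect_error(wiener_deconvolve_indicator(syn_trace(noisy, dt = dt), zerok),
               "zero")
})

test_that("high-frequency noise is suppressed by the Wiener SNR profile", {
  dt <- 0.01
  set.seed(4)
  hf <- sin(2 * pi * 10 * seq(0, 20, by = dt))
  kern <- make_indicator_kernel(0.25, dt)
  out <- wiener_deconvolve_indicator(syn_trace(hf, dt = dt), kern)
  # above the 1 Hz break the filter gain is at most |H| / (|H|^2 + 20)
  expect_lt(stats::sd(out$values), stats::sd(hf))
})

test_that("non-negative shift is exact and idempotent", {
  tr <- syn_trace(c(-2.3, 0, 1, 4), dt = 1)
  out <- shift_nonnegative(tr)
  expect_equal(out$values, c(0, 2.3, 3.3, 6.3))
  expect_equal(shift_nonnegative(out)$values, out$values)
  nn <- syn_trace(c(0, 1, 2, 0.5), dt = 1)
  expect_equal(shift_nonnegative(nn)$values, nn$values)
})

test_that("rise/decay kinetics fits recover constructed time constants", {
  dt <- 1 / 100
  tt <- seq(0, 6, by = dt)
  # rise to peak at 1 s, then exponential decay with tau = 0.8 s
  v <- ifelse(tt < 1, (tt / 1)^2, exp(-(tt - 1) / 0.8))
  set.seed(5)
  noisy <- syn_trace(v + rnorm(length(v), 0, 0.02), dt = dt)
  fit <- fit_rise_decay(noisy, c(0, 6))
  expect_false(fit$decay$is_rise)
  expect_equal(fit$decay$tau, 0.8, tolerance = 0.1)
  expect_true(fit$delay_defined)
  # noiseless decay: near-exact recovery
  pure <- syn_trace(0.3 + 2 * exp(-tt / 1.5), dt = dt)
  f2 <- fit_rise_decay(pure, c(0, 6))
  expect_equal(f2$decay$tau, 1.5, tolerance = 1e-3)
  expect_equal(f2$decay$c, 0.3, tolerance = 1e-3)
  # a trace that never crosses 3 sd has an undefined delay
  flat <- syn_trace(rep(c(-0.01, 0.01), 300), dt = dt)
  f3 <- fit_rise_decay(flat, c(0, 5))
  expect_false(f3$delay_defined)
  expect_true(is.na(f3$delay))
})

test_that("trace containers resample and round-trip through CSV", {
  tr <- syn_trace(sin(1:100 / 7), dt = 0.064, t0 = 1, kind = "calcium")
  rs <- resample_trace(tr, 0.032)   # nested grid: original knots preserved
  expect_equal(rs$dt, 0.032)
  expect_equal(rs$values[seq(1, length(rs$values), by = 2)], tr$values,
               tolerance = 1e-9)
  tf <- tempfile(fileext = ".csv")
  write_trace_csv(tr, tf)
  back <- read_trace_csv(tf)
  expect_equal(back$values, tr$values, tolerance = 1e-12)
  expect_identical(back$kind, "calcium")
  expect_equal(back$dt, tr$dt)
})
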