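test_that("double-exponential kernel matches its closed form", {
  dt <- 0.001
  k <- make_double_exp_kernel(0.5, dt)
  expect_equal(sum(k$values) * dt, 1, tolerance = 1e-12)
  expect_true(all(k$values >= 0))
  # peak of exp(-t/td) - exp(-t/tr) at t* = ln(td/tr) / (1/tr - 1/td)
  tstar <- log(0.5 / 0.03) / (1 / 0.03 - 1 / 0.5)
  expect_lt(abs((which.max(k$values) - 1) * dt - tstar), 2 * dt)
  # unimodal: increases to the peak, decreases after
  pk <- which.max(k$values)
  expect_true(all(diff(k$values[1:pk]) >= 0))
  expect_true(all(diff(k$values[pk:length(k$values)]) <= 0))
  # area invariant under grid refinement
  k2 <- make_double_exp_kernel(0.5, dt / 2)
  expect_equal(sum(k2$values) * dt / 2, 1, tolerance = 1e-6)
  expect_error(make_double_exp_kernel(-0.1, dt), "> 0")
})

test_that("equal rise and decay constants give the alpha-function limit", {
  dt <- 0.001
  k <- make_double_exp_kernel(0.03, dt)
  tt <- seq(0, by = dt, length.out = length(k$values))
  ref <- tt * exp(-tt / 0.03)
  ref <- ref / (sum(ref) * dt)
  expect_gt(stats::cor(k$values, ref), 0.99999)
})

test_that("biphasic kernel is band-pass with the OFF sign convention", {
  dt <- 0.002
  k <- make_biphasic_kernel(dt)
  expect_lt(abs(sum(k$values) * dt), 1e-10)         # zero net area
  expect_lt(k$values[which.max(abs(k$values))], 0)  # OFF: fast lobe negative
  kon <- make_biphasic_kernel(dt, sign = 1)
  expect_equal(kon$values, -k$values)
})

test_that("light-to-calcium cascade matches a direct convolution oracle", {
  dt <- 0.01
  set.seed(5)
  stim <- syn_trace(runif(800), dt = dt, kind = "stimulus")
  k1 <- make_biphasic_kernel(dt)
  k2 <- make_double_exp_kernel(0.2, dt)
  ca <- light_to_calcium(stim, k1, k2)
  # naive O(N K) causal convolution with first-value padding
  conv_naive <- function(x, kv) {
    xp <- c(rep(x[1], length(kv) - 1), x)
    sapply(seq_along(x), function(n0) {
      n <- n0 + length(kv) - 1
      sum(kv * xp[n - seq_along(kv) + 1]) * dt
    })
  }
  expected <- conv_naive(exp(conv_naive(stim$values, k1$values)), k2$values)
  expect_lt(max(abs(ca$values - expected)), 1e-8)
})

test_that("cascade output is causal and time-invariant", {
  dt <- 0.01
  set.seed(6)
  v <- runif(1000)
  k1 <- make_biphasic_kernel(dt)
  k2 <- make_double_exp_kernel(0.2, dt)
  ca1 <- light_to_calcium(syn_trace(v, dt = dt), k1, k2)$values
  v2 <- v; v2[601:1000] <- rev(v2[601:1000])
  ca2 <- light_to_calcium(syn_trace(v2, dt = dt), k1, k2)$values
  expect_equal(ca1[1:600], ca2[1:600])  # future samples do not leak back
  # shifting the stimulus shifts the response (interior samples)
  lag <- 50
  v3 <- c(rep(v[1], lag), v[1:(1000 - lag)])
  ca3 <- light_to_calcium(syn_trace(v3, dt = dt), k1, k2)$values
  expect_equal(ca3[(lag + 1):1000], ca1[1:(1000 - lag)], tolerance = 1e-10)
})

test_that("constant stimulus and gain behave linearly in the output stage", {
  dt <- 0.01
  stim <- syn_trace(rep(0.5, 600), dt = dt)
  k1 <- make_biphasic_kernel(dt)
  k2 <- make_double_exp_kernel(0.2, dt)
  ca <- light_to_calcium(stim, k1, k2, gain = 3, offset = 1)
  expect_equal(ca$values, rep(3 * 1 + 1, 600), tolerance = 1e-9)
  set.seed(7)
  stim2 <- syn_trace(runif(600), dt = dt)
  a <- light_to_calcium(stim2, k1, k2, gain = 1, offset = 0.2)$values
  b <- light_to_calcium(stim2, k1, k2, gain = 2, offset = 0.2)$values
  expect_equal(b - 0.2, 2 * (a - 0.2), tolerance = 1e-10)
  expect_error(light_to_calcium(stim, make_biphasic_kernel(0.02), k2),
               "dt")
})

test_that("a dark step drives a biphasic calcium rise through the OFF cascade", {
  dt <- 0.005
  v <- c(rep(0.5, 400), rep(0, 100), rep(0.5, 500))  # 500 ms dark step
  stim <- syn_trace(v, dt = dt)
  ca <- light_to_calcium(stim, make_biphasic_kernel(dt),
                         make_double_exp_kernel(0.15, dt))$values
  pre <- ca[390]
  during <- max(ca[401:520])
  late <- ca[900]
  expect_gt(during, pre)             # decrement raises calcium
  expect_lt(abs(late - pre), 0.5 * (during - pre))  # relaxes back
})
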