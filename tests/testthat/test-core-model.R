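test_that("release non-linearity is a calibrated sigmoid", {
  for (k in c(1, 10.2, 30)) for (x0 in c(0.1, 0.5, 1.2))
    expect_identical(release_nonlinearity(x0, k, x0), 0.5)
  expect_lt(release_nonlinearity(-1e3, 10.2, 0.5), 1e-12)
  expect_gt(release_nonlinearity(1e3, 10.2, 0.5), 1 - 1e-12)
  ca <- seq(-2, 3, by = 0.05)
  expect_true(all(diff(release_nonlinearity(ca, 10.2, 0.5)) > 0))
  # independent scalar evaluation of the closed form
  expect_equal(release_nonlinearity(0.7, 10.2, 0.5),
               1 / (1 + exp(-10.2 * (0.7 - 0.5))), tolerance = 1e-15)
  expect_error(release_nonlinearity(NaN, 10.2, 0.5), "finite")
  expect_error(release_nonlinearity(0.5, -1, 0.5), "> 0")
})

test_that("pool fluxes vanish at the right saturation/depletion boundaries", {
  p <- default_params()
  full <- c(RP = p$RP_max, IP = p$IP_max, RRP = p$RRP_max, Exo = 0)
  f <- pool_fluxes(full, ca = p$x0 - 2, p)
  expect_equal(unname(f[c("r", "i", "d")]), c(0, 0, 0))
  expect_lt(f[["e"]], p$e_max * 1e-8)
  f2 <- pool_fluxes(c(RP = p$RP_max / 2, IP = 0, RRP = 0, Exo = 1), 0.5, p)
  expect_equal(f2[["r"]], p$r_max * 0.5)
  expect_equal(f2[["i"]], 0)
  expect_equal(f2[["e"]], 0)
  expect_equal(f2[["d"]], p$d_max * 1)
})

test_that("pool fluxes match direct evaluation of the transfer formulas", {
  p <- default_params()
  st <- c(RP = 100, IP = 9, RRP = 2.5, Exo = 4)
  ca <- 0.62
  f <- pool_fluxes(st, ca, p)
  sig <- 1 / (1 + exp(-p$k * (ca - p$x0)))
  expect_equal(f[["r"]], p$r_max * (1 - 9 / p$IP_max) * 100 / p$RP_max)
  expect_equal(f[["i"]], p$i_max * (1 - 2.5 / p$RRP_max) * 9 / p$IP_max)
  expect_equal(f[["e"]], p$e_max * sig * 2.5 / p$RRP_max)
  expect_equal(f[["d"]], p$d_max * 4)
  expect_error(pool_fluxes(c(RP = -1, IP = 0, RRP = 0, Exo = 0), 0.5, p),
               "tolerance")
})

test_that("simulation conserves vesicles and respects pool bounds", {
  p <- default_params()
  fix <- flash_fixture(3)
  traj <- simulate_release(p, fix$calcium)
  tot <- traj$RP + traj$IP + traj$RRP + traj$Exo
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  tol <- 1e-6
  expect_true(all(traj$RP >= -tol * p$RP_max & traj$RP <= p$RP_max * (1 + tol)))
  expect_true(all(traj$IP >= -tol * p$IP_max & traj$IP <= p$IP_max * (1 + tol)))
  expect_true(all(traj$RRP >= -tol * p$RRP_max & traj$RRP <= p$RRP_max * (1 + tol)))
  expect_true(all(traj$Exo >= -tol))
})

test_that("release output scales exactly with jointly scaled rates and pools", {
  p <- default_params()
  fix <- flash_fixture(2)
  e1 <- simulate_release(p, fix$calcium)$e
  e2 <- simulate_release(scale_params(p, 2), fix$calcium)$e
  expect_lt(max(abs(e2 - 2 * e1)) / max(2 * e1), 1e-6)
  expect_equal(unclass(scale_params(p, 1)), unclass(p))
  expect_error(scale_params(p, 0), "> 0")
  expect_error(scale_params(p, -2), "> 0")
})

test_that("constant-calcium simulation converges to the root-solved fixed point", {
  p <- default_params()
  ca <- syn_trace(rep(0.6, 15000), dt = 0.01, kind = "calcium")
  traj <- simulate_release(p, ca, init = "full")
  ss <- steady_state_release(p, 0.6)
  n <- length(traj$time)
  end <- c(traj$RP[n], traj$IP[n], traj$RRP[n], traj$Exo[n])
  expect_lt(max(abs(end - unlist(ss[c("RP", "IP", "RRP", "Exo")]))) / sum(end),
            1e-8)
  expect_equal(traj$e[n], ss$phi, tolerance = 1e-8)
})

test_that("fixed-point occupancies halve when the parameters are halved", {
  p <- default_params()
  s1 <- steady_state_release(p, 0.7)
  s2 <- steady_state_release(scale_params(p, 0.5), 0.7,
                             total = 0.5 * (p$RP_max + p$IP_max + p$RRP_max))
  for (pool in c("RP", "IP", "RRP", "Exo"))
    expect_equal(s2[[pool]], 0.5 * s1[[pool]], tolerance = 1e-9)
})

test_that("steady-state release is non-decreasing in the calcium level", {
  p <- default_params()
  phis <- vapply(seq(0.05, 1.5, by = 0.05),
                 function(cc) steady_state_release(p, cc)$phi, numeric(1))
  expect_true(all(diff(phis) >= -1e-12))
})

test_that("a calcium step evokes a transient release peak that then relaxes", {
  p <- default_params()
  ca <- syn_trace(c(rep(0.2, 500), rep(0.9, 2500)), dt = 0.01,
                  kind = "calcium")
  traj <- simulate_release(p, ca)
  post <- traj$e[501:3000]
  expect_gt(max(post), 1.5 * post[length(post)])  # peak then depletion
  expect_lt(which.max(post), 300)                 # peaks within ~3 s of the step
  expect_true(all(diff(post[800:2500]) <= 1e-9))  # monotone relaxation after
})

test_that("adaptive solver agrees with an independent general-purpose ODE solver", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  fix <- flash_fixture(2)
  y0 <- c(p$RP_max, p$IP_max, p$RRP_max, 0)
  traj <- simulate_release(p, fix$calcium, init = y0)
  tt <- trace_time(fix$calcium)
  cafun <- stats::approxfun(tt, fix$calcium$values, rule = 2)
  rhs <- function(t, y, parms) {
    # same clipped-state flux definition as the compiled right-hand side
    RP <- min(max(y[1], 0), p$RP_max); IP <- min(max(y[2], 0), p$IP_max)
    RRP <- min(max(y[3], 0), p$RRP_max); Exo <- max(y[4], 0)
    sig <- 1 / (1 + exp(-p$k * (cafun(t) - p$x0)))
    r <- p$r_max * (1 - IP / p$IP_max) * RP / p$RP_max
    i <- p$i_max * (1 - RRP / p$RRP_max) * IP / p$IP_max
    e <- p$e_max * sig * RRP / p$RRP_max
    d <- p$d_max * Exo
    list(c(d - r, r - i, i - e, e - d))
  }
  sol <- deSolve::ode(y0, tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(sol[, 4] - traj$RRP)) / p$RRP_max, 1e-4)
})

test_that("reduced parameterisation expands with the documented couplings", {
  sp <- simplified_params(10, 4, 0.5, x0 = 0.5)
  p <- expand_simplified(sp)
  expect_equal(p$r_max, 2)
  expect_equal(p$i_max, 4)
  expect_equal(p$e_max, 2)
  expect_equal(p$k, 10.2)
  expect_equal(p$r_max / p$IP_max, 0.2)
  expect_equal(p$i_max / p$IP_max, 0.4)
  expect_error(simplified_params(10, 4, 1.2, 0.5), "\\[0, 1\\]")
  # zero release fraction: release stays at numerical zero for any stimulus
  p0 <- expand_simplified(simplified_params(10, 4, 0, x0 = 0.5))
  fix <- flash_fixture(1)
  expect_lt(max(simulate_release(p0, fix$calcium)$e), 1e-12)
})

test_that("parameter containers validate and round-trip through JSON", {
  expect_error(ribbon_params(-1, 2.5, 10, 14, 0.5, 13.8, 4), "> 0")
  expect_error(ribbon_params(2.5, 2.5, 10, -14, 0.5, 13.8, 4), "> 0")
  p <- default_params()
  tf <- tempfile(fileext = ".json")
  write_params_json(p, tf)
  expect_equal(unclass(read_params_json(tf)), unclass(p))
  sp <- simplified_params(10, 4, 0.5, 0.5)
  write_params_json(sp, tf)
  expect_equal(unclass(read_params_json(tf)), unclass(sp))
})
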