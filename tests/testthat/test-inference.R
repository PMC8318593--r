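test_that("normalised 0.5 maps to the prior modes in natural units", {
  pr <- prior_spec()
  nat <- to_natural(rep(0.5, 7), pr)[1, ]
  expect_equal(unname(nat), c(2.5, 2.5, 10, 14, 0.5, 13.8, 4.0),
               tolerance = 0.005)
  # pool sizes stay strictly positive over a large draw battery
  s <- sample_and_transform(pr, 1e5, seed = 3)
  expect_true(all(s$natural[, c("IP_max", "RRP_max")] > 0))
  expect_true(all(s$natural > 0))   # rejection handles the linear ones
  # determinism under a fixed seed
  s2 <- sample_and_transform(pr, 1e5, seed = 3)
  expect_identical(s$u, s2$u)
  expect_gt(s$n_rejected, 0)        # linear coordinates do get rejected
})

test_that("loss kernel is flat to the pseudo-observation then half-Gaussian", {
  losses <- c(0.5, 1, 2, 3, 10, 50)
  beta <- 1; sc <- 2
  w <- loss_kernel(losses, beta, sc)
  expect_equal(w[1:2], c(1, 1))
  expect_equal(w[3], exp(-1 / 8))
  expect_equal(w[4], exp(-(3 - 1)^2 / (2 * 4)))
  expect_lt(w[6], 1e-60)
  # at beta + scale the weight is exp(-1/2)
  expect_equal(loss_kernel(beta + sc, beta, sc), exp(-0.5))
  # default scale is the 25th percentile of the losses
  expect_equal(loss_kernel(losses, beta),
               loss_kernel(losses, beta, unname(quantile(losses, 0.25))))
  # identical losses: uniform weights
  expect_equal(loss_kernel(rep(2, 5), 1), rep(1, 5))
  expect_error(loss_kernel(c(1, NA), 1), "finite")
})

test_that("MDN conditional mean tracks a known linear-Gaussian relation", {
  set.seed(42)
  n <- 2000
  x <- runif(n)
  th <- matrix(rnorm(n, x, 0.1), ncol = 1)
  fit <- train_mdn(th, x, epochs = 250, batch_size = 1000, seed = 5)
  for (x0 in c(0.2, 0.5, 0.8)) {
    post <- condition_mdn(fit, x0)
    m <- sum(post$weights * vapply(post$means, `[`, numeric(1), 1))
    expect_equal(m, x0, tolerance = 0.05)
  }
  # conditional spread close to the generating sd
  post <- condition_mdn(fit, 0.5)
  mm <- vapply(post$means, `[`, numeric(1), 1)
  vv <- vapply(post$covs, `[`, numeric(1), 1, 1)
  sd_mix <- sqrt(sum(post$weights * (vv + mm^2)) - sum(post$weights * mm)^2)
  expect_lt(abs(sd_mix - 0.1), 0.02)
})

test_that("MDN training objective is invariant to dataset duplication", {
  set.seed(43)
  n <- 300
  x <- runif(n)
  th <- matrix(rnorm(n, x, 0.1), ncol = 1)
  fit <- train_mdn(th, x, epochs = 30, batch_size = 100, seed = 2)
  nll1 <- ribbonsyn:::mdn_nll(fit, th, x)
  nll2 <- ribbonsyn:::mdn_nll(fit, rbind(th, th), c(x, x))
  expect_equal(nll1, nll2, tolerance = 1e-12)
})

test_that("a single dominant training weight collapses the posterior onto it", {
  set.seed(44)
  n <- 400
  th <- matrix(runif(n, -1, 1), ncol = 1)
  x <- runif(n)
  w <- rep(0, n); w[17] <- 1
  fit <- train_mdn(th, x, weights = w, epochs = 150, batch_size = 400,
                   seed = 3)
  post <- condition_mdn(fit, x[17])
  m <- sum(post$weights * vapply(post$means, `[`, numeric(1), 1))
  expect_equal(m, th[17, 1], tolerance = 0.05)
})

test_that("conditioning at larger loss values yields broader posteriors", {
  # toy with conditional spread growing in x: theta | x ~ N(x, (0.05 + 0.3 x)^2)
  set.seed(45)
  n <- 4000
  x <- runif(n)
  th <- matrix(rnorm(n, x, 0.05 + 0.3 * x), ncol = 1)
  fit <- train_mdn(th, x, epochs = 250, batch_size = 1000, seed = 6)
  spread <- function(x0) {
    post <- condition_mdn(fit, x0)
    mm <- vapply(post$means, `[`, numeric(1), 1)
    vv <- vapply(post$covs, `[`, numeric(1), 1, 1)
    sqrt(sum(post$weights * (vv + mm^2)) - sum(post$weights * mm)^2)
  }
  expect_gt(spread(0.8), spread(0.2))
})

test_that("early stopping picks the round with the smallest median loss", {
  mk <- function(m) list(median_loss = m)
  expect_equal(select_final_posterior(lapply(c(5, 3, 4), mk)), 2)
  expect_equal(select_final_posterior(lapply(c(5, 4, 3), mk)), 3)
  expect_equal(select_final_posterior(lapply(c(3, 3, 4), mk)), 1)  # tie: earliest
})

test_that("a small sequential run is deterministic and structurally sound", {
  fix <- flash_fixture(2)
  rb <- recovery_target(fix, c(r_max = 2.5, i_max = 2.5, e_max = 10, k = 14,
                               x0 = 0.5, IP_max = 13.8, RRP_max = 4),
                        n_trials = 6, seed = 7)
  run <- function() run_sequential_inference(
    rb$target, rb$normalisation, fix$calcium, fix$proto$annotations,
    rounds = 2, n_sims = 120, epochs = 25, batch_size = 120, seed = 11)
  r1 <- run(); r2 <- run()
  expect_identical(vapply(r1$rounds, `[[`, numeric(1), "beta"),
                   vapply(r2$rounds, `[[`, numeric(1), "beta"))
  expect_identical(r1$final$means, r2$final$means)
  expect_length(r1$posteriors, 2)
  expect_s3_class(r1$final, "mixture_posterior")
  expect_equal(sum(r1$final$weights), 1, tolerance = 1e-12)
  for (cv in r1$final$covs) expect_true(all(eigen(cv)$values > 0))
  # kernel scale and pseudo-observation recorded per round
  expect_equal(r1$rounds[[1]]$beta,
               unname(quantile(r1$rounds[[1]]$losses, 0.001)))
  expect_equal(r1$rounds[[1]]$kernel_scale,
               unname(quantile(r1$rounds[[1]]$losses, 0.25)))
})

test_that("posterior sampling and HDI utilities behave", {
  post <- structure(list(weights = c(0.5, 0.5), means = list(0, 5),
                         covs = list(matrix(1), matrix(1)),
                         conditioned_at = 0, dim = 1),
                    class = "mixture_posterior")
  set.seed(9)
  s <- sample_mixture(post, 20000)
  expect_equal(mean(s), 2.5, tolerance = 0.1)
  # density integrates to ~1 on a grid
  g <- seq(-6, 11, by = 0.01)
  expect_equal(sum(dmixture(post, matrix(g, ncol = 1))) * 0.01, 1,
               tolerance = 1e-3)
  # HDI of a standard normal sample approximates +-1.645
  set.seed(10)
  h <- hdi_interval(rnorm(50000), 0.9)
  expect_equal(h[1], -1.645, tolerance = 0.05)
  expect_equal(h[2], 1.645, tolerance = 0.05)
})
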