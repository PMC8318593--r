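#' First-order Sobol sensitivity indices by the paired-matrix method
#'
#' Estimates \code{S_i = V[E[Y | theta_i]] / V[Y]} -- the expected relative
#' variance reduction from fixing parameter i -- with the Saltelli
#' paired-matrix Monte Carlo estimator: two independent sample matrices A
#' and B and, per parameter, the hybrid matrix AB_i (A with column i taken
#' from B); then \code{S_i = mean(Y_B * (Y_ABi - Y_A)) / V}. Works for
#' scalar or vector-valued (e.g. time-resolved) outputs. Negative estimates
#' are a normal feature of the Monte Carlo noise floor and are retained
#' (clip only for display).
#'
#' @param model Function mapping a parameter vector (one row of the sample
#'   matrix) to a numeric output (scalar or fixed-length vector).
#' @param sampler Either a function \code{(n) -> n x d matrix} of independent
#'   draws, or a matrix of samples whose columns are resampled independently
#'   (marginal sampling, appropriate for posterior samples whose
#'   correlations are weak).
#' @param n Number of base samples (total model runs: \code{n * (d + 2)}).
#' @param d Parameter dimension (required when \code{sampler} is a function
#'   and cannot be probed).
#' @param seed Integer seed.
#' @param total_order Also return total-order indices (Jansen estimator)?
#' @return Object of class \code{sobol_result}: \code{S} (d x T matrix of
#'   first-order indices), \code{SE} (matching standard errors),
#'   \code{var_y}, \code{n}, and optionally \code{ST}. Time points with
#'   vanishing output variance have \code{S} set to NA (flagged in
#'   \code{undefined}).
#' @export
sobol_first_order <- function(model, sampler, n = 1000, d = NULL, seed = 1,
                              total_order = FALSE) {
  set.seed(seed)
  if (is.matrix(sampler)) {
    pool <- sampler
    d <- ncol(pool)
    draw <- function(m) {
      out <- matrix(0, m, d)
      for (j in seq_len(d)) out[, j] <- pool[sample.int(nrow(pool), m,
                                                        replace = TRUE), j]
      out
    }
  } else {
    draw <- sampler
    if (is.null(d)) d <- ncol(draw(2))
  }
  A <- draw(n); B <- draw(n)
  run <- function(M) {
    y1 <- model(M[1, ])
    Y <- matrix(0, n, length(y1))
    Y[1, ] <- y1
    for (i in 2:n) Y[i, ] <- model(M[i, ])
    Y
  }
  YA <- run(A); YB <- run(B)
  Tn <- ncol(YA)
  Yall <- rbind(YA, YB)
  V <- apply(Yall, 2, stats::var)
  S <- SE <- matrix(NA_real_, d, Tn)
  ST <- if (total_order) matrix(NA_real_, d, Tn) else NULL
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    YABi <- run(ABi)
    U <- YB * (YABi - YA)            # n x T summands
    S[i, ] <- colMeans(U) / V
    SE[i, ] <- apply(U, 2, stats::sd) / sqrt(n) / V
    if (total_order) {
      W <- (YA - YABi)^2
      ST[i, ] <- colMeans(W) / (2 * V)
    }
  }
  undefined <- V < 1e-300
  S[, undefined] <- NA_real_
  structure(list(S = S, SE = SE, ST = ST, var_y = V, n = n, d = d,
                 undefined = undefined),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("<sobol_result> %d parameters, %d output(s), n = %d\n",
              x$d, ncol(x$S), x$n))
  if (ncol(x$S) == 1)
    print(round(cbind(S = x$S[, 1], SE = x$SE[, 1]), 4))
  invisible(x)
}

#' Time-resolved Sobol indices of the release output
#'
#' Runs \code{\link{sobol_first_order}} with the release model: parameters
#' are sampled per-dimension from the columns of \code{posterior_draws}
#' (independent marginal sampling; the joint posteriors are mostly
#' uncorrelated, which justifies the independence the estimator assumes),
#' the model is simulated on the given calcium input, and the output is the
#' release rate downsampled to \code{out_hz} (plus, as the last output
#' column, the time-integrated release).
#'
#' @param posterior_draws Matrix of natural-scale parameter samples (columns
#'   named as in \code{\link{prior_spec}} modes).
#' @param calcium Calcium input \code{\link{syn_trace}}.
#' @param n Base sample count.
#' @param seed Integer seed.
#' @param out_hz Output grid for the time-resolved indices; default 10.
#' @param RP_max,d_max Fixed parameters.
#' @return A \code{sobol_result}; the attribute \code{time} gives the output
#'   time grid (last column = integrated release).
#' @export
sobol_release <- function(posterior_draws, calcium, n = 500, seed = 1,
                          out_hz = 10, RP_max = 10 * exp(2.625),
                          d_max = 0.1) {
  keep <- seq(1, length(calcium$values),
              by = max(1L, round(1 / (out_hz * calcium$dt))))
  model <- function(th) {
    names(th) <- colnames(posterior_draws)
    pp <- draw_to_params(th, RP_max = RP_max, d_max = d_max)
    rel <- simulate_release(pp, calcium)$release
    c(rel$values[keep], sum(rel$values) * rel$dt)
  }
  res <- sobol_first_order(model, posterior_draws, n = n, seed = seed)
  attr(res, "time") <- trace_time(calcium)[keep]
  res
}
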