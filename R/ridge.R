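#' Ridge regression baseline from lagged calcium to glutamate
#'
#' The statistical reference model against which the kinetic cascade is
#' compared: ordinary ridge regression predicting the glutamate release at
#' each time point from the calcium values of the preceding \code{lag_s}
#' seconds (a causal lagged design). Columns are standardised before
#' penalisation and the intercept is left unpenalised; coefficients minimise
#' \code{||y - Xw||^2 + alpha ||w||^2}.
#'
#' @param calcium,glutamate Aligned \code{\link{syn_trace}}s on the same
#'   uniform grid.
#' @param lag_s History window [s]; default 0.5.
#' @param alpha Regularisation strength; default 0.1.
#' @return Object of class \code{ridge_baseline} with the fitted
#'   coefficients; use \code{\link{predict_ridge}} on new calcium traces.
#' @export
fit_ridge_baseline <- function(calcium, glutamate, lag_s = 0.5, alpha = 0.1) {
  stopifnot(inherits(calcium, "syn_trace"), inherits(glutamate, "syn_trace"))
  if (abs(calcium$dt - glutamate$dt) > 1e-12 ||
      length(calcium$values) != length(glutamate$values) ||
      abs(calcium$t0 - glutamate$t0) > 1e-9)
    stop("fit_ridge_baseline: traces must share one grid")
  L <- max(1L, round(lag_s / calcium$dt))
  des <- lagged_design(calcium$values, L)
  y <- glutamate$values[(L + 1):length(glutamate$values)]
  mu_x <- colMeans(des); sd_x <- apply(des, 2, stats::sd)
  sd_x[sd_x < 1e-12] <- 1
  Xs <- sweep(sweep(des, 2, mu_x), 2, sd_x, `/`)
  mu_y <- mean(y)
  XtX <- crossprod(Xs)
  w <- solve(XtX + alpha * diag(ncol(Xs)), crossprod(Xs, y - mu_y))
  structure(list(w = as.numeric(w), mu_x = mu_x, sd_x = sd_x, mu_y = mu_y,
                 L = L, dt = calcium$dt, alpha = alpha),
            class = "ridge_baseline")
}

# internal: rows are (x[t], x[t-1], ..., x[t-L]) for t = L+1 .. n
lagged_design <- function(x, L) {
  n <- length(x)
  des <- matrix(0, n - L, L + 1)
  for (k in 0:L) des[, k + 1] <- x[(L + 1 - k):(n - k)]
  des
}

#' Predict glutamate from calcium with a fitted ridge baseline
#'
#' @param fit A \code{ridge_baseline}.
#' @param calcium A \code{\link{syn_trace}} on the same grid spacing as the
#'   training data.
#' @return A \code{syn_trace} of predictions aligned to the calcium grid
#'   (the first \code{L} samples, which lack a full history, repeat the
#'   first prediction).
#' @export
predict_ridge <- function(fit, calcium) {
  stopifnot(inherits(fit, "ridge_baseline"), inherits(calcium, "syn_trace"))
  if (abs(calcium$dt - fit$dt) > 1e-12)
    stop("predict_ridge: grid spacing differs from the training data")
  des <- lagged_design(calcium$values, fit$L)
  Xs <- sweep(sweep(des, 2, fit$mu_x), 2, fit$sd_x, `/`)
  yh <- as.numeric(Xs %*% fit$w) + fit$mu_y
  trace_like(calcium, c(rep(yh[1], fit$L), yh), kind = "glutamate")
}

#' Unstandardised regression kernel of a ridge baseline
#'
#' @param fit A \code{ridge_baseline}.
#' @return Numeric vector of length L+1: the weight on calcium at lags
#'   0, dt, ..., L dt on the original scale.
#' @export
ridge_kernel <- function(fit) {
  stopifnot(inherits(fit, "ridge_baseline"))
  fit$w / fit$sd_x
}
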