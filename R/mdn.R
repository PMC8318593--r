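# Mixture-density network: a small feed-forward network mapping a scalar
# conditioning value (here, the relevant loss of a simulation) to the
# parameters of a full-covariance Gaussian mixture over the normalised model
# parameters. Covariances are parameterised through the Cholesky factor U of
# the precision matrix (log-diagonal + free off-diagonal entries), which
# keeps them positive definite by construction. Trained by Adam on the
# (kernel-)weighted negative log-likelihood with analytic gradients.

# ---- parameter-layout helpers -----------------------------------------------

mdn_layout <- function(d, n_comp) {
  noff <- d * (d - 1) / 2
  per <- 1 + d + d + noff   # logit, mean, log-diag, off-diag per component
  # off-diagonal ordering: (j, k) with k < j, column-major in the lower triangle
  off_idx <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
  list(d = d, n_comp = n_comp, noff = noff, K = n_comp * per,
       off_j = off_idx[, 1], off_k = off_idx[, 2],
       logit = seq_len(n_comp),
       mu = function(c) n_comp + (c - 1) * d + seq_len(d),
       sdg = function(c) n_comp + n_comp * d + (c - 1) * d + seq_len(d),
       off = function(c) if (noff == 0) integer(0) else
         n_comp + 2 * n_comp * d + (c - 1) * noff + seq_len(noff))
}

mdn_init <- function(layout, hidden = c(120, 120), seed = 1) {
  set.seed(seed)
  sizes <- c(1, hidden, layout$K)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    sc <- if (l == length(sizes) - 1) 0.01 else 1 / sqrt(sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sc),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  # spread the component means a little so the mixture can break symmetry
  for (c in seq_len(layout$n_comp))
    b[[length(b)]][layout$mu(c)] <-
      stats::rnorm(layout$d, 0, 0.3) * (c - (layout$n_comp + 1) / 2) / layout$n_comp
  list(W = W, b = b)
}

# smooth clamp of the log-precision-diagonal outputs: a*tanh(r/a)
SDG_CAP <- 8

# forward pass through the dense trunk; xs is a standardised column vector
mdn_trunk <- function(net, xs) {
  h <- list()
  a <- matrix(xs, ncol = 1)
  nl <- length(net$W)
  for (l in seq_len(nl - 1)) {
    a <- tanh(sweep(a %*% net$W[[l]], 2, net$b[[l]], `+`))
    h[[l]] <- a
  }
  o <- sweep(a %*% net$W[[nl]], 2, net$b[[nl]], `+`)
  list(h = h, o = o)
}

# weighted mixture NLL and gradient wrt the network outputs.
# theta: B x d (standardised), o: B x K, w: B weights summing to 1.
mdn_mixture_loss <- function(o, theta, w, layout, want_grad = TRUE) {
  B <- nrow(theta); d <- layout$d; nc <- layout$n_comp
  logits <- o[, layout$logit, drop = FALSE]
  logits <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(logits)))
  logpi <- logits - lse
  comp <- vector("list", nc)
  logN <- matrix(0, B, nc)
  for (c in seq_len(nc)) {
    mu <- o[, layout$mu(c), drop = FALSE]
    sraw <- o[, layout$sdg(c), drop = FALSE]
    s <- SDG_CAP * tanh(sraw / SDG_CAP)
    es <- exp(s)
    q <- if (layout$noff > 0) o[, layout$off(c), drop = FALSE] else
      matrix(0, B, 0)
    diff <- theta - mu
    z <- diff * es                       # diagonal contribution: z_k += U_kk diff_k
    if (layout$noff > 0)
      for (m in seq_len(layout$noff)) {
        jj <- layout$off_j[m]; kk <- layout$off_k[m]
        z[, kk] <- z[, kk] + q[, m] * diff[, jj]
      }
    logN[, c] <- rowSums(s) - 0.5 * rowSums(z^2) - 0.5 * d * log(2 * pi)
    comp[[c]] <- list(mu = mu, s = s, sraw = sraw, es = es, q = q,
                      diff = diff, z = z)
  }
  lj <- logpi + logN
  mx <- apply(lj, 1, max)
  ll <- mx + log(rowSums(exp(lj - mx)))
  loss <- -sum(w * ll)
  if (!want_grad) return(list(loss = loss))
  gamma <- exp(lj - ll)                  # responsibilities, B x nc
  pi_ <- exp(logpi)
  dO <- matrix(0, B, layout$K)
  dO[, layout$logit] <- w * (pi_ - gamma)
  for (c in seq_len(nc)) {
    cc <- comp[[c]]
    g <- w * gamma[, c]
    # d logN / d mu_j = (U z)_j ; U z has diagonal and off-diagonal parts
    Uz <- cc$z * cc$es
    if (layout$noff > 0)
      for (m in seq_len(layout$noff)) {
        jj <- layout$off_j[m]; kk <- layout$off_k[m]
        Uz[, jj] <- Uz[, jj] + cc$q[, m] * cc$z[, kk]
      }
    dO[, layout$mu(c)] <- -g * Uz
    ds <- -(g) * (1 - cc$z * cc$diff * cc$es)
    dO[, layout$sdg(c)] <- ds * (1 - (cc$s / SDG_CAP)^2)  # through the clamp
    if (layout$noff > 0) {
      dq <- matrix(0, B, layout$noff)
      for (m in seq_len(layout$noff)) {
        jj <- layout$off_j[m]; kk <- layout$off_k[m]
        dq[, m] <- g * cc$z[, kk] * cc$diff[, jj]
      }
      dO[, layout$off(c)] <- dq
    }
  }
  list(loss = loss, dO = dO)
}

# backprop the output gradient through the trunk
mdn_backprop <- function(net, xs, h, dO) {
  nl <- length(net$W)
  dW <- vector("list", nl); db <- vector("list", nl)
  delta <- dO
  for (l in nl:1) {
    a_prev <- if (l == 1) matrix(xs, ncol = 1) else h[[l - 1]]
    dW[[l]] <- crossprod(a_prev, delta)
    db[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(net$W[[l]])) * (1 - h[[l - 1]]^2)
  }
  list(dW = dW, db = db)
}

#' Train a mixture-density network on (parameter, loss) pairs
#'
#' Fits \code{q(theta | x)}, a conditional Gaussian mixture over normalised
#' parameters given the scalar relevant loss, with per-pair weights from the
#' loss kernel. Architecture: two tanh hidden layers (default 120 units
#' each) feeding a 3-component mixture head with full covariances via a
#' precision-Cholesky parameterisation. Optimised with Adam (learning rate
#' 1e-3), global-norm gradient clipping, minibatches of 1000 for 800 epochs.
#' Deterministic under a fixed seed.
#'
#' @param theta Matrix of normalised parameter draws (rows).
#' @param x Vector of conditioning values (the losses).
#' @param weights Per-pair non-negative weights; default all equal.
#' @param n_comp Mixture components; default 3.
#' @param hidden Hidden layer widths; default \code{c(120, 120)}.
#' @param epochs,batch_size,lr Training schedule; defaults 800 / 1000 / 1e-3.
#' @param clip Global gradient-norm clip; default 5.
#' @param seed Integer seed (initialisation and minibatch order).
#' @return An object of class \code{mdn_fit}; see
#'   \code{\link{condition_mdn}}.
#' @export
train_mdn <- function(theta, x, weights = NULL, n_comp = 3,
                      hidden = c(120, 120), epochs = 800, batch_size = 1000,
                      lr = 1e-3, clip = 5, seed = 1) {
  theta <- as.matrix(theta)
  n <- nrow(theta); d <- ncol(theta)
  stopifnot(length(x) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights >= 0), sum(weights) > 0)
  wn <- weights / sum(weights)
  # standardise both spaces (weighted) for conditioning stability
  xm <- sum(wn * x); xsd <- sqrt(max(sum(wn * (x - xm)^2), 1e-12))
  tm <- colSums(wn * theta)
  tsd <- sqrt(pmax(colSums(wn * sweep(theta, 2, tm)^2), 1e-12))
  xs <- (x - xm) / xsd
  ts <- sweep(sweep(theta, 2, tm), 2, tsd, `/`)
  layout <- mdn_layout(d, n_comp)
  net <- mdn_init(layout, hidden, seed = seed)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  curve <- numeric(epochs)
  set.seed(seed + 1)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_w <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      wb <- wn[idx]
      if (sum(wb) <= 0) next
      wb <- wb / sum(wb)
      fw <- mdn_trunk(net, xs[idx])
      ml <- mdn_mixture_loss(fw$o, ts[idx, , drop = FALSE], wb, layout)
      if (!is.finite(ml$loss))
        stop("train_mdn: non-finite training loss at epoch ", ep)
      gr <- mdn_backprop(net, xs[idx], fw$h, ml$dO)
      gn <- sqrt(sum(vapply(gr$dW, function(g) sum(g^2), numeric(1))) +
                   sum(vapply(gr$db, function(g) sum(g^2), numeric(1))))
      sc <- if (gn > clip) clip / gn else 1
      step <- step + 1
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (l in seq_along(net$W)) {
        gW <- gr$dW[[l]] * sc; gb <- gr$db[[l]] * sc
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        net$W[[l]] <- net$W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        net$b[[l]] <- net$b[[l]] - lr * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
      }
      ep_loss <- ep_loss + ml$loss; ep_w <- ep_w + 1
    }
    curve[ep] <- ep_loss / max(ep_w, 1)
  }
  structure(list(net = net, layout = layout, xm = xm, xsd = xsd, tm = tm,
                 tsd = tsd, hidden = hidden, curve = curve, seed = seed),
            class = "mdn_fit")
}

# internal: weighted NLL of a fitted (or candidate) network on a dataset
mdn_nll <- function(fit, theta, x, weights = NULL) {
  theta <- as.matrix(theta)
  if (is.null(weights)) weights <- rep(1, nrow(theta))
  wn <- weights / sum(weights)
  xs <- (x - fit$xm) / fit$xsd
  ts <- sweep(sweep(theta, 2, fit$tm), 2, fit$tsd, `/`)
  fw <- mdn_trunk(fit$net, xs)
  mdn_mixture_loss(fw$o, ts, wn, fit$layout, want_grad = FALSE)$loss
}

#' Condition a trained MDN at a loss value
#'
#' Evaluates the network at \code{x} and returns the resulting Gaussian
#' mixture over parameters, mapped back from the internal standardised space
#' to the normalised parameter space.
#'
#' @param fit An \code{mdn_fit} from \code{\link{train_mdn}}.
#' @param x Scalar conditioning value (e.g. the pseudo-observation beta_n).
#' @return An object of class \code{mixture_posterior}: \code{weights}
#'   (sums to 1), \code{means} (list of vectors), \code{covs} (list of
#'   positive-definite matrices), \code{conditioned_at}.
#' @export
condition_mdn <- function(fit, x) {
  stopifnot(inherits(fit, "mdn_fit"), length(x) == 1)
  layout <- fit$layout; d <- layout$d
  o <- mdn_trunk(fit$net, (x - fit$xm) / fit$xsd)$o[1, ]
  logits <- o[layout$logit]
  w <- exp(logits - max(logits)); w <- w / sum(w)
  means <- list(); covs <- list()
  for (c in seq_len(layout$n_comp)) {
    mu <- o[layout$mu(c)]
    s <- SDG_CAP * tanh(o[layout$sdg(c)] / SDG_CAP)
    U <- diag(exp(s), d)
    if (layout$noff > 0)
      U[cbind(layout$off_j, layout$off_k)] <- o[layout$off(c)]
    P <- U %*% t(U)
    Sig <- chol2inv(chol(P))
    means[[c]] <- fit$tm + fit$tsd * mu
    covs[[c]] <- diag(fit$tsd, d) %*% Sig %*% diag(fit$tsd, d)
  }
  structure(list(weights = w, means = means, covs = covs,
                 conditioned_at = x, dim = d),
            class = "mixture_posterior")
}

#' @export
print.mixture_posterior <- function(x, ...) {
  cat(sprintf("<mixture_posterior> %d components over %d parameters, conditioned at x = %.4g\n",
              length(x$weights), x$dim, x$conditioned_at))
  invisible(x)
}

#' Draw samples from a Gaussian-mixture posterior
#'
#' @param post A \code{mixture_posterior}.
#' @param n Number of draws.
#' @return An n x d matrix (normalised parameter space).
#' @export
sample_mixture <- function(post, n) {
  stopifnot(inherits(post, "mixture_posterior"))
  comp <- sample.int(length(post$weights), n, replace = TRUE,
                     prob = post$weights)
  out <- matrix(0, n, post$dim)
  for (c in seq_along(post$weights)) {
    idx <- which(comp == c)
    if (!length(idx)) next
    L <- chol(post$covs[[c]])
    z <- matrix(stats::rnorm(length(idx) * post$dim), length(idx))
    out[idx, ] <- sweep(z %*% L, 2, post$means[[c]], `+`)
  }
  out
}

#' Mixture density in the normalised parameter space
#'
#' @param post A \code{mixture_posterior}.
#' @param u Matrix of evaluation points (rows) or a single vector.
#' @param log Return log density?
#' @return Numeric vector of (log) densities.
#' @export
dmixture <- function(post, u, log = FALSE) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  d <- post$dim
  lds <- vapply(seq_along(post$weights), function(c) {
    ch <- chol(post$covs[[c]])
    z <- forwardsolve(t(ch), t(sweep(u, 2, post$means[[c]])))
    -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi) +
      log(post$weights[c])
  }, numeric(nrow(u)))
  lds <- matrix(lds, nrow = nrow(u))
  mx <- apply(lds, 1, max)
  out <- mx + log(rowSums(exp(lds - mx)))
  if (log) out else exp(out)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing a given probability mass, estimated from
#' sorted samples (the standard sliding-window estimator).
#'
#' @param samples Numeric vector.
#' @param prob Coverage; default 0.9.
#' @return Length-2 numeric \code{c(lower, upper)}.
#' @export
hdi_interval <- function(samples, prob = 0.9) {
  s <- sort(samples)
  n <- length(s)
  m <- max(1, floor(prob * n))
  widths <- s[(m + 1):n] - s[1:(n - m)]
  j <- which.min(widths)
  c(s[j], s[j + m])
}
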