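#' Half-uniform half-Gaussian loss kernel
#'
#' Converts simulation losses into training weights that focus the density
#' network on the low-loss region: weight 1 for losses up to the
#' pseudo-observation \code{beta}, then a half-Gaussian decay
#' \code{exp(-(loss - beta)^2 / (2 scale^2))}, with the scale set adaptively
#' to the 25th percentile of the round's losses.
#'
#' @param losses Finite numeric vector of relevant losses.
#' @param beta Pseudo-observation (kernel plateau edge).
#' @param scale Half-Gaussian scale; default the 25th percentile of
#'   \code{losses}.
#' @return Numeric vector of weights in (0, 1].
#' @export
loss_kernel <- function(losses, beta, scale = NULL) {
  if (any(!is.finite(losses))) stop("loss_kernel: losses must be finite")
  if (is.null(scale)) scale <- unname(stats::quantile(losses, 0.25))
  if (length(losses) > 1 && (length(unique(losses)) == 1 || scale <= 0))
    return(rep(1, length(losses)))
  if (scale <= 0) stop("loss_kernel: scale must be > 0")
  ifelse(losses <= beta, 1, exp(-(losses - beta)^2 / (2 * scale^2)))
}

#' Sequential neural posterior estimation for the ribbon model
#'
#' Runs the simulate-featurise-train loop: each round draws parameters from
#' the current prior (round 1: the normalised Gaussian prior; later rounds:
#' the previous round's conditioned mixture), simulates the release model on
#' the given calcium input, computes the relevant loss against the target
#' features, trains the mixture-density network on the (parameter, loss)
#' pairs under the loss-kernel weights, and conditions it at the round's
#' pseudo-observation \code{beta_n} (the 0.1th percentile of the round's
#' losses) to obtain that round's posterior.
#'
#' @param target_features Length-14 feature vector of the target trace.
#' @param normalisation Feature normalisation
#'   (\code{\link{feature_normalisation}}).
#' @param calcium Calcium input \code{\link{syn_trace}} driving every
#'   simulation.
#' @param annotations Protocol annotations for feature extraction.
#' @param prior A \code{\link{prior_spec}}; default \code{prior_spec()}.
#' @param rounds Number of rounds; default 3.
#' @param n_sims Simulations per round; default 3000.
#' @param seed Integer master seed; every stage seed derives from it.
#' @param epochs,batch_size MDN training schedule; defaults 800 / 1000.
#' @param RP_max,d_max Fixed (non-inferred) parameters for every simulation.
#' @param simulator Optional replacement simulator,
#'   \code{function(params) -> release syn_trace} (used by tests).
#' @param verbose Print per-round progress.
#' @return Object of class \code{snpe_result}: \code{posteriors} (one
#'   \code{mixture_posterior} per round), \code{rounds} (per-round records
#'   with draws, losses, beta, kernel scale, median loss), \code{final}
#'   (early-stopped posterior), \code{final_round}, and the \code{prior}.
#' @export
run_sequential_inference <- function(target_features, normalisation, calcium,
                                     annotations, prior = prior_spec(),
                                     rounds = 3, n_sims = 3000, seed = 1,
                                     epochs = 800, batch_size = 1000,
                                     RP_max = 10 * exp(2.625), d_max = 0.1,
                                     simulator = NULL, verbose = FALSE) {
  stopifnot(rounds >= 1, n_sims >= 10)
  base_seed <- as.integer(abs(seed) %% 1000003L)
  if (is.null(simulator))
    simulator <- function(params) simulate_release(params, calcium)$release
  source <- prior
  records <- list()
  posteriors <- list()
  for (n in seq_len(rounds)) {
    rseed <- base_seed * 101L + n
    draws <- sample_and_transform(source, n_sims, prior = prior, seed = rseed)
    losses <- rep(NA_real_, n_sims)
    for (i in seq_len(n_sims)) {
      li <- tryCatch({
        pp <- draw_to_params(draws$natural[i, ], RP_max = RP_max,
                             d_max = d_max)
        rel <- simulator(pp)
        sf <- extract_features(rel, annotations)
        relevant_loss(sf, target_features, normalisation)$R
      }, error = function(e) NA_real_)
      losses[i] <- li
    }
    ok <- is.finite(losses)
    if (mean(ok) < 0.5)
      stop("run_sequential_inference: simulator failure rate above 50% in round ", n)
    u <- draws$u[ok, , drop = FALSE]
    x <- losses[ok]
    beta_n <- unname(stats::quantile(x, 0.001))
    scale_n <- unname(stats::quantile(x, 0.25))
    w <- loss_kernel(x, beta_n, scale_n)
    fit <- train_mdn(u, x, weights = w, epochs = epochs,
                     batch_size = batch_size, seed = rseed + 7L)
    post <- condition_mdn(fit, beta_n)
    posteriors[[n]] <- post
    records[[n]] <- list(round = n, u = u, losses = x, beta = beta_n,
                         kernel_scale = scale_n, median_loss = stats::median(x),
                         n_failed = sum(!ok), mdn = fit)
    if (verbose)
      message(sprintf("round %d: beta=%.4g median=%.4g min=%.4g failed=%d",
                      n, beta_n, records[[n]]$median_loss, min(x), sum(!ok)))
    source <- post
  }
  sel <- select_final_posterior(records)
  structure(list(posteriors = posteriors, rounds = records,
                 final = posteriors[[sel]], final_round = sel, prior = prior,
                 seed = seed),
            class = "snpe_result")
}

#' Early-stopped posterior selection
#'
#' Returns the index of the round with the smallest median loss of its
#' samples; ties resolve to the earliest such round.
#'
#' @param rounds List of per-round records (each with \code{median_loss}).
#' @return Integer round index.
#' @export
select_final_posterior <- function(rounds) {
  stopifnot(length(rounds) >= 1)
  med <- vapply(rounds, function(r) r$median_loss, numeric(1))
  which.min(med)   # which.min takes the first of tied minima
}

#' @export
print.snpe_result <- function(x, ...) {
  med <- vapply(x$rounds, function(r) r$median_loss, numeric(1))
  cat(sprintf("<snpe_result> %d rounds; median losses: %s; final round %d\n",
              length(x$rounds), paste(signif(med, 4), collapse = ", "),
              x$final_round))
  invisible(x)
}

#' Draw natural-scale parameter samples from a posterior
#'
#' Samples the mixture in normalised space, rejects draws whose linearly
#' mapped parameters would be non-positive, and transforms to natural units.
#'
#' @param post A \code{mixture_posterior}.
#' @param n Number of samples.
#' @param prior The \code{\link{prior_spec}} defining the transform.
#' @param seed Integer seed.
#' @return List with \code{u} and \code{natural} matrices.
#' @export
posterior_samples <- function(post, n, prior = prior_spec(), seed = 1) {
  sample_and_transform(post, n, prior = prior, seed = seed)
}

#' Posterior-predictive feature check
#'
#' Simulates the model at parameters drawn from a posterior and summarises
#' the spread of derived response features (transience and sustain of each
#' flash response by default), for comparison with the target.
#'
#' @param post A \code{mixture_posterior}.
#' @param calcium Calcium input trace.
#' @param annotations Protocol annotations.
#' @param n Number of posterior draws; default 100.
#' @param prior \code{\link{prior_spec}} for the transform.
#' @param seed Integer seed.
#' @param prob Width of the prediction band; default 0.9.
#' @param RP_max,d_max Fixed parameters.
#' @return List with per-draw \code{transience} and \code{sustain} (first
#'   flash), and their central \code{prob} prediction bands.
#' @export
posterior_predictive <- function(post, calcium, annotations, n = 100,
                                 prior = prior_spec(), seed = 1, prob = 0.9,
                                 RP_max = 10 * exp(2.625), d_max = 0.1) {
  draws <- posterior_samples(post, n, prior = prior, seed = seed)
  tr <- su <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      pp <- draw_to_params(draws$natural[i, ], RP_max = RP_max, d_max = d_max)
      rel <- simulate_release(pp, calcium)$release
      mst <- max_sustain_transience(rel, annotations$dark_onsets)
      c(mst$transience[1], mst$sustain[1])
    }, error = function(e) c(NA_real_, NA_real_))
    tr[i] <- res[1]; su[i] <- res[2]
  }
  a <- (1 - prob) / 2
  list(transience = tr, sustain = su,
       transience_band = unname(stats::quantile(tr, c(a, 1 - a), na.rm = TRUE)),
       sustain_band = unname(stats::quantile(su, c(a, 1 - a), na.rm = TRUE)))
}
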