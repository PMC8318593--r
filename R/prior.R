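#' Prior over the seven free kinetic parameters
#'
#' Inference runs in a normalised parameter space where the prior is an
#' uncorrelated multivariate normal with mean 0.5 and standard deviation 0.2
#' in every dimension. Each normalised coordinate u maps to its natural-scale
#' parameter so that u = 0.5 lands on the prior mode
#' \code{(r_max, i_max, e_max, k, x0, IP_max, RRP_max) =
#' (2.5, 2.5, 10, 14, 0.5, ~13.8, ~4.0)}. Rates and non-linearity parameters
#' use a linear map (natural = 2 * mode * u); the two pool sizes use an
#' exponential map (natural = mode^(2u)), which keeps them strictly positive
#' for any draw. Because the model is scale invariant only the relative
#' values of the modes matter.
#'
#' @param modes Named vector of natural-scale prior modes.
#' @param norm_mean,norm_sd Mean and sd of the normalised prior; defaults
#'   0.5 and 0.2.
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(modes = c(r_max = 2.5, i_max = 2.5, e_max = 10,
                                 k = 14, x0 = 0.5, IP_max = exp(2.625),
                                 RRP_max = 4.0),
                       norm_mean = 0.5, norm_sd = 0.2) {
  stopifnot(all(modes > 0), norm_sd > 0)
  transform <- ifelse(names(modes) %in% c("IP_max", "RRP_max"),
                      "exponential", "linear")
  names(transform) <- names(modes)
  structure(list(modes = modes, transform = transform,
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 dim = length(modes)),
            class = "prior_spec")
}

#' Map normalised draws to natural-scale parameters
#'
#' @param u Matrix of normalised draws (rows) or a single vector.
#' @param prior A \code{\link{prior_spec}}.
#' @return Matrix of natural-scale parameter values (named columns).
#' @export
to_natural <- function(u, prior) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  stopifnot(ncol(u) == prior$dim)
  out <- u
  for (j in seq_len(prior$dim)) {
    if (prior$transform[j] == "linear") {
      out[, j] <- u[, j] * prior$modes[j] / 0.5
    } else {
      out[, j] <- exp(2 * u[, j] * log(prior$modes[j]))
    }
  }
  colnames(out) <- names(prior$modes)
  out
}

# internal: natural-scale validity of a normalised draw (positivity of the
# linearly mapped parameters; exponential ones are positive by construction)
valid_draws <- function(u, prior) {
  lin <- which(prior$transform == "linear")
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  apply(u[, lin, drop = FALSE] > 0, 1, all)
}

#' Draw parameters and map them to natural scale
#'
#' Samples normalised parameters from the prior (or from a fitted mixture
#' posterior standing in as the next round's prior), rejects draws whose
#' natural-scale rates would be non-positive, and returns both spaces.
#'
#' @param source A \code{\link{prior_spec}} or \code{mixture_posterior}.
#' @param n Number of draws.
#' @param prior The \code{prior_spec} defining the normalised-to-natural map
#'   (defaults to \code{source} when that is a \code{prior_spec}).
#' @param seed Integer seed; draws are bit-reproducible given (source, seed).
#' @return List with \code{u} (n x d normalised), \code{natural} (n x d),
#'   and \code{n_rejected}.
#' @export
sample_and_transform <- function(source, n, prior = NULL, seed = 1) {
  if (inherits(source, "prior_spec") && is.null(prior)) prior <- source
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  set.seed(seed)
  draw <- function(m) {
    if (inherits(source, "prior_spec")) {
      matrix(stats::rnorm(m * prior$dim, source$norm_mean, source$norm_sd),
             nrow = m)
    } else {
      sample_mixture(source, m)
    }
  }
  u <- matrix(numeric(0), 0, prior$dim)
  n_rejected <- 0L
  while (nrow(u) < n) {
    cand <- draw(max(n - nrow(u), 16))
    ok <- valid_draws(cand, prior)
    n_rejected <- n_rejected + sum(!ok)
    u <- rbind(u, cand[ok, , drop = FALSE])
  }
  u <- u[seq_len(n), , drop = FALSE]
  list(u = u, natural = to_natural(u, prior), n_rejected = n_rejected)
}

#' Build a \code{ribbon_params} object from one natural-scale draw
#'
#' The two fixed parameters are not part of the draw: \code{RP_max} defaults
#' to ten times the prior-mode intermediate-pool capacity and \code{d_max}
#' to 0.1/s.
#'
#' @param nat Named natural-scale vector (one row of
#'   \code{\link{to_natural}} output).
#' @param RP_max,d_max Fixed parameters.
#' @return A \code{\link{ribbon_params}}.
#' @export
draw_to_params <- function(nat, RP_max = 10 * exp(2.625), d_max = 0.1) {
  ribbon_params(r_max = nat[["r_max"]], i_max = nat[["i_max"]],
                e_max = nat[["e_max"]], k = nat[["k"]], x0 = nat[["x0"]],
                IP_max = nat[["IP_max"]], RRP_max = nat[["RRP_max"]],
                RP_max = RP_max, d_max = d_max)
}
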