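#' Names of the 14 summary features
#'
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function() {
  c("baseline_adapt",        # 1  mean during adaptation
    "baseline_bright",       # 2  mean during UV-bright periods
    "dark_mean",             # 3  mean during UV-dark periods
    "dark_max_mean",         # 4  mean over dark periods of the per-period max
    "first_max",             # 5  max amplitude, first dark flash
    "first_min",             # 6  25th percentile, first dark flash
    "second_max",            # 7  max amplitude, second dark flash
    "second_min",            # 8  25th percentile, second dark flash
    "int_first",             # 9  vesicles released during first activation
    "int_second",            # 10 vesicles released during second activation
    "int_last",              # 11 vesicles released during last activation
    "decay_tau",             # 12 exponential decay constant, first dark flash
    "decay_end",             # 13 fitted decay value at next light onset
    "decay_is_rise")         # 14 rise-instead-of-decay indicator
}

#' Exponential fit to the decay after the first dark flash
#'
#' The relaxation after the initial dark-flash transient is informative about
#' the pool sizes, so it gets dedicated features: an exponential
#' \code{c + a exp(-t/tau)} is fitted (by variable projection) to the first
#' dark period from its peak onwards; reported are the time constant, the
#' fitted value at the last sample before the next light onset, and whether
#' the fit is a rise rather than a decay (penalised later in the loss).
#'
#' @param release A \code{\link{syn_trace}} of release rates.
#' @param first_dark Length-2 numeric, [start, end] of the first dark period
#'   [s]; must span at least 0.5 s.
#' @return List with \code{tau} [s], \code{endpoint} [v.u./s], \code{is_rise}
#'   and the fit residual \code{rss}.
#' @export
fit_first_decay <- function(release, first_dark) {
  stopifnot(inherits(release, "syn_trace"))
  if (diff(first_dark) < 0.5) stop("fit_first_decay: window shorter than 0.5 s")
  tt <- trace_time(release)
  idx <- which(tt >= first_dark[1] & tt < first_dark[2])
  seg_t <- tt[idx]; seg <- release$values[idx]
  pk <- which.max(seg)
  pk <- min(pk, length(seg) - 3)   # keep a fittable tail
  ft <- expfit_varpro(seg_t[pk:length(seg)], seg[pk:length(seg)])
  endpoint <- ft$c + ft$a * exp(-(seg_t[length(seg)] - seg_t[pk]) / ft$tau)
  list(tau = ft$tau, endpoint = endpoint, is_rise = ft$a < 0, rss = ft$rss)
}

#' Extract the 14-component summary-feature vector of a release trace
#'
#' Projects a flash-protocol release trace to the low-dimensional feature
#' space used by the inference loss: baselines during adaptation and bright
#' periods, dark-period mean and mean maximal rate, maximal and minimal
#' (25th percentile) amplitudes of the first and second flash responses,
#' time-integrated release of the first, second and last activations, and
#' the first-decay fit (tau, endpoint, rise flag).
#'
#' @param release A \code{\link{syn_trace}} of release rates aligned to the
#'   protocol.
#' @param annotations Protocol annotations from
#'   \code{\link{make_flash_protocol}}; needs >= 2 dark periods.
#' @return Named numeric vector of length 14 (see
#'   \code{\link{feature_names}}); \code{decay_is_rise} is 0/1.
#' @export
extract_features <- function(release, annotations) {
  stopifnot(inherits(release, "syn_trace"))
  dark <- annotations$dark
  if (nrow(dark) < 2) stop("extract_features: need at least 2 dark periods")
  tt <- trace_time(release)
  v <- release$values
  win <- function(iv) v[tt >= iv[1] & tt < iv[2]]
  dark_segs <- lapply(seq_len(nrow(dark)), function(j) win(dark[j, ]))
  integ <- function(seg) sum(seg) * release$dt
  ft <- fit_first_decay(release, dark[1, ])
  out <- c(
    baseline_adapt = mean(win(annotations$adaptation[1, ])),
    baseline_bright = mean(unlist(lapply(seq_len(nrow(annotations$bright)),
                                         function(j) win(annotations$bright[j, ])))),
    dark_mean = mean(unlist(dark_segs)),
    dark_max_mean = mean(vapply(dark_segs, max, numeric(1))),
    first_max = max(dark_segs[[1]]),
    first_min = unname(stats::quantile(dark_segs[[1]], 0.25)),
    second_max = max(dark_segs[[2]]),
    second_min = unname(stats::quantile(dark_segs[[2]], 0.25)),
    int_first = integ(dark_segs[[1]]),
    int_second = integ(dark_segs[[2]]),
    int_last = integ(dark_segs[[length(dark_segs)]]),
    decay_tau = ft$tau,
    decay_end = ft$endpoint,
    decay_is_rise = as.numeric(ft$is_rise))
  out
}

#' Default loss weights
#'
#' The per-component weights of the relevant loss, in feature order:
#' \code{(0.5, 0.5, 5, 1, 1, 1, 1, 1, 1, 1, 2, 1, 1, w14)}. The last weight
#' is conditional on the first-decay fit of the simulated trace: 0.01 when a
#' decay was fitted, \code{10 * (1 + ceiling(tau))} when a rise was fitted
#' instead (a strong penalty for qualitatively wrong relaxation).
#'
#' @param sim_features Feature vector of the simulation (provides
#'   \code{decay_is_rise} and \code{decay_tau} for the conditional weight).
#' @return Numeric vector of 14 weights.
#' @export
loss_weights <- function(sim_features) {
  w <- c(0.5, 0.5, 5, 1, 1, 1, 1, 1, 1, 1, 2, 1, 1, NA)
  w[14] <- if (sim_features[["decay_is_rise"]] > 0.5)
    10 * (1 + ceiling(sim_features[["decay_tau"]])) else 0.01
  w
}

#' Normalisation statistics for the feature space
#'
#' Per-component mean and standard deviation computed across replicate
#' feature vectors (rows). Components with vanishing spread fall back to
#' sd 1 so they contribute the raw squared difference; the binary
#' \code{decay_is_rise} component is never rescaled.
#'
#' @param feature_matrix Matrix of feature vectors, one replicate per row.
#' @return List with \code{mean} and \code{sd} vectors (length 14).
#' @export
feature_normalisation <- function(feature_matrix) {
  feature_matrix <- as.matrix(feature_matrix)
  m <- colMeans(feature_matrix)
  s <- apply(feature_matrix, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  i14 <- length(m)
  m[i14] <- 0; s[i14] <- 1
  list(mean = m, sd = s)
}

#' Weighted relevant loss between simulated and target features
#'
#' \code{R = (1/14) * sum_i w_i ((x0_i - x_i) / sd_i)^2}: the mean of
#' weighted squared differences between the normalised feature vectors of a
#' simulation and of the target trace. Zero iff every weighted component
#' matches.
#'
#' @param sim_features,target_features Length-14 named feature vectors.
#' @param normalisation List with \code{mean}/\code{sd} from
#'   \code{\link{feature_normalisation}} (only \code{sd} enters; the means
#'   cancel in the difference).
#' @param weights Optional length-14 weights; default
#'   \code{\link{loss_weights}(sim_features)}.
#' @return List (class \code{loss_value}) with scalar \code{R} and the
#'   per-component \code{breakdown}.
#' @export
relevant_loss <- function(sim_features, target_features, normalisation,
                          weights = NULL) {
  nms <- feature_names()
  miss <- setdiff(nms, names(sim_features))
  if (length(miss)) stop("relevant_loss: missing feature(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(nms, names(target_features))
  if (length(miss)) stop("relevant_loss: target missing feature(s): ",
                         paste(miss, collapse = ", "))
  if (any(normalisation$sd <= 0)) stop("relevant_loss: normalisation sd must be > 0")
  if (is.null(weights)) weights <- loss_weights(sim_features)
  if (any(weights < 0)) stop("relevant_loss: weights must be >= 0")
  z <- (target_features[nms] - sim_features[nms]) / normalisation$sd
  comp <- weights * z^2
  structure(list(R = sum(comp) / length(nms), breakdown = comp),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> R = %.6g\n", x$R))
  invisible(x)
}
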