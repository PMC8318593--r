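#' Kinetic parameters of the three-pool ribbon release cascade
#'
#' Bundles the seven free parameters of the vesicle-pool cascade (maximal
#' transfer rates \code{r_max}, \code{i_max}, \code{e_max}; calcium
#' non-linearity slope \code{k} and operating point \code{x0}; pool capacities
#' \code{IP_max}, \code{RRP_max}) together with the two fixed parameters
#' (\code{RP_max}, the reserve-pool capacity, and \code{d_max}, the
#' endocytosis rate constant). The fixed pair does not shape the release
#' output on the tens-of-seconds timescales the model is used for, which is
#' why it is not inferred; defaults tie \code{RP_max} to ten times the
#' intermediate-pool capacity.
#'
#' Units are arbitrary vesicle units (v.u.) for capacities, v.u./s for rates,
#' and calcium units (c.u.) for \code{x0} (with \code{k} in 1/c.u.): the model
#' is scale invariant, so only relative values are meaningful.
#'
#' @param r_max Maximal reserve-to-intermediate transfer rate [v.u./s].
#' @param i_max Maximal intermediate-to-RRP transfer rate [v.u./s].
#' @param e_max Maximal release rate [v.u./s].
#' @param k Slope of the sigmoidal calcium non-linearity [1/c.u.].
#' @param x0 Operating point of the non-linearity [c.u.]; the release fraction
#'   equals 0.5 at calcium \code{x0}.
#' @param IP_max Intermediate (ribbon-tethered) pool capacity [v.u.].
#' @param RRP_max Readily releasable pool capacity [v.u.].
#' @param RP_max Reserve pool capacity [v.u.] (fixed; default 10 * IP_max).
#' @param d_max Endocytosis rate constant [1/s] (fixed; default 0.1).
#' @return An object of class \code{ribbon_params}.
#' @examples
#' p <- ribbon_params(r_max = 2.5, i_max = 2.5, e_max = 10, k = 14,
#'                    x0 = 0.5, IP_max = 13.8, RRP_max = 4)
#' @export
ribbon_params <- function(r_max, i_max, e_max, k, x0, IP_max, RRP_max,
                          RP_max = 10 * IP_max, d_max = 0.1) {
  p <- list(r_max = r_max, i_max = i_max, e_max = e_max, k = k, x0 = x0,
            IP_max = IP_max, RRP_max = RRP_max, RP_max = RP_max,
            d_max = d_max)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("ribbon_params: all parameters must be finite")
  pos <- c("r_max", "i_max", "e_max", "k", "IP_max", "RRP_max", "RP_max",
           "d_max")
  if (any(vals[pos] <= 0))
    stop("ribbon_params: ", paste(pos[vals[pos] <= 0], collapse = ", "),
         " must be > 0")
  if (x0 <= 0) stop("ribbon_params: x0 must be > 0")
  structure(p, class = "ribbon_params")
}

#' @export
print.ribbon_params <- function(x, ...) {
  cat("<ribbon_params>\n")
  cat(sprintf("  rates   : r_max=%.4g i_max=%.4g e_max=%.4g [v.u./s]\n",
              x$r_max, x$i_max, x$e_max))
  cat(sprintf("  sigmoid : k=%.4g [1/c.u.]  x0=%.4g [c.u.]\n", x$k, x$x0))
  cat(sprintf("  pools   : IP_max=%.4g RRP_max=%.4g RP_max=%.4g [v.u.]\n",
              x$IP_max, x$RRP_max, x$RP_max))
  cat(sprintf("  fixed   : d_max=%.4g [1/s]\n", x$d_max))
  invisible(x)
}

# internal: parameter vector in the order the C++ solver expects
params_vec <- function(p) {
  stopifnot(inherits(p, "ribbon_params"))
  c(p$r_max, p$i_max, p$e_max, p$k, p$x0, p$IP_max, p$RRP_max, p$RP_max,
    p$d_max)
}

#' Scale a parameter set by a common factor
#'
#' Multiplies every rate and capacity by \code{lam} while leaving the
#' non-linearity parameters \code{k} and \code{x0} untouched. Because the pool
#' equations are linear in occupancies and rates, the release output of the
#' scaled model is exactly \code{lam} times the original: the vesicle-unit
#' scale is arbitrary.
#'
#' @param params A \code{\link{ribbon_params}} object.
#' @param lam Positive scale factor.
#' @return The scaled \code{ribbon_params}.
#' @export
scale_params <- function(params, lam) {
  stopifnot(inherits(params, "ribbon_params"))
  if (!is.finite(lam) || lam <= 0) stop("scale_params: lam must be > 0")
  ribbon_params(r_max = params$r_max * lam, i_max = params$i_max * lam,
                e_max = params$e_max * lam, k = params$k, x0 = params$x0,
                IP_max = params$IP_max * lam, RRP_max = params$RRP_max * lam,
                RP_max = params$RP_max * lam, d_max = params$d_max)
}

#' Reduced parameterisation with pool-coupled rates
#'
#' In the reduced model used for tuning maps, the sigmoid slope is fixed at
#' \code{k = 10.2} (the across-region mean of fitted slopes) and the maximal
#' transfer rates are tied to the pool sizes: \code{r_max = 0.2 * IP_max},
#' \code{i_max = 0.4 * IP_max}, \code{e_max = e_tilde_max * RRP_max} with the
#' release fraction \code{e_tilde_max} in [0, 1]. \code{tau_decay} is the
#' decay constant of the calcium kernel used with this model.
#'
#' @param IP_max Intermediate pool capacity [v.u.].
#' @param RRP_max Readily releasable pool capacity [v.u.].
#' @param e_tilde_max Maximal release fraction in [0, 1].
#' @param x0 Non-linearity operating point [c.u.].
#' @param tau_decay Calcium kernel decay constant [s].
#' @return An object of class \code{simplified_params}.
#' @export
simplified_params <- function(IP_max, RRP_max, e_tilde_max, x0,
                              tau_decay = 0.3) {
  if (e_tilde_max < 0 || e_tilde_max > 1)
    stop("simplified_params: e_tilde_max must lie in [0, 1]")
  if (any(c(IP_max, RRP_max, x0, tau_decay) <= 0))
    stop("simplified_params: IP_max, RRP_max, x0, tau_decay must be > 0")
  structure(list(IP_max = IP_max, RRP_max = RRP_max,
                 e_tilde_max = e_tilde_max, x0 = x0, tau_decay = tau_decay),
            class = "simplified_params")
}

#' Expand reduced parameters to the full kinetic parameter set
#'
#' @param sp A \code{\link{simplified_params}} object.
#' @param RP_max,d_max Values for the fixed parameters; defaults as in
#'   \code{\link{ribbon_params}}.
#' @return A \code{\link{ribbon_params}} object with \code{k = 10.2} and the
#'   coupled rates.
#' @examples
#' expand_simplified(simplified_params(10, 4, 0.5, x0 = 0.5))
#' @export
expand_simplified <- function(sp, RP_max = 10 * sp$IP_max, d_max = 0.1) {
  stopifnot(inherits(sp, "simplified_params"))
  e_max <- sp$e_tilde_max * sp$RRP_max
  # e_tilde_max = 0 is a legitimate degenerate synapse (no release); keep the
  # simulator happy with an epsilon rate that releases nothing measurable
  if (e_max == 0) e_max <- .Machine$double.eps
  ribbon_params(r_max = 0.2 * sp$IP_max, i_max = 0.4 * sp$IP_max,
                e_max = e_max, k = 10.2, x0 = sp$x0, IP_max = sp$IP_max,
                RRP_max = sp$RRP_max, RP_max = RP_max, d_max = d_max)
}

#' Read or write kinetic parameters as flat JSON
#'
#' @param params A \code{ribbon_params} or \code{simplified_params} object.
#' @param path File path.
#' @return \code{read_params_json} returns the reconstructed object.
#' @export
write_params_json <- function(params, path) {
  x <- unclass(params)
  x$.class <- class(params)[1]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "simplified_params")) {
    do.call(simplified_params, x)
  } else {
    do.call(ribbon_params, x)
  }
}
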