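#' Sigmoidal calcium dependence of vesicle release
#'
#' The release fraction is \code{f(Ca) = 1 / (1 + exp(-k * (Ca - x0)))}: a
#' logistic function of intracellular calcium with slope \code{k} and
#' operating point \code{x0}, at which \code{f(x0) = 0.5}. \code{x0} acts as
#' an inverted baseline: the smaller it is, the less extra calcium is needed
#' to trigger release.
#'
#' @param ca Calcium level(s) [c.u.]; scalar or vector.
#' @param k Slope [1/c.u.], > 0.
#' @param x0 Operating point [c.u.].
#' @return Release fraction(s) in (0, 1).
#' @examples
#' release_nonlinearity(0.5, k = 10.2, x0 = 0.5)  # 0.5 by construction
#' @export
release_nonlinearity <- function(ca, k, x0) {
  if (any(!is.finite(ca))) stop("release_nonlinearity: ca must be finite")
  if (!is.finite(k) || k <= 0) stop("release_nonlinearity: k must be > 0")
  1 / (1 + exp(-k * (ca - x0)))
}

#' Instantaneous pool-transfer fluxes
#'
#' Evaluates the four fluxes of the cascade at a given pool state and calcium
#' level: \code{r = r_max (1 - IP/IP_max) RP/RP_max} (reserve to
#' intermediate), \code{i = i_max (1 - RRP/RRP_max) IP/IP_max} (intermediate
#' to readily releasable), \code{e = e_max f(Ca) RRP/RRP_max} (exocytosis) and
#' \code{d = d_max Exo} (endocytotic recycling). Upstream transfer stalls when
#' the receiving pool is full and when the donating pool is empty.
#'
#' @param state Named numeric vector or list with \code{RP}, \code{IP},
#'   \code{RRP}, \code{Exo} occupancies [v.u.].
#' @param ca Calcium level [c.u.].
#' @param params A \code{\link{ribbon_params}} object.
#' @param tol Relative tolerance on occupancy bound violations before an error
#'   is raised (guards against a blown-up solver state).
#' @return Named numeric vector \code{c(r, i, e, d)} [v.u./s].
#' @export
pool_fluxes <- function(state, ca, params, tol = 1e-6) {
  stopifnot(inherits(params, "ribbon_params"))
  s <- unlist(state)[c("RP", "IP", "RRP", "Exo")]
  caps <- c(params$RP_max, params$IP_max, params$RRP_max, Inf)
  if (any(s < -tol * c(caps[1:3], 1)) || any(s[1:3] > caps[1:3] * (1 + tol)))
    stop("pool_fluxes: occupancy outside [0, capacity] beyond tolerance")
  s <- pmin(pmax(s, 0), caps)
  r <- params$r_max * (1 - s[["IP"]] / params$IP_max) * s[["RP"]] / params$RP_max
  i <- params$i_max * (1 - s[["RRP"]] / params$RRP_max) * s[["IP"]] / params$IP_max
  e <- params$e_max * release_nonlinearity(ca, params$k, params$x0) *
    s[["RRP"]] / params$RRP_max
  d <- params$d_max * s[["Exo"]]
  c(r = r, i = i, e = e, d = d)
}

#' Simulate glutamate release driven by a calcium trace
#'
#' Integrates the three-pool cascade with an explicit adaptive Runge-Kutta
#' 3(2) (Bogacki-Shampine) scheme whose maximal step equals the calcium grid
#' spacing; calcium is linearly interpolated between samples. By default the
#' pools are first relaxed to their steady state at the first calcium sample
#' ("burn-in"), mirroring the adaptation period that precedes a recording.
#'
#' @param params A \code{\link{ribbon_params}} object.
#' @param calcium A \code{\link{syn_trace}} of kind "calcium" (any kind is
#'   accepted; values are read as c.u.).
#' @param init Initial-state policy: \code{"burnin"} (default; full pools,
#'   then relaxation at the first calcium value until the state change over
#'   one second falls below 1e-8 of the total vesicle count), \code{"full"}
#'   (RP, IP, RRP at capacity, Exo = 0), or a numeric vector
#'   \code{c(RP, IP, RRP, Exo)}.
#' @param rtol,atol Solver tolerances.
#' @return An object of class \code{pool_trajectory}: a list with
#'   \code{time}, occupancies \code{RP}, \code{IP}, \code{RRP}, \code{Exo}
#'   [v.u.], fluxes \code{r}, \code{i}, \code{e}, \code{d} [v.u./s], and the
#'   release trace as \code{release} (a \code{syn_trace} on the calcium grid).
#' @export
simulate_release <- function(params, calcium, init = "burnin",
                             rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(params, "ribbon_params"), inherits(calcium, "syn_trace"))
  pv <- params_vec(params)
  y_full <- c(params$RP_max, params$IP_max, params$RRP_max, 0)
  if (is.character(init)) {
    init <- match.arg(init, c("burnin", "full"))
    y0 <- if (init == "burnin") {
      ribbon_burnin_cpp(calcium$values[1], pv, y_full, rtol, atol,
                        tol_rel = 1e-8, max_time = 2000)
    } else {
      y_full
    }
  } else {
    stopifnot(is.numeric(init), length(init) == 4)
    y0 <- as.numeric(init)
  }
  m <- ribbon_ode_cpp(calcium$t0, calcium$dt, calcium$values, pv, y0,
                      rtol, atol)
  traj <- list(time = trace_time(calcium),
               RP = m[, "RP"], IP = m[, "IP"], RRP = m[, "RRP"],
               Exo = m[, "Exo"], r = m[, "r"], i = m[, "i"], e = m[, "e"],
               d = m[, "d"],
               release = syn_trace(m[, "e"], dt = calcium$dt,
                                   t0 = calcium$t0, kind = "release"),
               params = params, init = y0)
  class(traj) <- "pool_trajectory"
  traj
}

#' @export
print.pool_trajectory <- function(x, ...) {
  cat(sprintf("<pool_trajectory> %d samples over %.3g s; final release %.4g v.u./s\n",
              length(x$time), x$time[length(x$time)] - x$time[1],
              x$e[length(x$e)]))
  invisible(x)
}

#' @export
as.data.frame.pool_trajectory <- function(x, ...) {
  data.frame(time = x$time, RP = x$RP, IP = x$IP, RRP = x$RRP, Exo = x$Exo,
             r = x$r, i = x$i, e = x$e, d = x$d)
}

#' Algebraic steady state of the cascade at constant calcium
#'
#' At a constant calcium level every pool settles to the occupancy at which
#' all four fluxes equal a common throughput \code{phi}. This function finds
#' that fixed point by one-dimensional root solving of the vesicle-number
#' conservation constraint in \code{phi} -- a route fully independent of the
#' time-stepping simulator, useful as a cross-check and for steady-state
#' tuning curves.
#'
#' @param params A \code{\link{ribbon_params}} object.
#' @param ca Constant calcium level [c.u.].
#' @param total Total vesicle count; defaults to full pools
#'   (RP_max + IP_max + RRP_max).
#' @return List with occupancies \code{RP}, \code{IP}, \code{RRP}, \code{Exo}
#'   and the common flux \code{phi} (the steady-state release rate).
#' @export
steady_state_release <- function(params, ca,
                                 total = params$RP_max + params$IP_max +
                                   params$RRP_max) {
  stopifnot(inherits(params, "ribbon_params"))
  f <- release_nonlinearity(ca, params$k, params$x0)
  occ <- function(phi) {
    RRP <- phi * params$RRP_max / (params$e_max * f)
    Exo <- phi / params$d_max
    IP <- phi * params$IP_max / (params$i_max * (1 - RRP / params$RRP_max))
    RP <- phi * params$RP_max / (params$r_max * (1 - IP / params$IP_max))
    c(RP = RP, IP = IP, RRP = RRP, Exo = Exo)
  }
  # admissibility bound: IP(phi) < IP_max iff phi < phi_star; every occupancy
  # is strictly increasing in phi on (0, phi_star), and the total diverges at
  # phi_star, so the conservation gap g has a unique root in that interval
  g <- function(phi) sum(occ(phi)) - total
  phi_star <- params$i_max * params$e_max * f / (params$e_max * f + params$i_max)
  phi_hi <- NA_real_
  for (eps in 10^-(3:14)) {
    cand <- phi_star * (1 - eps)
    o <- occ(cand)
    if (all(is.finite(o)) && o[["RRP"]] < params$RRP_max &&
        o[["IP"]] < params$IP_max && g(cand) > 0) {
      phi_hi <- cand
      break
    }
  }
  if (!is.finite(phi_hi))
    stop("steady_state_release: could not bracket the fixed point")
  sol <- stats::uniroot(g, c(1e-300, phi_hi), tol = 1e-14)
  o <- occ(sol$root)
  list(RP = o[["RP"]], IP = o[["IP"]], RRP = o[["RRP"]], Exo = o[["Exo"]],
       phi = sol$root)
}
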