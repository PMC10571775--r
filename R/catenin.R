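#' Equilibrium occupancies of the three alpha-catenin states
#'
#' For the linear chain C1 <-> C2 <-> C3 detailed balance gives occupancy
#' ratios `C1 : C2 : C3 = 1 : u1/f1 : (u1 u2)/(f1 f2)`, normalized to sum to
#' one. This equals the long-time limit of the kinetic equations integrated by
#' [relax_catenin()].
#'
#' @inheritParams transition_rates
#' @return Named numeric vector `c(C1, C2, C3)` summing to 1.
#' @export
equilibrium_occupancy <- function(f, params = bell_params(), V = 0) {
  r <- transition_rates(f, params, V)
  # log-scale weights: ratios can overflow at large force
  lw <- c(0,
          log(r[["u1"]]) - log(r[["f1"]]),
          log(r[["u1"]]) + log(r[["u2"]]) - log(r[["f1"]]) - log(r[["f2"]]))
  w <- exp(lw - max(lw))
  out <- w / sum(w)
  names(out) <- c("C1", "C2", "C3")
  out
}

catenin_kinetic_rhs <- function(t, y, r) {
  list(c(-r[["u1"]] * y[1] + r[["f1"]] * y[2],
         r[["u1"]] * y[1] - (r[["f1"]] + r[["u2"]]) * y[2] + r[["f2"]] * y[3],
         r[["u2"]] * y[2] - r[["f2"]] * y[3]))
}

#' Relaxation of the three-state kinetics and settling time
#'
#' Integrates the kinetic equations of the C1 <-> C2 <-> C3 chain at a fixed
#' force from an arbitrary initial occupancy and reports the settling time:
#' the first time after which every occupancy stays within `settle_tol` (an
#' absolute occupancy deviation, default 0.01, i.e. 1% of the total) of its
#' equilibrium value.
#'
#' @inheritParams transition_rates
#' @param initial Initial occupancy triple, must sum to 1 (default: fully
#'   folded `c(1, 0, 0)`).
#' @param horizon Integration horizon in seconds.
#' @param settle_tol Absolute occupancy tolerance defining "settled".
#' @param dt Output time step (s).
#' @return A list with `trajectory` (data.frame: time, C1, C2, C3),
#'   `settling_time` (s), `equilibrium`, and `settled` (FALSE when the horizon
#'   was too short, in which case `settling_time` is the horizon).
#' @export
relax_catenin <- function(f, params = bell_params(), V = 0,
                          initial = c(1, 0, 0), horizon = 20,
                          settle_tol = 0.01, dt = 0.001) {
  if (length(initial) != 3L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8)
    stop("`initial` must be three non-negative occupancies summing to 1",
         call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  r <- transition_rates(f, params, V)
  eq <- equilibrium_occupancy(f, params, V)
  times <- seq(0, horizon, by = dt)
  sol <- deSolve::ode(y = as.numeric(initial), times = times,
                      func = catenin_kinetic_rhs, parms = r,
                      method = "lsoda", atol = 1e-12, rtol = 1e-10)
  occ <- sol[, 2:4, drop = FALSE]
  dev <- pmax(abs(occ[, 1] - eq[1]), abs(occ[, 2] - eq[2]),
              abs(occ[, 3] - eq[3]))
  outside <- which(dev > settle_tol)
  if (length(outside) == 0L) {
    settling <- 0
    settled <- TRUE
  } else if (max(outside) == length(times)) {
    settling <- horizon
    settled <- FALSE
    warning("horizon shorter than settling time; returning horizon",
            call. = FALSE)
  } else {
    settling <- times[max(outside) + 1L]
    settled <- TRUE
  }
  traj <- data.frame(time = sol[, 1], C1 = occ[, 1], C2 = occ[, 2],
                     C3 = occ[, 3])
  list(trajectory = traj, settling_time = settling, equilibrium = eq,
       settled = settled)
}

#' Steady-state Jub bound to junctional alpha-catenin
#'
#' Each alpha-catenin molecule in state `s` carries one Jub binding site with
#' dissociation constant `jub_K[s]`. With `n_cat` molecules at the node
#' distributed over the equilibrium occupancies, bound Jub follows from
#' simultaneous binding equilibria sharing one free-Jub pool:
#' `bound_s = n_cat * C_s * Jfree / (K_s + Jfree)`, with `Jfree` solving the
#' conservation `jub_pool = Jfree + sum_s bound_s`. Vinculin enters only
#' through the occupancies (it does not alter Jub binding itself).
#'
#' Because the M1-exposed state C2 has the weakest affinity and the fully
#' unfolded C3 the strongest, bound Jub is high at zero force (C1), dips at
#' intermediate forces where C2 dominates, and is maximal at high force.
#'
#' @inheritParams transition_rates
#' @param jub_pool Total Jub available at the node (same units as `jub_K`).
#' @param n_cat Total alpha-catenin at the node (molecules/node); defaults to
#'   `params$n_cat`.
#' @param occupancy Optional occupancy triple overriding the equilibrium at
#'   `f` (used by the coupled model to reuse precomputed occupancies).
#' @return Named numeric vector `c(bound, free)`.
#' @export
bound_jub <- function(f, params = bell_params(), V = 0,
                      jub_pool = 30, n_cat = params$n_cat,
                      occupancy = NULL) {
  if (jub_pool < 0) stop("`jub_pool` must be non-negative", call. = FALSE)
  if (jub_pool == 0) return(c(bound = 0, free = 0))
  occ <- if (is.null(occupancy)) equilibrium_occupancy(f, params, V) else occupancy
  sites <- n_cat * occ
  K <- params$jub_K
  imbalance <- function(Jf) jub_pool - Jf - sum(sites * Jf / (K + Jf))
  Jf <- uniroot(imbalance, c(0, jub_pool), tol = 1e-12)$root
  b <- sum(sites * Jf / (K + Jf))
  c(bound = b, free = Jf)
}

#' Force at which two equilibrium occupancies cross
#'
#' Finds by bisection (to 0.01 pN) the force where the named pair of
#' equilibrium occupancies are equal: `"C1C2"` locates the unfolding of the
#' M1 domain, `"C2C3"` the unfolding of M2/M3. The C1-C2 crossover decreases
#' with Vinculin (Vinculin inhibits refolding of C2); the C2-C3 crossover is
#' Vinculin-independent.
#'
#' @param which `"C1C2"` or `"C2C3"`.
#' @inheritParams transition_rates
#' @param bracket Search interval in pN.
#' @param tol Bisection tolerance (pN).
#' @return Crossover force in pN.
#' @export
crossover_force <- function(which = c("C1C2", "C2C3"),
                            params = bell_params(), V = 0,
                            bracket = c(0, 50), tol = 0.01) {
  which <- match.arg(which)
  gap <- function(f) {
    occ <- equilibrium_occupancy(f, params, V)
    if (which == "C1C2") occ[["C1"]] - occ[["C2"]] else occ[["C2"]] - occ[["C3"]]
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- gap(lo); ghi <- gap(hi)
  if (sign(glo) == sign(ghi))
    stop(sprintf("no %s crossover in [%g, %g] pN", which, lo, hi),
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- gap(mid)
    if (gm == 0) return(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid; glo <- gm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
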