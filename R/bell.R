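#' Bell-model parameters for the three-state alpha-catenin module
#'
#' Alpha-catenin in the cadherin-catenin complex (CCC) is modelled as a linear
#' three-state chain C1 (fully folded) <-> C2 (M1 exposed) <-> C3 (M2/M3 also
#' unfolded). Transition rates follow Bell's model: unfolding rates grow
#' exponentially with the per-molecule force, folding rates shrink
#' exponentially (see [transition_rates()]).
#'
#' The shipped defaults are calibrated (see
#' `system.file("scripts", "calibrate-bell.R", package = "hippomech")`) so
#' that, at zero Vinculin,
#'
#' * the equilibrium C1-C2 crossover sits at 4.5 pN,
#' * the C2-C3 crossover sits at 10 pN,
#' * relaxation from the fully folded state near the first crossover settles
#'   in 2-4 s, and
#' * the bound-Jub minimum over 0-15 pN lies between 5 and 9 pN.
#'
#' @param kf10,ku10 Zero-force folding/unfolding rates of the C1<->C2
#'   transition (1/s).
#' @param kf20,ku20 Zero-force folding/unfolding rates of the C2<->C3
#'   transition (1/s).
#' @param xf1,xu1,xf2,xu2 Folding/unfolding transition distances (nm).
#' @param kBT Thermal energy (pN nm); 4.1 corresponds to 25 degrees C.
#' @param KV Vinculin half-saturation of the C2->C1 refolding inhibition
#'   (relative Vinculin units): the C2->C1 folding rate is multiplied by
#'   `1 / (1 + V / KV)`.
#' @param tau0,E0,gamma Parameters of the classical Bell bond-lifetime form
#'   `tau = tau0 * exp((E0 - gamma * F) / kBT)` exposed by [bell_lifetime()];
#'   `tau0` in s, `E0` in pN nm, `gamma` in nm. Not used by the three-state
#'   kinetics.
#' @param jub_K Dissociation constants of Jub for alpha-catenin in states
#'   C1, C2, C3 (same units as the Jub pool passed to [bound_jub()]).
#'   Affinities order a3 > a1 > a2: M1 exposure (C2) inhibits Jub binding,
#'   full unfolding (C3) enhances it.
#' @param n_cat Default total alpha-catenin per node (molecules/node).
#' @return An object of class `"bell_params"` (a validated list).
#' @seealso [transition_rates()], [equilibrium_occupancy()], [bound_jub()]
#' @export
bell_params <- function(kf10 = 0.25 * exp(9 / 4.1),
                        ku10 = 0.25,
                        kf20 = 0.05 * exp(20 / 4.1),
                        ku20 = 0.05,
                        xf1 = 1, xu1 = 1, xf2 = 1, xu2 = 1,
                        kBT = 4.1,
                        KV = 2,
                        tau0 = 1e-4, E0 = 20, gamma = 1,
                        jub_K = c(C1 = 10 / 3, C2 = 50, C3 = 5 / 4),
                        n_cat = 30) {
  p <- list(kf10 = kf10, ku10 = ku10, kf20 = kf20, ku20 = ku20,
            xf1 = xf1, xu1 = xu1, xf2 = xf2, xu2 = xu2,
            kBT = kBT, KV = KV, tau0 = tau0, E0 = E0, gamma = gamma,
            jub_K = jub_K, n_cat = n_cat)
  pos <- c("kf10", "ku10", "kf20", "ku20", "xf1", "xu1", "xf2", "xu2",
           "kBT", "KV", "tau0", "gamma", "n_cat")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  if (length(p$jub_K) != 3L || any(p$jub_K <= 0))
    stop("`jub_K` must be three positive dissociation constants", call. = FALSE)
  names(p$jub_K) <- c("C1", "C2", "C3")
  structure(p, class = "bell_params")
}

#' @export
print.bell_params <- function(x, ...) {
  cat("Three-state alpha-catenin Bell parameters\n")
  cat(sprintf("  C1<->C2: kf0 = %.4g, ku0 = %.4g 1/s, xf = %.3g, xu = %.3g nm\n",
              x$kf10, x$ku10, x$xf1, x$xu1))
  cat(sprintf("  C2<->C3: kf0 = %.4g, ku0 = %.4g 1/s, xf = %.3g, xu = %.3g nm\n",
              x$kf20, x$ku20, x$xf2, x$xu2))
  cat(sprintf("  kBT = %.3g pN nm, Vinculin KV = %.3g\n", x$kBT, x$KV))
  cat(sprintf("  Jub K (C1, C2, C3) = %.3g, %.3g, %.3g; n_cat = %g molecules/node\n",
              x$jub_K[1], x$jub_K[2], x$jub_K[3], x$n_cat))
  invisible(x)
}

#' Bell bond lifetime
#'
#' Classical exponential force dependence of a molecular bond lifetime,
#' `tau = tau0 * exp((E0 - gamma * F) / kBT)`. Exposed as a utility; the
#' three-state kinetics use the rate form in [transition_rates()] instead.
#'
#' @param F Applied force per bond (pN, >= 0); vectorized.
#' @param params A [bell_params()] object supplying `tau0`, `E0`, `gamma`,
#'   `kBT`.
#' @return Lifetime in seconds, strictly decreasing in `F`.
#' @examples
#' p <- bell_params()
#' bell_lifetime(p$E0 / p$gamma, p)  # equals tau0
#' @export
bell_lifetime <- function(F, params = bell_params()) {
  stopifnot(inherits(params, "bell_params"))
  if (any(F < 0)) stop("force must be non-negative", call. = FALSE)
  params$tau0 * exp((params$E0 - params$gamma * F) / params$kBT)
}

#' Force-dependent transition rates of the three-state chain
#'
#' Unfolding rates `ku_i(f) = ku_i0 * exp(f * xu_i / kBT)` increase with
#' force; folding rates `kf_i(f) = kf_i0 * exp(-f * xf_i / kBT)` decrease.
#' Vinculin binds the exposed M1 domain and hinders refolding of C2 to C1:
#' `kf1` is additionally multiplied by `1 / (1 + V / KV)` (equal to 1 at
#' `V = 0`). `ku1`, `ku2` and `kf2` are Vinculin-independent.
#'
#' @param f Per-molecule force (pN, >= 0), scalar.
#' @param params A [bell_params()] object.
#' @param V Relative Vinculin level (>= 0).
#' @return Named numeric vector `c(u1, f1, u2, f2)` in 1/s: `u1` drives
#'   C1 -> C2, `f1` C2 -> C1, `u2` C2 -> C3, `f2` C3 -> C2.
#' @export
transition_rates <- function(f, params = bell_params(), V = 0) {
  stopifnot(inherits(params, "bell_params"))
  if (length(f) != 1L || is.na(f) || f < 0)
    stop("`f` must be a single non-negative force", call. = FALSE)
  if (length(V) != 1L || is.na(V) || V < 0)
    stop("`V` must be a single non-negative level", call. = FALSE)
  kBT <- params$kBT
  c(u1 = params$ku10 * exp(f * params$xu1 / kBT),
    f1 = params$kf10 * exp(-f * params$xf1 / kBT) / (1 + V / params$KV),
    u2 = params$ku20 * exp(f * params$xu2 / kBT),
    f2 = params$kf20 * exp(-f * params$xf2 / kBT))
}
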