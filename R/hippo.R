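#' Cell geometry for the Hippo membrane-region model
#'
#' A cell is modelled with one well-mixed cytosol and `n_regions` membrane
#' regions (one per junctional edge; a hexagonal wing-disc cell has 6).
#' Fat-Dachsous trans-dimers require an apposed membrane on the adjacent
#' cell. Two closures are supported per region:
#'
#' * `"self"` - mean-field closure for a uniform tissue: the apposed cell is
#'   statistically identical, so the neighbour's membrane concentrations are
#'   taken equal to the region's own. This is the default used throughout the
#'   scans and the coupled model, where all cells share the same Fat/Ds
#'   parameterization.
#' * `"isolated"` - no apposed membrane, no trans binding.
#'
#' @param n_regions Number of membrane regions (>= 1).
#' @param neighbor Character vector (length 1 or `n_regions`) of
#'   `"self"`/`"isolated"`.
#' @return Object of class `"cell_geometry"`.
#' @export
cell_geometry <- function(n_regions = 6, neighbor = "self") {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 1 ||
      n_regions != round(n_regions))
    stop("`n_regions` must be a positive integer", call. = FALSE)
  neighbor <- rep_len(as.character(neighbor), n_regions)
  if (!all(neighbor %in% c("self", "isolated")))
    stop("`neighbor` entries must be \"self\" or \"isolated\"", call. = FALSE)
  structure(list(n_regions = as.integer(n_regions), neighbor = neighbor),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cell geometry: %d membrane regions (%s)\n", x$n_regions,
              paste(unique(x$neighbor), collapse = "/")))
  invisible(x)
}

# species bookkeeping ---------------------------------------------------------

.hippo_cyt <- c("Fat_c", "Ds_c", "Fj_c", "Dachs_c", "Riq_c", "Ex_c", "Wts_c",
                "Yki_a", "Yki_p")
.hippo_mem <- c("Fat_m", "Ds_m", "FatDs", "DsFat", "Dachs_m", "Riq_m",
                "Ex_m", "WA", "WR", "EW")

hippo_state_names <- function(geometry) {
  c(.hippo_cyt,
    as.vector(t(outer(.hippo_mem, seq_len(geometry$n_regions),
                      function(s, j) paste0(s, ".", j)))))
}

#' Parameters of the upstream Hippo network
#'
#' Rates are in 1/min or 1/(nM min); concentrations in nM. The network
#' comprises:
#'
#' * constant production (`prod`) and first-order degradation (`deg`) of the
#'   cytosolic species Fat, Ds, Fj, Dachs, Riq, Ex, Wts and Yki (Yki is
#'   produced in its active form; both Yki forms degrade);
#' * membrane delivery/recycling of Fat, Ds and Ex (`kFm`/`kFr`, `kDm`/`kDr`,
#'   `kEm`/`kEr`), delivery split equally over the regions;
#' * Fat-Ds trans-dimerization (`kFD`, `kFDr`); cytosolic Four-jointed
#'   multiplies the on-rate by a saturating factor `1 + aF * Fj/(KFj + Fj)`
#'   through Fat (>= 1) and `1 / (1 + aD * Fj/(KFj + Fj))` through Ds
#'   (<= 1, never 0). Dimerized Fat/Ds does not recycle;
#' * Dachs membrane binding (`kAm`, off `kAr`) scaled by a decreasing Hill
#'   function (`KFA`, `nFA`) of total membrane Fat in the region (free +
#'   dimer), subsuming the Dlish/App route; Riquiqui membrane binding
#'   (`kRm`, `kRr`) scaled by an increasing Hill function (`KDR`, `nDR`) of
#'   total membrane Ds;
#' * reversible Wts binding to membrane Dachs (`kWAp`/`kWAm`), Riq
#'   (`kWRp`/`kWRm`) and Ex (`kEWp`/`kEWm`); Dachs-bound Wts is degraded at
#'   `kdWA` (Dachs released), Riq-bound Wts is inactivated at `kiWR`
#'   (Minibrain's action folded into the rate constant, Riq released);
#' * active Wts equals the summed Ex-Wts complex; it phosphorylates Yki at
#'   `kYp`, reversed at `kYd`; membrane Ex additionally inactivates Yki
#'   directly at `kEY` (modelled as flux into the inactive Yki pool);
#' * optional stabilization of membrane Ex by Fat
#'   (`ex_stabilization_mode = "fat_stabilizes_ex"`): the Ex recycling rate is
#'   divided by `1 + sE * FatTot/(KE + FatTot)`.
#'
#' Default values are chosen so that at baseline all binding equilibria sit
#' mid-range (complex fractions roughly 0.2-0.8) and the canonical
#' Fat-production scan monotonicities hold over a 10-fold range.
#'
#' @param prod,deg Named numeric vectors of production (nM/min) and
#'   degradation (1/min) rates for `Fat`, `Ds`, `Fj`, `Dachs`, `Riq`, `Ex`,
#'   `Wts`, `Yki`.
#' @param kFm,kFr,kDm,kDr,kEm,kEr Membrane delivery/recycling rates (1/min).
#' @param kFD,kFDr Fat-Ds trans-dimer on rate (1/(nM min)) and off rate
#'   (1/min).
#' @param aF,aD,KFj Four-jointed modulation amplitudes and half-saturation
#'   (nM).
#' @param kAm,kAr,KFA,nFA Dachs membrane binding/unbinding and the Fat
#'   inhibition Hill constants.
#' @param kRm,kRr,KDR,nDR Riq membrane binding/unbinding and the Ds promotion
#'   Hill constants.
#' @param kWAp,kWAm,kWRp,kWRm,kEWp,kEWm Wts binding/unbinding rates to
#'   membrane Dachs, Riq and Ex.
#' @param kdWA Dachs-mediated Wts degradation (1/min).
#' @param kiWR Riq/Mnb-mediated Wts inactivation (1/min).
#' @param kYp Yki phosphorylation per nM of active Wts (1/(nM min)).
#' @param kYd Yki dephosphorylation (1/min).
#' @param kEY Direct Yki inhibition per nM of total membrane Ex
#'   (1/(nM min)).
#' @param ex_stabilization_mode `"parallel"` (Fat and Ex act independently) or
#'   `"fat_stabilizes_ex"`.
#' @param sE,KE Amplitude and half-saturation (nM) of the Fat-dependent Ex
#'   stabilization.
#' @return Object of class `"hippo_params"`.
#' @export
hippo_params <- function(prod = c(Fat = 2, Ds = 2, Fj = 2, Dachs = 2,
                                  Riq = 2, Ex = 2, Wts = 2, Yki = 2),
                         deg = c(Fat = 0.2, Ds = 0.2, Fj = 0.2, Dachs = 0.2,
                                 Riq = 0.2, Ex = 0.2, Wts = 0.2, Yki = 0.2),
                         kFm = 2, kFr = 1, kDm = 2, kDr = 1, kEm = 2, kEr = 1,
                         kFD = 0.1, kFDr = 0.5, aF = 1, aD = 1, KFj = 10,
                         kAm = 2, kAr = 1, KFA = 5, nFA = 2,
                         kRm = 2, kRr = 1, KDR = 4, nDR = 2,
                         kWAp = 0.05, kWAm = 0.5,
                         kWRp = 0.05, kWRm = 0.5,
                         kEWp = 0.05, kEWm = 0.5,
                         kdWA = 0.2, kiWR = 0.2,
                         kYp = 0.05, kYd = 0.2, kEY = 0.01,
                         ex_stabilization_mode = c("parallel",
                                                   "fat_stabilizes_ex"),
                         sE = 3, KE = 5) {
  ex_stabilization_mode <- match.arg(ex_stabilization_mode)
  species <- c("Fat", "Ds", "Fj", "Dachs", "Riq", "Ex", "Wts", "Yki")
  for (nm in c("prod", "deg")) {
    v <- get(nm)
    if (!all(species %in% names(v)))
      stop(sprintf("`%s` must name all of: %s", nm,
                   paste(species, collapse = ", ")), call. = FALSE)
    if (any(v < 0)) stop(sprintf("`%s` rates must be >= 0", nm), call. = FALSE)
  }
  p <- list(prod = prod[species], deg = deg[species],
            kFm = kFm, kFr = kFr, kDm = kDm, kDr = kDr, kEm = kEm, kEr = kEr,
            kFD = kFD, kFDr = kFDr, aF = aF, aD = aD, KFj = KFj,
            kAm = kAm, kAr = kAr, KFA = KFA, nFA = nFA,
            kRm = kRm, kRr = kRr, KDR = KDR, nDR = nDR,
            kWAp = kWAp, kWAm = kWAm, kWRp = kWRp, kWRm = kWRm,
            kEWp = kEWp, kEWm = kEWm, kdWA = kdWA, kiWR = kiWR,
            kYp = kYp, kYd = kYd, kEY = kEY,
            ex_stabilization_mode = ex_stabilization_mode, sE = sE, KE = KE)
  scal <- setdiff(names(p), c("prod", "deg", "ex_stabilization_mode"))
  for (nm in scal) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
  }
  if (nFA < 1 || nDR < 1)
    stop("Hill coefficients `nFA`, `nDR` must be >= 1", call. = FALSE)
  if (KFA <= 0 || KDR <= 0 || KFj <= 0 || KE <= 0)
    stop("half-saturation constants must be positive", call. = FALSE)
  structure(p, class = "hippo_params")
}

#' @export
print.hippo_params <- function(x, ...) {
  cat("Upstream Hippo network parameters (nM, min)\n")
  cat("  production:", paste(sprintf("%s=%g", names(x$prod), x$prod),
                             collapse = " "), "\n")
  cat("  degradation:", paste(sprintf("%s=%g", names(x$deg), x$deg),
                              collapse = " "), "\n")
  cat(sprintf("  Ex stabilization mode: %s\n", x$ex_stabilization_mode))
  invisible(x)
}

#' Default initial Hippo state
#'
#' Cytosolic species start at their production/degradation balance
#' (`prod/deg`, or 0 when degradation is 0); all membrane species start at 0.
#'
#' @param params A [hippo_params()] object.
#' @param geometry A [cell_geometry()] object.
#' @return Named non-negative numeric state vector.
#' @export
hippo_initial_state <- function(params = hippo_params(),
                                geometry = cell_geometry()) {
  nm <- hippo_state_names(geometry)
  y <- setNames(numeric(length(nm)), nm)
  cyt0 <- ifelse(params$deg > 0, params$prod / params$deg, 0)
  y["Fat_c"] <- cyt0[["Fat"]]; y["Ds_c"] <- cyt0[["Ds"]]
  y["Fj_c"] <- cyt0[["Fj"]]; y["Dachs_c"] <- cyt0[["Dachs"]]
  y["Riq_c"] <- cyt0[["Riq"]]; y["Ex_c"] <- cyt0[["Ex"]]
  y["Wts_c"] <- cyt0[["Wts"]]; y["Yki_a"] <- cyt0[["Yki"]]
  y
}

reg <- function(y, species, Nm) {
  y[paste0(species, ".", seq_len(Nm))]
}

#' Time derivative of the Hippo network state
#'
#' Implements the reaction network described in [hippo_params()] for a single
#' cell with `geometry$n_regions` membrane regions. The cytosolic Wts balance
#' contains three reversible binding pairs (to membrane Dachs, Riq and Ex,
#' summed over regions), and an optional externally supplied per-region
#' Wts-sequestration sink (`jub_wts_sink`, nM/min) through which the coupled
#' model routes Jub-mediated sequestration; it is zero when the biochemical
#' model runs stand-alone.
#'
#' @param state Named state vector as produced by [hippo_initial_state()].
#' @param params A [hippo_params()] object.
#' @param geometry A [cell_geometry()] object.
#' @param jub_wts_sink Per-region sequestration rate (nM/min), length 1 or
#'   `n_regions`. May be negative for the return flux from the Jub-Wts
#'   complex.
#' @return Named derivative vector (nM/min), same layout as `state`.
#' @export
hippo_rhs <- function(state, params, geometry = cell_geometry(),
                      jub_wts_sink = 0) {
  Nm <- geometry$n_regions
  nm <- hippo_state_names(geometry)
  if (length(state) != length(nm))
    stop(sprintf("state has %d entries but geometry implies %d",
                 length(state), length(nm)), call. = FALSE)
  if (is.null(names(state)) || !all(names(state) == nm))
    names(state) <- nm
  if (any(state < -1e-6))
    stop("state contains negative concentrations", call. = FALSE)
  state <- pmax(state, 0)
  sink <- rep_len(jub_wts_sink, Nm)

  y <- state
  dy <- setNames(numeric(length(y)), nm)
  p <- params

  Fat_m <- reg(y, "Fat_m", Nm); Ds_m <- reg(y, "Ds_m", Nm)
  FatDs <- reg(y, "FatDs", Nm); DsFat <- reg(y, "DsFat", Nm)
  Am <- reg(y, "Dachs_m", Nm); Rm <- reg(y, "Riq_m", Nm)
  Ex_m <- reg(y, "Ex_m", Nm)
  WA <- reg(y, "WA", Nm); WR <- reg(y, "WR", Nm); EW <- reg(y, "EW", Nm)
  W <- y[["Wts_c"]]

  FatTot <- Fat_m + FatDs
  DsTot <- Ds_m + DsFat

  # Four-jointed modulation of trans binding
  fj <- y[["Fj_c"]] / (p$KFj + y[["Fj_c"]])
  alphaF <- 1 + p$aF * fj
  alphaD <- 1 / (1 + p$aD * fj)

  # trans-dimer fluxes; "self" regions see their own membrane as the
  # neighbour (mean-field closure), "isolated" regions have none
  self_mask <- as.numeric(geometry$neighbor == "self")
  bindFD <- p$kFD * alphaF * alphaD * Fat_m * Ds_m * self_mask
  dy[paste0("FatDs.", seq_len(Nm))] <- bindFD - p$kFDr * FatDs
  dy[paste0("DsFat.", seq_len(Nm))] <- bindFD - p$kFDr * DsFat

  # Fat
  dy["Fat_c"] <- p$prod[["Fat"]] - p$deg[["Fat"]] * y[["Fat_c"]] -
    p$kFm * y[["Fat_c"]] + p$kFr * sum(Fat_m)
  dy[paste0("Fat_m.", seq_len(Nm))] <-
    p$kFm * y[["Fat_c"]] / Nm - p$kFr * Fat_m - bindFD + p$kFDr * FatDs
  # Ds
  dy["Ds_c"] <- p$prod[["Ds"]] - p$deg[["Ds"]] * y[["Ds_c"]] -
    p$kDm * y[["Ds_c"]] + p$kDr * sum(Ds_m)
  dy[paste0("Ds_m.", seq_len(Nm))] <-
    p$kDm * y[["Ds_c"]] / Nm - p$kDr * Ds_m - bindFD + p$kFDr * DsFat
  # Fj
  dy["Fj_c"] <- p$prod[["Fj"]] - p$deg[["Fj"]] * y[["Fj_c"]]

  # Dachs: membrane binding inhibited by membrane Fat (decreasing Hill)
  hA <- hill_factor(FatTot, p$KFA, p$nFA, "decreasing")
  bindA <- p$kAm * hA * y[["Dachs_c"]] / Nm
  dy["Dachs_c"] <- p$prod[["Dachs"]] - p$deg[["Dachs"]] * y[["Dachs_c"]] -
    sum(bindA) + p$kAr * sum(Am)
  dy[paste0("Dachs_m.", seq_len(Nm))] <-
    bindA - p$kAr * Am - p$kWAp * W * Am + (p$kWAm + p$kdWA) * WA

  # Riq: membrane binding promoted by membrane Ds (increasing Hill)
  hR <- hill_factor(DsTot, p$KDR, p$nDR, "increasing")
  bindR <- p$kRm * hR * y[["Riq_c"]] / Nm
  dy["Riq_c"] <- p$prod[["Riq"]] - p$deg[["Riq"]] * y[["Riq_c"]] -
    sum(bindR) + p$kRr * sum(Rm)
  dy[paste0("Riq_m.", seq_len(Nm))] <-
    bindR - p$kRr * Rm - p$kWRp * W * Rm + (p$kWRm + p$kiWR) * WR

  # Ex: recycling optionally slowed by membrane Fat
  kErEff <- if (p$ex_stabilization_mode == "fat_stabilizes_ex") {
    p$kEr / (1 + p$sE * FatTot / (p$KE + FatTot))
  } else {
    rep(p$kEr, Nm)
  }
  dy["Ex_c"] <- p$prod[["Ex"]] - p$deg[["Ex"]] * y[["Ex_c"]] -
    p$kEm * y[["Ex_c"]] + sum(kErEff * Ex_m)
  dy[paste0("Ex_m.", seq_len(Nm))] <-
    p$kEm * y[["Ex_c"]] / Nm - kErEff * Ex_m - p$kEWp * W * Ex_m +
    p$kEWm * EW

  # Wts: three reversible binding pairs, degradation routes, external sink
  dy["Wts_c"] <- p$prod[["Wts"]] - p$deg[["Wts"]] * W -
    p$kWAp * W * sum(Am) + p$kWAm * sum(WA) -
    p$kWRp * W * sum(Rm) + p$kWRm * sum(WR) -
    p$kEWp * W * sum(Ex_m) + p$kEWm * sum(EW) -
    sum(sink)
  dy[paste0("WA.", seq_len(Nm))] <- p$kWAp * W * Am - (p$kWAm + p$kdWA) * WA
  dy[paste0("WR.", seq_len(Nm))] <- p$kWRp * W * Rm - (p$kWRm + p$kiWR) * WR
  dy[paste0("EW.", seq_len(Nm))] <- p$kEWp * W * Ex_m - p$kEWm * EW

  # Yki: phosphorylation by active Wts (= total Ex-Wts complex) plus direct
  # Ex-dependent inactivation, reversible
  activeWts <- sum(EW)
  Ya <- y[["Yki_a"]]; Yp <- y[["Yki_p"]]
  inact <- p$kYp * activeWts * Ya + p$kEY * sum(Ex_m) * Ya
  dy["Yki_a"] <- p$prod[["Yki"]] - p$deg[["Yki"]] * Ya - inact + p$kYd * Yp
  dy["Yki_p"] <- inact - p$kYd * Yp - p$deg[["Yki"]] * Yp

  dy
}

hippo_ode_func <- function(t, y, parms) {
  list(hippo_rhs(y, parms$params, parms$geometry, parms$sink))
}

#' Steady state of the Hippo network
#'
#' Integrates the network with a stiff solver until the maximum absolute
#' derivative falls below `tol` times the dominant rate scale (the largest
#' production rate, floored at 1 nM/min), then polishes with damped Newton
#' iterations on a finite-difference Jacobian. Non-negativity is preserved;
#' if the polish leaves the feasible region or fails to reduce the residual,
#' the integrated state is returned.
#'
#' @inheritParams hippo_rhs
#' @param init Optional initial state (default [hippo_initial_state()]); a
#'   warm start from a nearby solution speeds up parameter scans.
#' @param t_block,max_blocks Integration is performed in blocks of
#'   `t_block` minutes, up to `max_blocks` blocks, checking the residual
#'   after each.
#' @param tol Relative residual tolerance (default `1e-8`).
#' @return Named state vector with attributes `residual` (max abs derivative)
#'   and `converged` (logical).
#' @export
hippo_steady_state <- function(params = hippo_params(),
                               geometry = cell_geometry(),
                               jub_wts_sink = 0, init = NULL,
                               t_block = 500, max_blocks = 8, tol = 1e-8) {
  y <- if (is.null(init)) hippo_initial_state(params, geometry) else init
  parms <- list(params = params, geometry = geometry, sink = jub_wts_sink)
  scale <- max(1, max(params$prod))
  resid <- function(y) max(abs(hippo_rhs(y, params, geometry, jub_wts_sink)))
  for (b in seq_len(max_blocks)) {
    sol <- deSolve::ode(y = y, times = c(0, t_block), func = hippo_ode_func,
                        parms = parms, method = "lsoda",
                        atol = 1e-9, rtol = 1e-6)
    y <- pmax(sol[nrow(sol), -1], 0)
    if (resid(y) < tol * scale) break
  }
  # Newton polish with finite-difference Jacobian
  r0 <- resid(y)
  if (r0 >= tol * scale) {
    f <- function(v) hippo_rhs(v, params, geometry, jub_wts_sink)
    n <- length(y)
    for (it in 1:20) {
      fy <- f(y)
      if (max(abs(fy)) < tol * scale * 1e-2) break
      J <- matrix(0, n, n)
      h <- pmax(1e-7, 1e-7 * abs(y))
      for (j in seq_len(n)) {
        yj <- y; yj[j] <- yj[j] + h[j]
        J[, j] <- (f(yj) - fy) / h[j]
      }
      step <- tryCatch(solve(J, -fy), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      improved <- FALSE
      for (k in 1:6) {
        cand <- y + lambda * step
        if (all(cand >= 0) && max(abs(f(cand))) < max(abs(fy))) {
          y <- cand; improved <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!improved) break
    }
  }
  r <- resid(y)
  if (r >= tol * scale)
    warning(sprintf("steady state not converged: residual %.3g (tol %.3g)",
                    r, tol * scale), call. = FALSE)
  attr(y, "residual") <- r
  attr(y, "converged") <- r < tol * scale
  y
}

#' Summaries of a Hippo state
#'
#' @param state A Hippo state vector.
#' @param geometry Matching [cell_geometry()].
#' @return Named vector with total membrane Dachs, Riq, Fat, Ds, Ex, the
#'   active Wts level (total Ex-Wts complex), total Wts material and active
#'   Yki.
#' @export
hippo_summary <- function(state, geometry = cell_geometry()) {
  Nm <- geometry$n_regions
  names(state) <- hippo_state_names(geometry)
  c(membrane_dachs = sum(reg(state, "Dachs_m", Nm)),
    membrane_riq = sum(reg(state, "Riq_m", Nm)),
    membrane_fat = sum(reg(state, "Fat_m", Nm) + reg(state, "FatDs", Nm)),
    membrane_ds = sum(reg(state, "Ds_m", Nm) + reg(state, "DsFat", Nm)),
    membrane_ex = sum(reg(state, "Ex_m", Nm)),
    active_wts = sum(reg(state, "EW", Nm)),
    total_wts = state[["Wts_c"]] + sum(reg(state, "WA", Nm) +
                                         reg(state, "WR", Nm) +
                                         reg(state, "EW", Nm)),
    yki_active = state[["Yki_a"]])
}

#' Scan steady-state outputs over Fat production
#'
#' Computes the steady state of the Hippo network across a range of Fat
#' production rates and reports total membrane Dachs, total membrane Riq and
#' active Yki. With increasing Fat production, membrane Dachs falls (Fat
#' inhibits Dachs localization) and membrane Riq rises (trans-dimerized Ds is
#' retained at the membrane and recruits Riq). In `"fat_stabilizes_ex"` mode
#' the extra membrane Ex strengthens Wts activation, so Yki lies at or below
#' the `"parallel"`-mode curve.
#'
#' @param params A [hippo_params()] object (its `prod["Fat"]` is overridden).
#' @param fat_production_range Ascending vector (>= 5 points) of Fat
#'   production rates (nM/min).
#' @param mode Ex-stabilization mode(s) to run.
#' @param geometry A [cell_geometry()].
#' @return Data frame with columns `fat_production`, `mode`,
#'   `membrane_dachs`, `membrane_riq`, `yki_active`, `converged`.
#' @export
fat_production_scan <- function(params = hippo_params(),
                                fat_production_range = seq(0.3, 3,
                                                           length.out = 9),
                                mode = c("parallel", "fat_stabilizes_ex"),
                                geometry = cell_geometry()) {
  if (is.unsorted(fat_production_range, strictly = TRUE))
    stop("`fat_production_range` must be sorted ascending", call. = FALSE)
  if (length(fat_production_range) < 5)
    stop("`fat_production_range` needs at least 5 points", call. = FALSE)
  mode <- match.arg(mode, several.ok = TRUE)
  rows <- list()
  for (md in mode) {
    p <- params
    p$ex_stabilization_mode <- md
    warm <- NULL
    for (pf in fat_production_range) {
      p$prod[["Fat"]] <- pf
      ss <- tryCatch(
        suppressWarnings(hippo_steady_state(p, geometry, init = warm)),
        error = function(e) NULL)
      if (is.null(ss)) {
        rows[[length(rows) + 1L]] <- data.frame(
          fat_production = pf, mode = md, membrane_dachs = NA_real_,
          membrane_riq = NA_real_, yki_active = NA_real_, converged = FALSE)
        next
      }
      warm <- ss
      sm <- hippo_summary(ss, geometry)
      rows[[length(rows) + 1L]] <- data.frame(
        fat_production = pf, mode = md,
        membrane_dachs = sm[["membrane_dachs"]],
        membrane_riq = sm[["membrane_riq"]],
        yki_active = sm[["yki_active"]],
        converged = isTRUE(attr(ss, "converged")))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
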