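#' Configuration of the coupled biochemical-signaling-and-mechanics model
#'
#' Assembles the parameterization of the three sub-models plus the coupling
#' constants. Per-cell vectors refer to the seven-cell patch (cell 1 =
#' centre, cells 2-7 = boundary ring).
#'
#' @param hippo A [hippo_params()] object.
#' @param bell A [bell_params()] object.
#' @param alpha_catenin Total alpha-catenin per node, per cell
#'   (molecules/node; length 1 or 7). The physiological range is roughly
#'   26-46 molecules/node.
#' @param jub_production Jub production rate per cell (nM/min; length 1
#'   or 7).
#' @param jub_degradation First-order decay of free Jub (1/min).
#' @param jub_K_scale Multiplier taking the single-junction Jub dissociation
#'   constants (`bell$jub_K`, molecule units) to the cell-level nM scale.
#' @param conv_nM Conversion factor from alpha-catenin molecules/node to nM
#'   of Jub binding sites per membrane region.
#' @param kJWp,kJWm Binding/unbinding rates of cytosolic Wts to junctional
#'   (alpha-catenin-bound) Jub (1/(nM min), 1/min). Jub-bound Wts is
#'   sequestered: it cannot associate with Ex.
#' @param kdJW Degradation of Wts inside the Jub-Wts complex (1/min).
#'   A positive value makes sequestration a genuine drain on the Wts pool;
#'   with turnover-free sequestration the reversible complex would simply
#'   equilibrate and leave steady-state Wts unchanged.
#' @param vinculin Relative Vinculin level (applies to all cells).
#' @param boundary_force Signed imposed force per exterior node (pN;
#'   positive = stretch).
#' @param fixed_tension Optional tension (pN/node) applied uniformly to
#'   every node, bypassing the mechanical model (used for
#'   tension/alpha-catenin scans and for oracle checks). `NULL` runs the
#'   full mechanics.
#' @param growth_enabled Grow rest lengths at the Yki-dependent rate.
#' @param g0 Growth gain (1/(nM min)): rest-length growth rate is
#'   `g0 * max(0, yki - Y0)`, capped at `rate_max`. The default puts the
#'   belt-tension scale of the patch high enough that cells operate on the
#'   rising branch of the bound-Jub curve.
#' @param Y0 Reference Yki level (nM) below which there is no growth.
#' @param rate_max Growth-rate cap (1/min).
#' @param horizon Coupled simulation horizon (min).
#' @param dt_couple Coupling step (min): mechanics is relaxed and the
#'   catenin/Jub quasi-equilibrium refreshed every step.
#' @param mech_relax Seconds of mechanical relaxation per coupling step.
#' @param edge_length,KN,KT,Xi,FA_belt,FA_transverse Patch geometry and
#'   mechanical constants (see [build_hex_patch()]).
#' @param center_swelling Initial area scale of the centre cell (1 = no
#'   swelling). The growth experiments start from a modestly enlarged
#'   centre cell (e.g. osmotic water uptake); the pre-strain this stores in
#'   the ring is what lets differential growth feed back as compression on
#'   the neighbours.
#' @return Object of class `"bsm_config"`.
#' @export
bsm_config <- function(hippo = hippo_params(),
                       bell = bell_params(),
                       alpha_catenin = 30,
                       jub_production = 250,
                       jub_degradation = 1,
                       jub_K_scale = 60,
                       conv_nM = 2,
                       kJWp = 0.002, kJWm = 0.2, kdJW = 0.2,
                       vinculin = 0,
                       boundary_force = 0,
                       fixed_tension = NULL,
                       growth_enabled = FALSE,
                       g0 = 0.01, Y0 = 4, rate_max = 0.02,
                       horizon = 60, dt_couple = 0.5,
                       mech_relax = 30,
                       edge_length = 1, KN = 1500, KT = 1500, Xi = 100,
                       FA_belt = 900, FA_transverse = 0,
                       center_swelling = 1) {
  stopifnot(inherits(hippo, "hippo_params"), inherits(bell, "bell_params"))
  alpha_catenin <- rep_len(alpha_catenin, 7)
  jub_production <- rep_len(jub_production, 7)
  if (any(alpha_catenin < 1))
    stop("`alpha_catenin` must be >= 1 molecule/node in every cell",
         call. = FALSE)
  if (any(jub_production < 0) || jub_degradation <= 0)
    stop("Jub production must be >= 0 and degradation > 0", call. = FALSE)
  if (conv_nM <= 0 || jub_K_scale <= 0)
    stop("`conv_nM` and `jub_K_scale` must be positive", call. = FALSE)
  if (!is.null(fixed_tension) && fixed_tension < 0)
    stop("`fixed_tension` must be >= 0", call. = FALSE)
  if (dt_couple <= 0 || horizon <= 0)
    stop("`horizon` and `dt_couple` must be positive", call. = FALSE)
  for (nm in c("jub_K_scale", "conv_nM", "kJWp", "kJWm", "kdJW", "g0",
               "Y0", "rate_max", "mech_relax", "edge_length", "KN", "KT",
               "Xi", "FA_belt", "FA_transverse", "vinculin")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
  }
  if (KN <= 0 || KT <= 0 || Xi <= 0 || edge_length <= 0)
    stop("`KN`, `KT`, `Xi` and `edge_length` must be positive",
         call. = FALSE)
  if (!is.numeric(center_swelling) || length(center_swelling) != 1L ||
      center_swelling <= 0)
    stop("`center_swelling` must be a positive area scale", call. = FALSE)
  structure(list(hippo = hippo, bell = bell,
                 alpha_catenin = alpha_catenin,
                 jub_production = jub_production,
                 jub_degradation = jub_degradation,
                 jub_K_scale = jub_K_scale, conv_nM = conv_nM,
                 kJWp = kJWp, kJWm = kJWm, kdJW = kdJW, vinculin = vinculin,
                 boundary_force = boundary_force,
                 fixed_tension = fixed_tension,
                 growth_enabled = growth_enabled,
                 g0 = g0, Y0 = Y0, rate_max = rate_max,
                 horizon = horizon, dt_couple = dt_couple,
                 mech_relax = mech_relax,
                 edge_length = edge_length, KN = KN, KT = KT, Xi = Xi,
                 FA_belt = FA_belt, FA_transverse = FA_transverse,
                 center_swelling = center_swelling),
            class = "bsm_config")
}

#' @export
print.bsm_config <- function(x, ...) {
  cat("BSM configuration\n")
  cat(sprintf("  alpha-catenin (molecules/node): centre %g, boundary %s\n",
              x$alpha_catenin[1],
              paste(unique(x$alpha_catenin[-1]), collapse = "/")))
  cat(sprintf("  Jub production (nM/min): centre %g, boundary %s\n",
              x$jub_production[1],
              paste(unique(x$jub_production[-1]), collapse = "/")))
  cat(sprintf("  boundary force %g pN/node%s; growth %s; horizon %g min\n",
              x$boundary_force,
              if (is.null(x$fixed_tension)) ""
              else sprintf(" (bypassed: fixed tension %g pN)",
                           x$fixed_tension),
              if (x$growth_enabled) "on" else "off", x$horizon))
  invisible(x)
}

#' Force per alpha-catenin molecule
#'
#' The junctional tension at a node is shared by the `n_catenin` parallel
#' cadherin-catenin complexes anchored there.
#'
#' @param tension Node tension (pN, >= 0); vectorized.
#' @param n_catenin Alpha-catenin molecules per node (>= 1).
#' @return Per-molecule force in pN.
#' @examples
#' per_molecule_force(600, 60)  # 10 pN
#' @export
per_molecule_force <- function(tension, n_catenin) {
  if (any(n_catenin < 1))
    stop("`n_catenin` must be >= 1", call. = FALSE)
  if (any(tension < 0)) stop("tension must be >= 0", call. = FALSE)
  tension / n_catenin
}

#' Wts-sequestration sink from junctional Jub
#'
#' Mass-action sequestration of cytosolic Wts by alpha-catenin-bound Jub:
#' `sink = kJWp * wts_c * bound_jub - kJWm * jub_wts`. The forward term
#' drains cytosolic Wts (excluding it from Ex activation); the reverse term
#' returns Wts from the Jub-Wts complex.
#'
#' @param bound_jub Junctional bound Jub per region (nM, >= 0).
#' @param wts_c Cytosolic Wts (nM).
#' @param jub_wts Current Jub-Wts complex per region (nM).
#' @param kJWp,kJWm Binding/unbinding rates.
#' @return Per-region net sequestration rate (nM/min), positive toward the
#'   complex.
#' @export
jub_wts_coupling <- function(bound_jub, wts_c, jub_wts = 0,
                             kJWp = 0.002, kJWm = 0.2) {
  if (any(bound_jub < 0)) stop("`bound_jub` must be >= 0", call. = FALSE)
  kJWp * wts_c * bound_jub - kJWm * jub_wts
}

#' Yki-dependent rest-length growth rate
#'
#' Growth switches on above the reference Yki level `Y0` and saturates at
#' `rate_max`: `rate = min(g0 * max(0, yki - Y0), rate_max)`.
#'
#' @param yki Active Yki (nM); vectorized.
#' @param g0 Gain (1/(nM min)).
#' @param Y0 Reference Yki (nM).
#' @param rate_max Cap (1/min).
#' @return Growth rate (1/min).
#' @export
yki_growth_rate <- function(yki, g0 = 5e-4, Y0 = 4, rate_max = 0.01) {
  if (any(yki < 0)) stop("`yki` must be >= 0", call. = FALSE)
  pmin(g0 * pmax(0, yki - Y0), rate_max)
}

# extended per-cell state: hippo state + JubWts per region + total Jub -------

bsm_cell_state_names <- function(geometry) {
  c(hippo_state_names(geometry),
    paste0("JW.", seq_len(geometry$n_regions)), "Jub_tot")
}

# shared-pool Jub binding across the regions of one cell.
# sites: n_regions x 3 matrix of binding-site concentrations (nM) per state;
# K: the three dissociation constants (nM). Returns per-region bound Jub.
solve_cell_jub <- function(jub_avail, sites, K) {
  if (jub_avail <= 0 || sum(sites) == 0)
    return(list(bound = numeric(nrow(sites)), free = max(jub_avail, 0)))
  tot_sites <- colSums(sites)
  imbalance <- function(Jf)
    jub_avail - Jf - sum(tot_sites * Jf / (K + Jf))
  Jf <- uniroot(imbalance, c(0, jub_avail), tol = 1e-10)$root
  frac <- Jf / (K + Jf)
  list(bound = as.numeric(sites %*% frac), free = Jf)
}

# rhs of one cell's extended state; `sites` frozen for the coupling step
bsm_cell_rhs <- function(y, cfg, geometry, sites) {
  Nm <- geometry$n_regions
  nh <- length(hippo_state_names(geometry))
  K <- cfg$bell$jub_K * cfg$jub_K_scale
  JW <- pmax(y[nh + seq_len(Nm)], 0)
  Jtot <- max(y[nh + Nm + 1], 0)
  jub_avail <- max(Jtot - sum(JW), 0)
  sj <- solve_cell_jub(jub_avail, sites, K)
  W <- max(y[["Wts_c"]], 0)
  sink <- jub_wts_coupling(sj$bound, W, JW, cfg$kJWp, cfg$kJWm)
  dh <- hippo_rhs(y[seq_len(nh)], cfg$hippo, geometry, jub_wts_sink = sink)
  dJW <- sink - cfg$kdJW * JW
  pj <- attr(sites, "jub_production")
  # Jub is recycled when complexed Wts degrades, so only free Jub decays
  dJtot <- pj - cfg$jub_degradation * sj$free
  c(dh, dJW, dJtot)
}

bsm_cell_ode <- function(t, y, parms) {
  list(bsm_cell_rhs(y, parms$cfg, parms$geometry, parms$sites))
}

# per-region binding sites for one cell given per-region per-molecule forces
cell_sites <- function(cfg, f_regions, n_cat_regions) {
  occ <- t(vapply(f_regions,
                  function(f) equilibrium_occupancy(f, cfg$bell,
                                                    cfg$vinculin),
                  numeric(3)))
  cfg$conv_nM * n_cat_regions * occ
}

#' Run the coupled biochemical-signaling-and-mechanics model
#'
#' Operator-split loop over coupling steps of `dt_couple` minutes:
#' relax the mechanical network (unless `fixed_tension` bypasses it), read
#' node tensions, convert to per-molecule forces via each node's
#' alpha-catenin level, take the alpha-catenin/Jub quasi-equilibrium per
#' membrane region, freeze the resulting Jub binding sites, advance each
#' cell's Hippo + Jub-Wts ODEs over the step, and (optionally) grow rest
#' lengths at the Yki-dependent rate. Deterministic given the configuration.
#'
#' Each cell's upstream Hippo network runs in the mean-field single-cell
#' closure (regions self-apposed), so cells differ only through tension,
#' alpha-catenin and Jub production - the quantities the experiments vary.
#'
#' @param config A [bsm_config()].
#' @param record Record the per-cell summary every `record` coupling steps
#'   (default: final step only).
#' @return Object of class `"bsm_run"`: list with `summary` (final per-cell
#'   data.frame: cell, cell_class, yki, bound_jub, rest_ratio, tension),
#'   `timeseries` (same columns plus time, when `record` is set), `network`
#'   (final mechanical state or `NULL`), and `config`.
#' @export
run_bsm <- function(config, record = NULL) {
  stopifnot(inherits(config, "bsm_config"))
  cfg <- config
  geometry <- cell_geometry(6, "self")
  nh <- length(hippo_state_names(geometry))
  n_steps <- max(1L, round(cfg$horizon / cfg$dt_couple))

  use_mech <- is.null(cfg$fixed_tension)
  net <- NULL
  rest0 <- NULL
  if (use_mech) {
    net <- build_hex_patch(cfg$edge_length, cfg$KN, cfg$KT, cfg$Xi,
                           cfg$FA_belt, cfg$FA_transverse)
    if (cfg$center_swelling != 1)
      net <- apply_swelling(net, 1, cfg$center_swelling)
    net <- integrate_network(net, imposed = cfg$boundary_force,
                             horizon = 300, v_tol = 1e-4)
    rest0 <- vapply(1:7, function(ci) mean(cell_belt_rest(net, ci)),
                    numeric(1))
  }

  # initial per-cell state: stand-alone Hippo steady state, no Jub coupling
  ss0 <- suppressWarnings(hippo_steady_state(cfg$hippo, geometry))
  cell_states <- lapply(1:7, function(ci) {
    setNames(c(as.numeric(ss0), rep(0, geometry$n_regions),
               cfg$jub_production[ci] / cfg$jub_degradation),
             bsm_cell_state_names(geometry))
  })

  rows <- list()
  snapshot <- function(time) {
    do.call(rbind, lapply(1:7, function(ci) {
      y <- cell_states[[ci]]
      names(y) <- bsm_cell_state_names(geometry)
      tens <- if (use_mech) {
        mean(node_tension(net, net$cells[[ci]]$vertices))
      } else cfg$fixed_tension
      K <- cfg$bell$jub_K * cfg$jub_K_scale
      sites <- attr(cell_states[[ci]], "sites")
      bj <- if (is.null(sites)) NA_real_ else {
        jub_avail <- max(y[["Jub_tot"]] - sum(y[paste0("JW.", 1:6)]), 0)
        sum(solve_cell_jub(jub_avail, sites, K)$bound)
      }
      rr <- if (use_mech) {
        mean(cell_belt_rest(net, ci)) / rest0[ci]
      } else 1
      data.frame(time = time, cell = ci,
                 cell_class = if (ci == 1) "center" else "boundary",
                 yki = y[["Yki_a"]], bound_jub = bj,
                 jub_wts = sum(y[paste0("JW.", 1:6)]),
                 rest_ratio = rr, tension = tens)
    }))
  }

  for (step in seq_len(n_steps)) {
    # 1. mechanics -> per-region per-molecule forces
    if (use_mech) {
      net <- integrate_network(net, imposed = cfg$boundary_force,
                               horizon = cfg$mech_relax, v_tol = 1e-4)
      tens_nodes <- node_tension(net)
    }
    sites_list <- lapply(1:7, function(ci) {
      vs <- if (use_mech) net$cells[[ci]]$vertices else NULL
      if (use_mech) {
        tv <- tens_nodes[as.character(vs)]
        # each cell reads the shared node tension through its own
        # complement of alpha-catenin molecules
        f_nodes <- per_molecule_force(tv, cfg$alpha_catenin[ci])
        nxt <- c(2:6, 1)
        f_reg <- (f_nodes + f_nodes[nxt]) / 2
        n_reg <- rep(cfg$alpha_catenin[ci], 6)
      } else {
        f_reg <- rep(per_molecule_force(cfg$fixed_tension,
                                        cfg$alpha_catenin[ci]), 6)
        n_reg <- rep(cfg$alpha_catenin[ci], 6)
      }
      s <- cell_sites(cfg, f_reg, n_reg)
      attr(s, "jub_production") <- cfg$jub_production[ci]
      s
    })

    # 2. advance each cell's extended ODEs over the coupling step
    for (ci in 1:7) {
      parms <- list(cfg = cfg, geometry = geometry,
                    sites = sites_list[[ci]])
      y <- cell_states[[ci]]
      sol <- deSolve::ode(y = y, times = c(0, cfg$dt_couple),
                          func = bsm_cell_ode, parms = parms,
                          method = "lsoda", atol = 1e-10, rtol = 1e-8)
      ynew <- pmax(sol[nrow(sol), -1], 0)
      attr(ynew, "sites") <- sites_list[[ci]]
      cell_states[[ci]] <- ynew
    }

    # 3. growth feedback on rest lengths
    if (use_mech && cfg$growth_enabled) {
      yk <- vapply(cell_states, function(y) {
        names(y) <- bsm_cell_state_names(geometry); y[["Yki_a"]]
      }, numeric(1))
      rates <- yki_growth_rate(yk, cfg$g0, cfg$Y0, cfg$rate_max)
      net <- grow_cells(net, rates, cfg$dt_couple)
    }

    if (!is.null(record) && (step %% record == 0 || step == n_steps))
      rows[[length(rows) + 1L]] <- snapshot(step * cfg$dt_couple)
  }
  if (is.null(record)) rows <- list(snapshot(n_steps * cfg$dt_couple))
  ts <- do.call(rbind, rows)
  rownames(ts) <- NULL
  structure(list(summary = ts[ts$time == max(ts$time), , drop = FALSE],
                 timeseries = ts, network = net, config = cfg),
            class = "bsm_run")
}

#' @export
print.bsm_run <- function(x, ...) {
  cat("Coupled BSM run\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

cell_belt_edge_idx <- function(net, ci) {
  vs <- net$cells[[ci]]$vertices
  nxt <- c(2:6, 1)
  vapply(1:6, function(k) {
    i <- vs[k]; j <- vs[nxt[k]]
    which((net$belt$from == i & net$belt$to == j) |
            (net$belt$from == j & net$belt$to == i))
  }, integer(1))
}

cell_belt_rest <- function(net, ci) {
  net$belt$rest[cell_belt_edge_idx(net, ci)]
}

# grow each cell's edges at its rate; shared belt edges take the mean of
# the two owning cells' rates
grow_cells <- function(net, rates, dt) {
  nb <- nrow(net$belt)
  acc <- numeric(nb); cnt <- numeric(nb)
  for (ci in 1:7) {
    idx <- cell_belt_edge_idx(net, ci)
    acc[idx] <- acc[idx] + rates[ci]
    cnt[idx] <- cnt[idx] + 1
  }
  belt_rates <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  tr_rates <- numeric(nrow(net$transverse))
  for (ci in 1:7) {
    idx <- which(net$transverse$to == net$cells[[ci]]$center |
                   net$transverse$from == net$cells[[ci]]$center)
    tr_rates[idx] <- rates[ci]
  }
  grow_rest_lengths(net, belt_rates, tr_rates, dt)
}
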