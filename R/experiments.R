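#' Default configuration of the growth experiments
#'
#' The centre-perturbation and Jub-production experiments run with growth
#' enabled, a 40-min horizon, and a centre cell that starts modestly
#' swollen (area scale 1.15, emulating osmotic enlargement). The stored
#' pre-strain is what transmits differential growth to the neighbours as
#' compression.
#'
#' @param ... Overrides passed to [bsm_config()].
#' @return A [bsm_config()].
#' @export
growth_experiment_config <- function(...) {
  bsm_config(growth_enabled = TRUE, horizon = 40, center_swelling = 1.15,
             ...)
}

#' Steady state of one cell of the coupled model at fixed tension
#'
#' Solves the extended single-cell system (Hippo network + Jub-Wts complex +
#' Jub pool) to steady state with the junctional tension prescribed, i.e.
#' with the mechanical model bypassed. Used by [tension_catenin_heatmap()]
#' and as the manual-composition oracle for [run_bsm()].
#'
#' @param config A [bsm_config()].
#' @param tension Node tension (pN/node).
#' @param n_cat Alpha-catenin level (molecules/node).
#' @param jub_production Jub production rate (nM/min).
#' @param t_block,max_blocks,tol Steady-state iteration controls as in
#'   [hippo_steady_state()].
#' @return Named vector: `yki`, `bound_jub`, `jub_wts`, `active_wts`,
#'   `converged` (0/1).
#' @export
bsm_cell_steady <- function(config, tension, n_cat = NULL,
                            jub_production = NULL,
                            t_block = 400, max_blocks = 8, tol = 1e-7) {
  stopifnot(inherits(config, "bsm_config"))
  cfg <- config
  if (!is.null(n_cat)) cfg$alpha_catenin <- rep(n_cat, 7)
  if (!is.null(jub_production)) cfg$jub_production <- rep(jub_production, 7)
  geometry <- cell_geometry(6, "self")
  f <- per_molecule_force(tension, cfg$alpha_catenin[1])
  sites <- cell_sites(cfg, rep(f, 6), rep(cfg$alpha_catenin[1], 6))
  attr(sites, "jub_production") <- cfg$jub_production[1]
  parms <- list(cfg = cfg, geometry = geometry, sites = sites)
  y <- c(as.numeric(suppressWarnings(hippo_steady_state(cfg$hippo, geometry))),
         rep(0, 6), cfg$jub_production[1] / cfg$jub_degradation)
  names(y) <- bsm_cell_state_names(geometry)
  scale <- max(1, max(cfg$hippo$prod), cfg$jub_production[1])
  resid <- function(y) max(abs(bsm_cell_rhs(y, cfg, geometry, sites)))
  conv <- FALSE
  for (b in seq_len(max_blocks)) {
    sol <- deSolve::ode(y = y, times = c(0, t_block), func = bsm_cell_ode,
                        parms = parms, method = "lsoda",
                        atol = 1e-9, rtol = 1e-6)
    y <- pmax(sol[nrow(sol), -1], 0)
    if (resid(y) < tol * scale) { conv <- TRUE; break }
  }
  K <- cfg$bell$jub_K * cfg$jub_K_scale
  JW <- y[paste0("JW.", 1:6)]
  jub_avail <- max(y[["Jub_tot"]] - sum(JW), 0)
  bj <- sum(solve_cell_jub(jub_avail, sites, K)$bound)
  c(yki = y[["Yki_a"]], bound_jub = bj, jub_wts = sum(JW),
    active_wts = sum(y[paste0("EW.", 1:6)]), converged = as.numeric(conv))
}

#' Yki over a tension by alpha-catenin grid
#'
#' Steady-state Yki of the uniform (unperturbed) coupled model over a grid
#' of imposed node tensions and alpha-catenin levels, with the mechanics
#' bypassed (tension prescribed directly, as in the molecular-level
#' analysis). At low alpha-catenin the per-molecule force spans the
#' high-force branch and Yki rises with tension; at high alpha-catenin the
#' per-molecule force traverses all three alpha-catenin states and the
#' response is triphasic.
#'
#' @param config A [bsm_config()].
#' @param tension_grid Ascending node tensions (pN/node).
#' @param catenin_grid Ascending alpha-catenin levels (molecules/node).
#' @return Data frame: `tension`, `alpha_catenin`, `yki`, `bound_jub`,
#'   `converged`.
#' @export
tension_catenin_heatmap <- function(config = bsm_config(),
                                    tension_grid = seq(200, 1000,
                                                       length.out = 10),
                                    catenin_grid = seq(5, 100,
                                                       length.out = 10)) {
  if (is.unsorted(tension_grid) || is.unsorted(catenin_grid))
    stop("grids must be sorted ascending", call. = FALSE)
  grid <- expand.grid(tension = tension_grid, alpha_catenin = catenin_grid)
  res <- t(apply(grid, 1, function(g) {
    out <- tryCatch(
      bsm_cell_steady(config, tension = g[["tension"]],
                      n_cat = g[["alpha_catenin"]]),
      error = function(e) c(yki = NA_real_, bound_jub = NA_real_,
                            jub_wts = NA_real_, active_wts = NA_real_,
                            converged = 0))
    out[c("yki", "bound_jub", "converged")]
  }))
  data.frame(grid, yki = res[, 1], bound_jub = res[, 2],
             converged = res[, 3] > 0)
}

summarize_run <- function(run) {
  s <- run$summary
  ctr <- s[s$cell_class == "center", , drop = FALSE]
  bnd <- s[s$cell_class == "boundary", , drop = FALSE]
  c(yki_center = mean(ctr$yki), yki_boundary = mean(bnd$yki),
    R_center = mean(ctr$rest_ratio), R_boundary = mean(bnd$rest_ratio),
    tension_center = mean(ctr$tension), tension_boundary = mean(bnd$tension),
    jub_center = mean(ctr$bound_jub), jub_boundary = mean(bnd$bound_jub))
}

#' Centre-cell alpha-catenin perturbation
#'
#' Sweeps the alpha-catenin level of the centre cell while the boundary
#' cells stay at `boundary_catenin`, under each of the given imposed
#' boundary forces, and reports centre and boundary Yki (and growth when
#' enabled) at the end of the coupled run.
#'
#' @param config A [bsm_config()] (its growth/horizon settings are used).
#' @param center_catenin_range Centre-cell alpha-catenin levels
#'   (molecules/node, within 5-100).
#' @param boundary_catenin Boundary-cell level (molecules/node).
#' @param boundary_forces Imposed forces to run (pN/node; signed).
#' @return Data frame: `center_catenin`, `boundary_force`, `yki_center`,
#'   `yki_boundary`, `R_center`, `R_boundary`, `tension_center`,
#'   `tension_boundary`.
#' @export
center_perturbation <- function(config = growth_experiment_config(),
                                center_catenin_range = seq(20, 40, by = 5),
                                boundary_catenin = 30,
                                boundary_forces = c(-100, 100)) {
  if (any(center_catenin_range < 5 | center_catenin_range > 100))
    stop("`center_catenin_range` must lie within [5, 100]", call. = FALSE)
  rows <- list()
  for (bf in boundary_forces) {
    for (ac in center_catenin_range) {
      cfg <- config
      cfg$alpha_catenin <- c(ac, rep(boundary_catenin, 6))
      cfg$boundary_force <- bf
      sm <- summarize_run(run_bsm(cfg))
      rows[[length(rows) + 1L]] <-
        data.frame(center_catenin = ac, boundary_force = bf, t(sm))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centre-boundary differential response
#'
#' Reports the centre-minus-boundary differences in Yki and in the
#' rest-length growth ratio R (final/initial rest length) as the centre
#' cell's alpha-catenin is swept, for each boundary force.
#'
#' @inheritParams center_perturbation
#' @return Data frame: `center_catenin`, `boundary_force`, `delta_yki`
#'   (centre - boundary), `delta_R` (centre - boundary, in percent),
#'   plus the underlying per-class values.
#' @export
differential_response_scan <- function(config = growth_experiment_config(),
                                       center_catenin_range = seq(20, 40,
                                                                  by = 5),
                                       boundary_catenin = 30,
                                       boundary_forces = c(800, 100)) {
  res <- center_perturbation(config, center_catenin_range,
                             boundary_catenin, boundary_forces)
  res$delta_yki <- res$yki_center - res$yki_boundary
  res$delta_R <- 100 * (res$R_center - res$R_boundary)
  res
}

#' Centre-cell Jub production scan
#'
#' Sweeps the Jub production rate of the centre cell at fixed boundary
#' production and boundary force, reporting the centre-minus-boundary Yki
#' and growth differences.
#'
#' @param config A [bsm_config()].
#' @param center_jub_range Centre-cell Jub production rates (nM/min).
#' @param boundary_jub Boundary-cell production rate (nM/min).
#' @param boundary_force Imposed force (pN/node).
#' @return Data frame: `center_jub`, `delta_yki`, `delta_R`, plus per-class
#'   values.
#' @export
jub_production_scan <- function(config = growth_experiment_config(),
                                center_jub_range = seq(50, 450, by = 100),
                                boundary_jub = 250,
                                boundary_force = 800) {
  if (any(center_jub_range < 0))
    stop("`center_jub_range` must be positive", call. = FALSE)
  rows <- list()
  for (pj in center_jub_range) {
    cfg <- config
    cfg$jub_production <- c(pj, rep(boundary_jub, 6))
    cfg$boundary_force <- boundary_force
    sm <- summarize_run(run_bsm(cfg))
    rows[[length(rows) + 1L]] <-
      data.frame(center_jub = pj, boundary_force = boundary_force, t(sm))
  }
  out <- do.call(rbind, rows)
  out$delta_yki <- out$yki_center - out$yki_boundary
  out$delta_R <- 100 * (out$R_center - out$R_boundary)
  rownames(out) <- NULL
  out
}
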