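test_that("per-molecule force divides node tension among complexes", {
  expect_equal(per_molecule_force(600, 60), 10)
  expect_equal(per_molecule_force(800, 20), 40)
  expect_equal(per_molecule_force(100, 10), 2 * per_molecule_force(100, 20))
  expect_error(per_molecule_force(100, 0.5), "n_catenin")
  expect_error(per_molecule_force(-5, 10), "tension")
})

test_that("Jub-Wts coupling is mass action with a reverse flux", {
  expect_equal(jub_wts_coupling(0, wts_c = 5), 0)
  # increasing in bound Jub at fixed Wts
  s <- jub_wts_coupling(c(1, 2, 4), wts_c = 5, kJWp = 0.1, kJWm = 0)
  expect_true(all(diff(s) > 0))
  expect_equal(jub_wts_coupling(2, 5, jub_wts = 3, kJWp = 0.1, kJWm = 0.2),
               0.1 * 5 * 2 - 0.2 * 3)
  expect_error(jub_wts_coupling(-1, 5), "bound_jub")
})

test_that("growth rate switches on above the Yki reference and saturates", {
  expect_equal(yki_growth_rate(4, Y0 = 4), 0)
  expect_equal(yki_growth_rate(3, Y0 = 4), 0)
  y <- seq(0, 12, by = 0.5)
  r <- yki_growth_rate(y, g0 = 1e-3, Y0 = 4, rate_max = 5e-3)
  expect_true(all(diff(r) >= 0))
  expect_equal(max(r), 5e-3)
  expect_error(yki_growth_rate(-1), "yki")
})

test_that("a uniform fixed-tension configuration yields identical cells", {
  cfg <- fast_bsm_config(fixed_tension = 400)
  run <- run_bsm(cfg)
  expect_equal(nrow(run$summary), 7)
  expect_lt(diff(range(run$summary$yki)), 1e-9)
  expect_lt(diff(range(run$summary$bound_jub)), 1e-9)
})

test_that("the coupled run is deterministic", {
  cfg <- fast_bsm_config(fixed_tension = 500)
  r1 <- run_bsm(cfg)
  r2 <- run_bsm(cfg)
  expect_identical(r1$summary, r2$summary)
})

test_that("with mechanics, the six ring cells are equivalent by symmetry", {
  cfg <- bsm_config(horizon = 4, dt_couple = 1, boundary_force = 100)
  run <- run_bsm(cfg)
  ring <- run$summary[run$summary$cell_class == "boundary", ]
  expect_lt(diff(range(ring$yki)), 1e-6)
  expect_lt(diff(range(ring$tension)), 1e-6)
})

test_that("fixed-tension coupling equals the manually composed pipeline", {
  # oracle: with the tension prescribed, the alpha-catenin occupancies and
  # hence the Jub binding sites are constant, so the operator-split loop
  # must equal one uninterrupted integration of the single-cell system
  cfg <- fast_bsm_config(fixed_tension = 600)
  run <- run_bsm(cfg)

  geometry <- cell_geometry(6, "self")
  f <- per_molecule_force(600, cfg$alpha_catenin[1])
  occ <- equilibrium_occupancy(f, cfg$bell, cfg$vinculin)
  sites <- cfg$conv_nM * cfg$alpha_catenin[1] *
    matrix(occ, nrow = 6, ncol = 3, byrow = TRUE)
  attr(sites, "jub_production") <- cfg$jub_production[1]
  y0 <- c(as.numeric(suppressWarnings(
    hippo_steady_state(cfg$hippo, geometry))),
    rep(0, 6), cfg$jub_production[1] / cfg$jub_degradation)
  names(y0) <- hippomech:::bsm_cell_state_names(geometry)
  sol <- deSolve::ode(y = y0, times = c(0, cfg$horizon),
                      func = hippomech:::bsm_cell_ode,
                      parms = list(cfg = cfg, geometry = geometry,
                                   sites = sites),
                      method = "lsoda", atol = 1e-9, rtol = 1e-6)
  yki_direct <- sol[nrow(sol), "Yki_a"]
  expect_equal(run$summary$yki[1], unname(yki_direct), tolerance = 1e-6)
})

test_that("Jub production of zero silences the tension route", {
  cfg <- fast_bsm_config(fixed_tension = 600, jub_production = 0)
  run <- run_bsm(cfg)
  # without Jub there is no sequestration: Yki equals the stand-alone
  # Hippo steady state
  g <- cell_geometry(6, "self")
  ss <- hippo_steady_state(cfg$hippo, g)
  expect_equal(run$summary$yki[1],
               unname(hippo_summary(ss, g)["yki_active"]),
               tolerance = 1e-4)
  # and tension has no effect
  cfg2 <- fast_bsm_config(fixed_tension = 100, jub_production = 0)
  expect_equal(run_bsm(cfg2)$summary$yki[1], run$summary$yki[1],
               tolerance = 1e-6)
})

test_that("steady-state Yki rises with bound Jub through Wts sequestration", {
  cfg <- bsm_config()
  lo <- bsm_cell_steady(cfg, tension = 300, jub_production = 50)
  hi <- bsm_cell_steady(cfg, tension = 300, jub_production = 450)
  expect_gt(hi[["bound_jub"]], lo[["bound_jub"]])
  expect_lt(hi[["active_wts"]], lo[["active_wts"]])
  expect_gt(hi[["yki"]], lo[["yki"]])
})

test_that("configuration validation catches bad values", {
  expect_error(bsm_config(alpha_catenin = 0), "alpha_catenin")
  expect_error(bsm_config(jub_degradation = 0), "degradation")
  expect_error(bsm_config(KN = -5), "KN")
  expect_error(bsm_config(fixed_tension = -1), "fixed_tension")
  expect_error(bsm_config(dt_couple = 0), "dt_couple")
})
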