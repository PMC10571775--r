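test_that("hippo rhs: null dynamics, printed Wts binding term, region checks", {
  g <- cell_geometry(1)
  zero <- hippo_params(prod = setNames(rep(0, 8), names(hippo_params()$prod)),
                       deg = setNames(rep(0, 8), names(hippo_params()$deg)),
                       kFm = 0, kFr = 0, kDm = 0, kDr = 0, kEm = 0, kEr = 0,
                       kFD = 0, kFDr = 0, kAm = 0, kAr = 0, kRm = 0, kRr = 0,
                       kWAp = 0, kWAm = 0, kWRp = 0, kWRm = 0, kEWp = 0,
                       kEWm = 0, kdWA = 0, kiWR = 0, kYp = 0, kYd = 0,
                       kEY = 0)
  y <- hippo_initial_state(zero, g)
  y[] <- runif(length(y))
  expect_true(all(hippo_rhs(y, zero, g) == 0))

  # only Wts-Dachs binding active at unit rate: d[W]/dt = -k+ [W] [Am]
  p <- zero
  p$kWAp <- 1
  y <- hippo_initial_state(zero, g)
  y["Wts_c"] <- 1
  y["Dachs_m.1"] <- 1
  d <- hippo_rhs(y, p, g)
  expect_equal(d[["Wts_c"]], -1)
  expect_equal(d[["WA.1"]], 1)
  expect_equal(d[["Dachs_m.1"]], -1)  # binding consumes membrane Dachs
  expect_true(all(d[setdiff(names(d),
                            c("Wts_c", "WA.1", "Dachs_m.1"))] == 0))

  # geometry/state validation
  expect_error(hippo_rhs(y[-1], p, g), "entries")
  y2 <- y; y2["Wts_c"] <- -1
  expect_error(hippo_rhs(y2, p, g), "negative")
})

test_that("Wts material is conserved when production/degradation are off", {
  g <- cell_geometry(6)
  p <- hippo_params()
  p$prod[] <- 0; p$deg[] <- 0; p$kdWA <- 0; p$kiWR <- 0
  set.seed(42)
  for (i in 1:5) {
    y <- hippo_initial_state(hippo_params(), g)
    y[] <- runif(length(y), 0, 5)
    d <- hippo_rhs(y, p, g)
    expect_equal(wts_total(d), 0, tolerance = 1e-12)
  }
  # and along an actual trajectory
  y0 <- hippo_initial_state(hippo_params(), g)
  y0["Wts_c"] <- 4; y0[paste0("Dachs_m.", 1:6)] <- 1
  y0[paste0("Ex_m.", 1:6)] <- 1
  sol <- deSolve::ode(y = y0, times = seq(0, 50, by = 10),
                      func = function(t, y, q) list(hippo_rhs(y, p, g)),
                      parms = NULL, atol = 1e-10, rtol = 1e-8)
  tot <- apply(sol[, -1], 1, wts_total)
  expect_lt(max(abs(tot - tot[1])), 1e-6)
})

test_that("each reversible pair satisfies detailed balance in isolation", {
  # with only one binding pair active and fixed partners, the equilibrium
  # complex/free ratio is k+ [partner] / k-
  g <- cell_geometry(1)
  base <- hippo_params()
  zero_names <- setNames(rep(0, 8), names(base$prod))
  p <- hippo_params(prod = zero_names, deg = zero_names,
                    kFm = 0, kFr = 0, kDm = 0, kDr = 0, kEm = 0, kEr = 0,
                    kFD = 0, kFDr = 0, kAm = 0, kAr = 0, kRm = 0, kRr = 0,
                    kWAp = 0.4, kWAm = 0.8, kWRp = 0, kWRm = 0,
                    kEWp = 0, kEWm = 0, kdWA = 0, kiWR = 0,
                    kYp = 0, kYd = 0, kEY = 0)
  y0 <- hippo_initial_state(p, g)
  y0["Wts_c"] <- 2; y0["Dachs_m.1"] <- 3
  sol <- deSolve::ode(y = y0, times = c(0, 400),
                      func = function(t, y, q) list(hippo_rhs(y, p, g)),
                      parms = NULL, atol = 1e-12, rtol = 1e-10)
  yf <- sol[nrow(sol), -1]
  names(yf) <- names(y0)
  expect_equal(yf[["WA.1"]] / yf[["Wts_c"]],
               0.4 * yf[["Dachs_m.1"]] / 0.8, tolerance = 1e-6)
})

test_that("steady state solves the network and is a true attractor", {
  p <- hippo_params()
  g <- cell_geometry()
  ss <- hippo_steady_state(p, g)
  expect_true(attr(ss, "converged"))
  expect_lt(attr(ss, "residual"), 1e-8 * max(1, max(p$prod)))
  expect_true(all(ss >= 0))
  # oracle: re-integrate from a +/-10% perturbed start and return
  set.seed(7)
  y0 <- ss * runif(length(ss), 0.9, 1.1)
  sol <- deSolve::ode(y = y0, times = c(0, 2000),
                      func = function(t, y, q) list(hippo_rhs(y, p, g)),
                      parms = NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-8)
  yf <- sol[nrow(sol), -1]
  expect_lt(max(abs(yf - ss)), 1e-5 * max(ss))
  # a species with zero production but nonzero degradation vanishes
  p2 <- p; p2$prod[["Fj"]] <- 0
  ss2 <- hippo_steady_state(p2, g)
  names(ss2) <- names(ss)
  expect_equal(ss2[["Fj_c"]], 0, tolerance = 1e-10)
})

test_that("states stay non-negative under integration from valid starts", {
  p <- hippo_params()
  g <- cell_geometry()
  set.seed(11)
  y0 <- hippo_initial_state(p, g) * runif(69, 0, 2)
  sol <- deSolve::ode(y = y0, times = seq(0, 300, by = 60),
                      func = function(t, y, q)
                        list(hippo_rhs(pmax(y, 0), p, g)),
                      parms = NULL, atol = 1e-9, rtol = 1e-6)
  expect_true(all(sol[, -1] > -1e-7))
})

test_that("Fat production scan reproduces the canonical monotonicities", {
  p <- hippo_params()
  rng <- seq(0.3, 3, length.out = 6)
  sc <- fat_production_scan(p, rng, mode = c("parallel",
                                             "fat_stabilizes_ex"))
  expect_true(all(sc$converged))
  par <- sc[sc$mode == "parallel", ]
  stab <- sc[sc$mode == "fat_stabilizes_ex", ]
  # membrane Dachs falls, membrane Riq rises with Fat production
  expect_true(all(diff(par$membrane_dachs) < 0))
  expect_true(all(diff(par$membrane_riq) > 0))
  # Ex stabilization by Fat strengthens Yki inhibition, pointwise
  expect_true(all(stab$yki_active <= par$yki_active + 1e-9))
  # and strictly at the top of the range
  expect_lt(stab$yki_active[nrow(stab)], par$yki_active[nrow(par)])
  # input validation
  expect_error(fat_production_scan(p, c(1, 0.5, 2)), "ascending")
  expect_error(fat_production_scan(p, c(1, 2)), "5 points")
})

test_that("Yki falls monotonically as Ex->Yki inhibition strengthens", {
  g <- cell_geometry()
  yk <- vapply(c(0, 0.01, 0.05, 0.2), function(kEY) {
    p <- hippo_params(kEY = kEY)
    unname(hippo_summary(hippo_steady_state(p, g), g)["yki_active"])
  }, numeric(1))
  expect_true(all(diff(yk) < 0))
})
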