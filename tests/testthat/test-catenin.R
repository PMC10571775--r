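test_that("Hill factor matches its closed form and limits", {
  expect_equal(hill_factor(0, 1, 2, "decreasing"), 1)
  expect_equal(hill_factor(1, 1, 3, "increasing"), 0.5)
  expect_equal(hill_factor(1, 1, 3, "decreasing"), 0.5)
  expect_equal(hill_factor(2, 1, 2, "increasing"), 0.8)
  expect_error(hill_factor(1, -1, 2, "increasing"), "K")
  expect_error(hill_factor(1, 1, 0.5, "increasing"), "n")
  # stays in [0, 1] over a wide range
  x <- 10^seq(-3, 3, length.out = 25)
  for (d in c("increasing", "decreasing")) {
    v <- hill_factor(x, K = 5, n = 2, d)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("Bell lifetime follows the exponential force law", {
  p <- bell_params()
  expect_equal(bell_lifetime(0, p), p$tau0 * exp(p$E0 / p$kBT))
  expect_equal(bell_lifetime(p$E0 / p$gamma, p), p$tau0)
  # adding kBT*ln(2)/gamma to the force halves the lifetime
  f <- 3
  expect_equal(bell_lifetime(f + p$kBT * log(2) / p$gamma, p),
               bell_lifetime(f, p) / 2)
  expect_error(bell_lifetime(-1, p), "non-negative")
})

test_that("transition rates have Bell form and Vinculin acts on f1 only", {
  p <- bell_params()
  r0 <- transition_rates(0, p, V = 0)
  expect_equal(unname(r0), c(p$ku10, p$kf10, p$ku20, p$kf20))
  # doubling identity for the unfolding rate
  f <- 2.5
  expect_equal(transition_rates(f + p$kBT * log(2) / p$xu1, p)[["u1"]],
               2 * transition_rates(f, p)[["u1"]])
  # monotonicity in force
  fs <- seq(0, 20, by = 0.5)
  rs <- t(vapply(fs, transition_rates, numeric(4), params = p))
  expect_true(all(diff(rs[, "u1"]) > 0) && all(diff(rs[, "u2"]) > 0))
  expect_true(all(diff(rs[, "f1"]) < 0) && all(diff(rs[, "f2"]) < 0))
  # Vinculin: only f1 changes, with factor 1/(1 + V/KV)
  rV <- transition_rates(f, p, V = 4)
  rn <- transition_rates(f, p, V = 0)
  expect_equal(rV[c("u1", "u2", "f2")], rn[c("u1", "u2", "f2")])
  expect_equal(rV[["f1"]], rn[["f1"]] / (1 + 4 / p$KV))
})

test_that("equilibrium occupancies normalize and match the kinetic ODE limit", {
  p <- bell_params()
  for (f in c(0, 2, 4.5, 7, 12, 18)) {
    for (V in c(0, 5)) {
      eq <- equilibrium_occupancy(f, p, V)
      expect_equal(sum(eq), 1, tolerance = 1e-12)
      # oracle: long-horizon integration of the kinetic equations
      tr <- relax_catenin(f, p, V, horizon = 80)$trajectory
      kin <- unlist(tr[nrow(tr), c("C1", "C2", "C3")])
      expect_lt(max(abs(kin - eq)), 1e-8)
    }
  }
  # detailed-balance symmetry: where u1 = f1 the first two states tie
  fstar <- p$kBT * log(p$kf10 / p$ku10) / (p$xu1 + p$xf1)
  eq <- equilibrium_occupancy(fstar, p)
  expect_equal(eq[["C1"]], eq[["C2"]], tolerance = 1e-10)
})

test_that("occupancy monotonicity in force: C1 falls, C3 rises", {
  p <- bell_params()
  fs <- seq(0, 20, by = 0.25)
  occ <- t(vapply(fs, equilibrium_occupancy, numeric(3), params = p))
  expect_true(all(diff(occ[, 1]) <= 1e-12))
  expect_true(all(diff(occ[, 3]) >= -1e-12))
})

test_that("relaxation conserves occupancy and reports settling", {
  p <- bell_params()
  out <- relax_catenin(4.5, p, initial = c(1, 0, 0), horizon = 20)
  sums <- rowSums(out$trajectory[, c("C1", "C2", "C3")])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(out$settled)
  # starting at equilibrium settles immediately
  eq <- equilibrium_occupancy(3, p)
  expect_equal(relax_catenin(3, p, initial = eq)$settling_time, 0)
  # short horizon is flagged
  expect_warning(out2 <- relax_catenin(4.5, p, horizon = 0.5),
                 "horizon")
  expect_false(out2$settled)
})

test_that("bound Jub has the inhibited-middle-state profile", {
  p <- bell_params()
  expect_equal(bound_jub(5, p, jub_pool = 0),
               c(bound = 0, free = 0))
  f <- seq(0, 15, by = 0.05)
  b <- vapply(f, function(x) bound_jub(x, p, jub_pool = 30)[["bound"]], 0)
  # conservation bound + free = pool
  bf <- bound_jub(7, p, jub_pool = 30)
  expect_equal(bf[["bound"]] + bf[["free"]], 30, tolerance = 1e-6)
  # continuity: no jumps on a fine grid
  expect_lt(max(abs(diff(b))), 0.2)
  # rescaling all dissociation constants and the pool leaves the bound
  # fraction profile shape intact (same argmin)
  p2 <- bell_params(jub_K = p$jub_K * 10)
  b2 <- vapply(f, function(x)
    bound_jub(x, p2, jub_pool = 300, n_cat = 300)[["bound"]], 0)
  expect_equal(f[which.min(b)], f[which.min(b2)], tolerance = 0.5)
})

test_that("crossover detection errors cleanly without a bracket", {
  p <- bell_params()
  expect_error(crossover_force("C1C2", p, bracket = c(20, 30)),
               "crossover")
})
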