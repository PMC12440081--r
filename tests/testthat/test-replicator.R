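test_that("fitnesses are the payoff-row expectations", {
  dec <- game_decomposition(0.1, 0.2, 0.3)
  f <- fitnesses(dec, 0.5)
  expect_equal(f$f_w, 1.10)
  expect_equal(f$f_m, 1.25)
  # against the payoff expectation a(1-x) + bx and c(1-x) + dx
  P <- compose_payoff(dec)
  for (x in c(0, 0.25, 0.7, 1)) {
    f <- fitnesses(dec, x)
    expect_equal(f$f_w, P[1, 1] * (1 - x) + P[1, 2] * x)
    expect_equal(f$f_m, P[2, 1] * (1 - x) + P[2, 2] * x)
  }
  # pure-mutant limit returns the second-column entries b, d
  f1 <- fitnesses(dec, 1)
  expect_equal(c(f1$f_w, f1$f_m), c(1.2, 1.1))
  # no interactions: frequency independence
  f0 <- fitnesses(game_decomposition(0.3, 0, 0), c(0, 0.5, 1))
  expect_equal(f0$f_w, rep(1, 3))
  expect_equal(f0$f_m, rep(1.3, 3))
  expect_error(fitnesses(dec, 1.2), "\\[0, 1\\]")
})

test_that("sigma_m is the relative fitness advantage (f_m - f_w)/f_w", {
  set.seed(11)
  for (i in 1:1000) {
    dec <- random_decomposition(1)
    x <- runif(1)
    f <- fitnesses(dec, x)
    expect_equal(sigma_m(dec, x) * f$f_w, f$f_m - f$f_w, tolerance = 1e-12)
  }
  # no interactions: sigma reduces to s_m for every x
  expect_equal(sigma_m(game_decomposition(0.2, 0, 0), x_grid_101),
               rep(0.2, 101))
  # masking pair: sigma vanishes identically
  expect_equal(sigma_m(game_decomposition(0.2, 0.2, -0.2), x_grid_101),
               rep(0, 101))
  # interior zero of the masking-at-half family
  expect_equal(sigma_m(game_decomposition(0.1, 0.5, 0.3), 0.5), 0)
})

test_that("replicator velocity matches x(1-x)(f_m - f_w) and its zeros", {
  dec <- game_decomposition(0.1, 0.5, 0.3)
  expect_equal(replicator_rhs(dec, c(0, 1)), c(0, 0))
  expect_equal(replicator_rhs(game_decomposition(0.1, 0, 0), 0.5), 0.025)
  # masking: velocity vanishes on the whole grid
  expect_equal(replicator_rhs(game_decomposition(0.2, 0.2, -0.2), x_grid_101),
               rep(0, 101))
  set.seed(12)
  for (i in 1:100) {
    d <- random_decomposition(1)
    x <- runif(1)
    f <- fitnesses(d, x)
    expect_equal(replicator_rhs(d, x), x * (1 - x) * (f$f_m - f$f_w),
                 tolerance = 1e-12)
  }
})

test_that("fixed points include the admissible interior root with stability", {
  # selection only: mutant fixes
  fp <- fixed_points(game_decomposition(0.1, 0, 0))
  expect_equal(fp$points$x, c(0, 1))
  expect_identical(fp$points$stability, c("unstable", "stable"))
  # interior stable point at (s + a_mw)/(a_wm + a_mw) = 0.4/0.8
  fp2 <- fixed_points(game_decomposition(0.1, 0.5, 0.3))
  expect_equal(fp2$points$x, c(0, 0.5, 1))
  expect_identical(fp2$points$stability, c("unstable", "stable", "unstable"))
  # bistable game: interior unstable
  fp3 <- fixed_points(game_decomposition(0.1, -0.4, -0.3))
  xi <- (0.1 - 0.3) / (-0.4 - 0.3)
  expect_equal(fp3$points$x[2], xi, tolerance = 1e-12)
  expect_identical(fp3$points$stability, c("stable", "unstable", "stable"))
  # fully neutral game: degenerate
  expect_true(fixed_points(game_decomposition(0, 0, 0))$degenerate)
  # masking family is also identically stationary
  expect_true(fixed_points(game_decomposition(0.2, 0.2, -0.2))$degenerate)
  # interior root position to high accuracy on random coexistence games
  set.seed(13)
  for (i in 1:100) {
    d <- random_decomposition(1)
    den <- d$alpha_wm + d$alpha_mw
    if (den == 0) next
    xi <- (d$s_m + d$alpha_mw) / den
    fps <- fixed_points(d)
    if (xi > 0 && xi < 1) {
      expect_equal(sort(fps$points$x)[2], xi, tolerance = 1e-12)
    } else {
      expect_equal(nrow(fps$points), 2)
    }
  }
})

test_that("integration approaches the correct fixed point", {
  # no-interaction replicator equation has the logistic-form solution
  # x(t) = x0 e^{st} / (1 - x0 + x0 e^{st})
  dec <- game_decomposition(0.1, 0, 0)
  tr <- integrate_replicator(dec, 0.01, horizon = 100, n_out = 51)
  closed <- 0.01 * exp(0.1 * tr$time) / (1 - 0.01 + 0.01 * exp(0.1 * tr$time))
  expect_equal(tr$x, closed, tolerance = 1e-7)
  trlong <- integrate_replicator(dec, 0.01, horizon = 400)
  expect_lt(abs(tail(trlong$x, 1) - 1), 1e-6)
  # a fixed point stays fixed
  trfp <- integrate_replicator(game_decomposition(0.1, 0.5, 0.3), 0.5, 50)
  expect_equal(trfp$x, rep(0.5, length(trfp$x)))
  # masking: every start is stationary
  trmask <- integrate_replicator(game_decomposition(0.2, 0.2, -0.2), 0.3, 50)
  expect_equal(trmask$x, rep(0.3, length(trmask$x)), tolerance = 1e-9)
  # monotone between fixed points
  expect_true(all(diff(trlong$x) >= -1e-12))
})

test_that("deterministic regime pairs hold sigma_m at the target for all x", {
  for (s in c(0.05, 0.1, 0.2, 0.3)) {
    cases <- list(
      list(kind = "maintenance", s_m = s, target = s),
      list(kind = "masking", s_m = s, target = 0),
      list(kind = "mirroring", s_m = s, target = -s),
      list(kind = "mimicry", s_m = 0, target = s)
    )
    for (cs in cases) {
      pair <- regime_coefficients_deterministic(cs$kind, cs$s_m,
                                                target = cs$target)
      dec <- game_decomposition(cs$s_m, pair$alpha_wm, pair$alpha_mw)
      expect_lt(max(abs(sigma_m(dec, x_grid_101) - cs$target)), 1e-12)
    }
  }
  # printed coefficient values
  expect_equal(regime_coefficients_deterministic("masking", 0.3),
               list(alpha_mw = -0.3, alpha_wm = 0.3))
  expect_equal(regime_coefficients_deterministic("maintenance", 0.3),
               list(alpha_mw = 0, alpha_wm = 0))
  expect_equal(regime_coefficients_deterministic("mirroring", 0.2),
               list(alpha_mw = -0.4, alpha_wm = 0.5))
  # singular parameters are refused
  expect_error(regime_coefficients_deterministic("mirroring", 1), "singular")
  expect_error(regime_coefficients_deterministic("mimicry", 0, target = -1),
               "singular")
  expect_error(regime_coefficients_deterministic("mimicry", 0.1, target = 0.2),
               "s_m = 0")
})

test_that("regime dynamics are the non-interacting dynamics up to time rescaling", {
  # the interacting velocity divided by f_w(x) must equal the velocity of
  # the non-interacting system with selection equal to the regime target
  xs <- seq(0.01, 0.99, length.out = 25)
  for (s in c(0.1, 0.25)) {
    for (kind in c("maintenance", "masking", "mirroring")) {
      pair <- regime_coefficients_deterministic(kind, s)
      dec <- game_decomposition(s, pair$alpha_wm, pair$alpha_mw)
      target <- switch(kind, maintenance = s, masking = 0, mirroring = -s)
      ref <- xs * (1 - xs) * target
      f_w <- fitnesses(dec, xs)$f_w
      expect_equal(replicator_rhs(dec, xs) / f_w, ref, tolerance = 1e-12)
    }
    # mimicry: s_m = 0 but rescaled velocity matches selection s
    pair <- regime_coefficients_deterministic("mimicry", 0, target = s)
    dec <- game_decomposition(0, pair$alpha_wm, pair$alpha_mw)
    f_w <- fitnesses(dec, xs)$f_w
    expect_equal(replicator_rhs(dec, xs) / f_w, xs * (1 - xs) * s,
                 tolerance = 1e-12)
  }
  # pointwise-in-time equality additionally holds when alpha_wm = 0:
  # mimicry has alpha_wm != 0, maintenance has alpha_wm = 0
  dec0 <- game_decomposition(0.1, 0, 0)
  tr_ref <- integrate_replicator(dec0, 0.2, horizon = 80, n_out = 41)
  pairm <- regime_coefficients_deterministic("maintenance", 0.1)
  trm <- integrate_replicator(
    game_decomposition(0.1, pairm$alpha_wm, pairm$alpha_mw), 0.2,
    horizon = 80, n_out = 41)
  expect_equal(trm$x, tr_ref$x, tolerance = 1e-8)
})

test_that("constancy-based classification labels the four regimes", {
  expect_identical(
    classify_regime_dynamics(game_decomposition(0.2, 0.2, -0.2), 0.2),
    "masking")
  expect_identical(
    classify_regime_dynamics(game_decomposition(0.2, 0.5, -0.4), 0.2),
    "mirroring")
  expect_identical(
    classify_regime_dynamics(game_decomposition(0.2, 0, 0), 0.2),
    "maintenance")
  pair <- regime_coefficients_deterministic("mimicry", 0, target = 0.3)
  expect_identical(
    classify_regime_dynamics(
      game_decomposition(0, pair$alpha_wm, pair$alpha_mw), 0.3),
    "mimicry")
  # generic interacting game: sigma varies with x
  expect_identical(
    classify_regime_dynamics(game_decomposition(0.2, 0.3, 0.1), 0.2),
    "none")
})

test_that("steady-state equivalence classifies reached stable states", {
  # alternate-masking family alpha_mw = alpha_wm - 2 s_m, steady state 1/2
  dec <- game_decomposition(0.1, 0.5, 0.3)
  expect_identical(steady_state_equivalence(dec, 0.1, 0.3),
                   "alternate-masking")
  expect_equal(dec$alpha_mw, dec$alpha_wm - 2 * dec$s_m)
  # the non-interacting reference itself: maintenance
  expect_identical(
    steady_state_equivalence(game_decomposition(0.1, 0, 0), 0.1, 0.3),
    "maintenance")
  # alpha_mw < -s_m and alpha_wm > s_m: velocity negative on (0,1), so the
  # wild-type fixes although s_m > 0 - mirroring of the steady state
  decmir <- game_decomposition(0.1, 0.3, -0.2)
  expect_identical(steady_state_equivalence(decmir, 0.1, 0.5), "mirroring")
  tr <- integrate_replicator(decmir, 0.5, horizon = 2000)
  expect_lt(tail(tr$x, 1), 1e-3)
  # mimicry: s_m = 0 with one zero coefficient reaches fixation
  decmim <- game_decomposition(0, 0, 0.2)
  expect_identical(steady_state_equivalence(decmim, 0.2, 0.4), "mimicry")
  # degenerate game: no single steady state
  res <- steady_state_equivalence(game_decomposition(0, 0, 0), 0.1, 0.4)
  expect_identical(as.character(res), "none")
  expect_match(attr(res, "diagnostic"), "stationary")
})

test_that("long-run integration agrees with quadrant-predicted outcomes", {
  set.seed(14)
  for (dec in random_decomposition(12)) {
    gp <- game_coordinates(dec)
    if (gp$quadrant == "boundary") next
    for (x0 in c(0.1, 0.9)) {
      xf <- tail(integrate_replicator(dec, x0, horizon = 3000)$x, 1)
      fps <- fixed_points(dec)
      stable <- fps$points$x[fps$points$stability == "stable"]
      expect_true(min(abs(xf - stable)) < 1e-4)
      if (gp$quadrant == "mutant dominates") expect_gt(xf, 0.999)
      if (gp$quadrant == "wild-type dominates") expect_lt(xf, 0.001)
    }
  }
})
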