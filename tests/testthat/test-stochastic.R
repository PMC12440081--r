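test_that("the no-interaction mode solves the mutation-selection balance", {
  expect_equal(mode_no_interaction(0, 0.001), 0.5)
  expect_equal(mode_no_interaction(0, 0.1), 0.5)
  expect_identical(mode_no_interaction(0.1, 0), 1)
  expect_identical(mode_no_interaction(-0.1, 0), 0)
  expect_identical(mode_no_interaction(0, 0), 0.5)
  xm <- mode_no_interaction(0.1, 0.001)
  expect_equal(xm, 0.99010, tolerance = 1e-5)
  # residual of sigma x (1 - x) + mu (1 - 2x) at the root
  res <- 0.1 * xm * (1 - xm) + 0.001 * (1 - 2 * xm)
  expect_lt(abs(res), 1e-12)
  # continuity through sigma = 0 (slope there is 1/(8 mu)) and
  # monotonicity in sigma
  sig <- seq(-0.01, 0.01, length.out = 2001)
  xs <- vapply(sig, mode_no_interaction, numeric(1), mu = 1e-3)
  expect_lt(max(abs(diff(xs))), 3 * diff(sig)[1] / (8 * 1e-3))
  expect_true(all(diff(xs) > 0))
  expect_equal(xs[1001], 0.5)
})

test_that("closed-form selection at the mode equals direct evaluation", {
  # no interactions: recovers s_m
  expect_equal(sigma_at_mode(game_decomposition(0.25, 0, 0), 1e-3), 0.25)
  # equivalence with direct evaluation of sigma_m at the computed mode,
  # both signs of s_m
  set.seed(21)
  for (i in 1:1000) {
    dec <- random_decomposition(1)
    mu <- 10^runif(1, -4, -2)
    direct <- sigma_m(dec, mode_no_interaction(dec$s_m, mu))
    expect_lt(abs(sigma_at_mode(dec, mu) - direct),
              1e-12 * max(1, abs(direct)))
  }
  # s_m = 0 is the two-sided limit: evaluation at 1/2
  dec0 <- game_decomposition(0, 0.2, 0.1)
  expect_equal(sigma_at_mode(dec0, 1e-3), sigma_m(dec0, 0.5))
})

test_that("first-order stochastic surfaces match their printed forms", {
  expect_equal(
    unname(stochastic_surface_first_order("maintenance", 0.1, 0.001, 0.5)),
    0.0045455, tolerance = 1e-5)
  expect_equal(
    unname(stochastic_surface_first_order("masking", 0.1, 0.001, 0.3)), 0.5)
  expect_equal(
    unname(stochastic_surface_first_order("mimicry", 0, 0.001, 0.3,
                                          sigma_target = 0.1)),
    -0.0890909, tolerance = 1e-6)
  # masking surface confirms the interior equilibrium at 1/2
  dec <- game_decomposition(0.1, 0.5, 0.3)
  fp <- fixed_points(dec)
  expect_equal(sort(fp$points$x)[2], 0.5)
  # invalid combinations are refused
  expect_error(stochastic_surface_first_order("maintenance", 0, 1e-3, 0.3),
               "s_m != 0")
  expect_error(stochastic_surface_first_order("mimicry", 0.1, 1e-3, 0.3,
                                              sigma_target = 0.1), "s_m = 0")
  expect_error(stochastic_surface_first_order("mimicry", 0, 1e-3, 0.3,
                                              sigma_target = 0), "sigma")
})

test_that("surfaces reduce to the deterministic regime pairs as mu -> 0", {
  for (s in c(0.05, 0.2)) {
    det <- regime_coefficients_deterministic("maintenance", s)
    expect_equal(
      unname(stochastic_surface_first_order("maintenance", s, 0, 0.4)),
      det$alpha_wm)
    detm <- regime_coefficients_deterministic("mirroring", s)
    expect_equal(
      unname(stochastic_surface_first_order("mirroring", s, 0,
                                            detm$alpha_wm)),
      detm$alpha_mw)
    detk <- regime_coefficients_deterministic("masking", s)
    expect_equal(
      unname(stochastic_surface_first_order("masking", s, 0, detk$alpha_mw)),
      detk$alpha_wm)
    deti <- regime_coefficients_deterministic("mimicry", 0, target = s)
    expect_equal(
      unname(stochastic_surface_first_order("mimicry", 0, 0, deti$alpha_mw,
                                            sigma_target = s)),
      deti$alpha_wm)
    expect_equal(
      unname(stochastic_surface_exact("mimicry", 0, 0, deti$alpha_mw,
                                      sigma_target = s)),
      deti$alpha_wm, tolerance = 1e-9)
  }
  # printed deterministic mimicry limit value
  expect_equal(
    unname(stochastic_surface_exact("mimicry", 0, 0, 0.3, sigma_target = 0.1)),
    -0.0909091, tolerance = 1e-6)
})

test_that("exact surfaces satisfy the implicit condition and masking is exact", {
  for (kind in c("maintenance", "mirroring")) {
    con <- stochastic_surface_exact(kind, 0.1, 1e-3, 0.5)
    dec <- if (kind == "mirroring") {
      game_decomposition(0.1, 0.5, unname(con))
    } else {
      game_decomposition(0.1, unname(con), 0.5)
    }
    target <- if (kind == "mirroring") -0.1 else 0.1
    expect_lt(abs(sigma_m(dec, mode_no_interaction(target, 1e-3)) - target),
              1e-10)
  }
  # the masking condition is exactly linear: both solvers coincide
  expect_equal(unname(stochastic_surface_exact("masking", 0.1, 1e-3, 0.3)),
               unname(stochastic_surface_first_order("masking", 0.1, 1e-3,
                                                     0.3)),
               tolerance = 1e-12)
})

test_that("first-order surfaces converge to the exact solve as mu shrinks", {
  mus <- c(1e-2, 3e-3, 1e-3, 3e-4)
  for (kind in c("maintenance", "mirroring", "mimicry")) {
    errs <- vapply(mus, function(mu) {
      if (kind == "mimicry") {
        abs(stochastic_surface_exact(kind, 0, mu, 0.3, sigma_target = 0.1) -
              stochastic_surface_first_order(kind, 0, mu, 0.3,
                                             sigma_target = 0.1))
      } else {
        abs(stochastic_surface_exact(kind, 0.1, mu, 0.5) -
              stochastic_surface_first_order(kind, 0.1, mu, 0.5))
      }
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
    slope <- unname(coef(lm(log(errs) ~ log(mus)))[2])
    # at least quadratic in mu (measured slope is ~3: the mu^2 error
    # coefficient of each printed surface vanishes identically)
    expect_gt(slope, 1.8)
  }
})

test_that("the Wright-Fisher chain stationary law matches the mode theory", {
  # neutral symmetric chain: distribution symmetric, mode at 1/2
  sd0 <- wf_stationary_distribution(game_decomposition(0, 0, 0), 200, 0.01)
  p <- sd0$distribution$probability
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_true(all(p >= 0))
  expect_equal(p, rev(p), tolerance = 1e-9)
  expect_equal(sd0$mode, 0.5)
  # selection-only chain: mode near the mutation-selection balance
  sd1 <- wf_stationary_distribution(game_decomposition(0.1, 0, 0), 1000,
                                    0.001)
  expect_lt(abs(sd1$mode - 0.9901), 0.02)
  # masking pair: interacting chain peaks at the neutral 1/2
  sd2 <- wf_stationary_distribution(game_decomposition(0.1, 0.5, 0.3), 1000,
                                    0.001)
  expect_lt(abs(sd2$mode - 0.5), 0.02)
  # mu = 0 has absorbing fixation states
  expect_error(wf_stationary_distribution(game_decomposition(0.1, 0, 0),
                                          100, 0), "absorbing|fixation")
})

test_that("exact-surface chains reproduce the target reference mode", {
  # interacting chain built on each exact surface has the same stationary
  # mode as the non-interacting chain with selection equal to the target
  N <- 1000
  mu <- 1e-3
  for (s in c(0.05, 0.1, 0.2)) {
    ref_main <- wf_stationary_distribution(game_decomposition(s, 0, 0),
                                           N, mu)$mode
    con <- unname(stochastic_surface_exact("maintenance", s, mu, 0.3))
    m <- wf_stationary_distribution(game_decomposition(s, con, 0.3),
                                    N, mu)$mode
    expect_lt(abs(m - ref_main), 0.02) # two 101-bin histogram bins
    conm <- unname(stochastic_surface_exact("mirroring", s, mu,
                                            2 * s / (1 - s)))
    ref_mir <- wf_stationary_distribution(game_decomposition(-s, 0, 0),
                                          N, mu)$mode
    mm <- wf_stationary_distribution(
      game_decomposition(s, 2 * s / (1 - s), conm), N, mu)$mode
    expect_lt(abs(mm - ref_mir), 0.02)
  }
})
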