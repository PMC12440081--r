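#' Frequency-dependent fitnesses of wild-type and mutant
#'
#' Expected payoffs of each type when the mutant fraction is `x`:
#' `f_w(x) = 1 + alpha_wm * x` and `f_m(x) = 1 + s_m + alpha_mw * (1 - x)`,
#' equal to the payoff-matrix expectations `a (1 - x) + b x` and
#' `c (1 - x) + d x`.
#'
#' @param dec A `game_decomposition`.
#' @param x Mutant fraction(s) in `[0, 1]`.
#' @return A list with numeric vectors `f_w` and `f_m`.
#' @examples
#' fitnesses(game_decomposition(0.1, 0.2, 0.3), x = 0.5)
#' @export
fitnesses <- function(dec, x) {
  dec <- as_game_decomposition(dec)
  check_fraction(x)
  list(f_w = 1 + dec$alpha_wm * x,
       f_m = 1 + dec$s_m + dec$alpha_mw * (1 - x))
}

check_fraction <- function(x, name = "x") {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a mutant fraction in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Frequency-dependent selection coefficient
#'
#' The relative fitness advantage of the mutant at mutant fraction `x`,
#' `sigma_m(x) = (f_m(x) - f_w(x)) / f_w(x)`, which in decomposed
#' coefficients reads
#' `(s_m + alpha_mw - (alpha_wm + alpha_mw) x) / (1 + alpha_wm x)`.
#' When both interaction coefficients vanish it reduces to the intrinsic
#' selection coefficient `s_m` for every `x`.
#'
#' @inheritParams fitnesses
#' @return Numeric vector of selection coefficients, one per `x`.
#' @examples
#' sigma_m(game_decomposition(0.2, 0.2, -0.2), x = c(0, 0.5, 1)) # masked: 0
#' @export
sigma_m <- function(dec, x) {
  dec <- as_game_decomposition(dec)
  check_fraction(x)
  (dec$s_m + dec$alpha_mw - (dec$alpha_wm + dec$alpha_mw) * x) /
    (1 + dec$alpha_wm * x)
}

#' Right-hand side of the replicator equation
#'
#' `dx/dt = x (1 - x) [(c - a)(1 - x) - (b - d) x]`, identically equal to
#' `x (1 - x) (f_m(x) - f_w(x))`.
#'
#' @inheritParams fitnesses
#' @return Numeric vector `dx/dt`, one value per `x`.
#' @export
replicator_rhs <- function(dec, x) {
  dec <- as_game_decomposition(dec)
  check_fraction(x)
  u <- dec$s_m + dec$alpha_mw   # c - a
  v <- dec$alpha_wm - dec$s_m   # b - d
  x * (1 - x) * (u * (1 - x) - v * x)
}

#' Fixed points of the replicator equation and their stability
#'
#' The boundaries `x = 0` and `x = 1` are always stationary; an interior
#' stationary point `x* = (s_m + alpha_mw) / (alpha_wm + alpha_mw)`
#' (equivalently `(c - a) / ((b - d) + (c - a))`) is included when it lies
#' in `(0, 1)`. Stability is determined from the sign of the replicator
#' velocity on either side of each point. A game whose velocity vanishes
#' identically (the masking family, including the fully neutral game) is
#' returned with `degenerate = TRUE`: every `x` is stationary.
#'
#' @param dec A `game_decomposition`.
#' @param eps Half-width of the neighbourhood used for sign sampling.
#' @return An object of class `fixed_point_set`: a list with a data frame
#'   `points` (columns `x`, `stability` in `stable`/`unstable`/`degenerate`)
#'   and a logical `degenerate`.
#' @examples
#' fixed_points(game_decomposition(0.1, 0.5, 0.3)) # interior point at 0.5
#' @export
fixed_points <- function(dec, eps = 1e-6) {
  dec <- as_game_decomposition(dec)
  u <- dec$s_m + dec$alpha_mw
  v <- dec$alpha_wm - dec$s_m
  if (u == 0 && v == 0) {
    pts <- data.frame(x = c(0, 1), stability = "degenerate",
                      stringsAsFactors = FALSE)
    out <- list(points = pts, degenerate = TRUE)
    class(out) <- "fixed_point_set"
    return(out)
  }
  xs <- c(0, 1)
  if ((u + v) != 0) {
    xi <- u / (u + v)
    if (xi > 0 && xi < 1) xs <- sort(c(xs, xi))
  }
  stab <- vapply(xs, function(x0) {
    # sign of the velocity just inside each side of the point; boundaries
    # only have one interior side
    s_left <- if (x0 > 0) sign(replicator_rhs(dec, x0 - eps)) else NULL
    s_right <- if (x0 < 1) sign(replicator_rhs(dec, x0 + eps)) else NULL
    sides <- c(if (!is.null(s_left)) s_left > 0 else NULL,   # inflow from left
               if (!is.null(s_right)) s_right < 0 else NULL) # inflow from right
    if (any(c(s_left, s_right) == 0)) "degenerate"
    else if (all(sides)) "stable"
    else "unstable"
  }, character(1))
  out <- list(points = data.frame(x = xs, stability = stab,
                                  stringsAsFactors = FALSE),
              degenerate = FALSE)
  class(out) <- "fixed_point_set"
  out
}

#' @export
print.fixed_point_set <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate replicator dynamics: every x in [0, 1] is stationary\n")
  } else {
    cat("Replicator fixed points:\n")
    print(x$points, row.names = FALSE)
  }
  invisible(x)
}

#' Numerically integrate the replicator equation
#'
#' Solves `dx/dt = x (1 - x)(f_m - f_w)` with an adaptive solver
#' (`deSolve::ode`, lsoda) at absolute and relative tolerance `tol`,
#' clipping the state to `[0, 1]`.
#'
#' @param dec A `game_decomposition`.
#' @param x0 Initial mutant fraction in `[0, 1]`.
#' @param horizon Final time (generations; time is dimensionless since the
#'   wild-type reference growth is 1).
#' @param n_out Number of equally spaced output times (including `t = 0`).
#' @param tol Solver tolerance (both absolute and relative).
#' @return A data frame of class `replicator_trajectory` with columns
#'   `time` and `x`.
#' @examples
#' tr <- integrate_replicator(game_decomposition(0.1, 0, 0), 0.01, 500)
#' tail(tr, 1) # approaches fixation of the mutant
#' @export
integrate_replicator <- function(dec, x0, horizon = 1000, n_out = 201,
                                 tol = 1e-10) {
  dec <- as_game_decomposition(dec)
  check_fraction(x0, "x0")
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(
    y = c(x = x0), times = times,
    func = function(t, y, parms) {
      x <- min(max(y[[1]], 0), 1)
      list(replicator_rhs(dec, x))
    },
    atol = tol, rtol = tol
  )
  out <- data.frame(time = sol[, "time"],
                    x = pmin(pmax(sol[, "x"], 0), 1))
  class(out) <- c("replicator_trajectory", "data.frame")
  out
}

regime_kinds <- c("maintenance", "masking", "mirroring", "mimicry")

#' Interaction coefficients of the deterministic regimes
#'
#' For each regime the pair `(alpha_mw, alpha_wm)` that makes the
#' frequency-dependent selection coefficient constant in `x` and equal to
#' the regime's target:
#'
#' * maintenance (`sigma_m(x) = s_m`): `(0, 0)` — the only solution;
#' * masking (`sigma_m(x) = 0`, `s_m != 0`): `(-s_m, s_m)`;
#' * mirroring (`sigma_m(x) = -s_m`): `(-2 s_m, 2 s_m / (1 - s_m))`;
#' * mimicry (`s_m = 0`, `sigma_m(x) = s'`): `(s', -s'/(1 + s'))`.
#'
#' @param kind One of `"maintenance"`, `"masking"`, `"mirroring"`,
#'   `"mimicry"`.
#' @param s_m Intrinsic selection coefficient (must be 0 for mimicry,
#'   nonzero for masking and mirroring).
#' @param target For mimicry, the nonzero target selection coefficient
#'   `s'`; ignored otherwise.
#' @return A named list with `alpha_mw` and `alpha_wm`.
#' @examples
#' regime_coefficients_deterministic("masking", s_m = 0.3)
#' @export
regime_coefficients_deterministic <- function(kind, s_m, target = NULL) {
  kind <- match.arg(kind, regime_kinds)
  switch(kind,
    maintenance = list(alpha_mw = 0, alpha_wm = 0),
    masking = {
      if (s_m == 0) stop("masking requires s_m != 0", call. = FALSE)
      list(alpha_mw = -s_m, alpha_wm = s_m)
    },
    mirroring = {
      if (s_m == 0) stop("mirroring requires s_m != 0", call. = FALSE)
      if (s_m == 1) stop("mirroring is singular at s_m = 1 ",
                         "(alpha_wm = 2 s_m / (1 - s_m))", call. = FALSE)
      list(alpha_mw = -2 * s_m, alpha_wm = 2 * s_m / (1 - s_m))
    },
    mimicry = {
      if (s_m != 0) stop("mimicry requires s_m = 0", call. = FALSE)
      if (is.null(target) || target == 0) {
        stop("mimicry requires a nonzero target selection coefficient",
             call. = FALSE)
      }
      if (target == -1) stop("mimicry is singular at target s' = -1",
                             call. = FALSE)
      list(alpha_mw = target, alpha_wm = -target / (1 + target))
    }
  )
}

#' Classify a game by the constancy of its selection coefficient
#'
#' Tests whether `sigma_m(x)` is constant in `x` by clearing the (positive)
#' denominator and matching polynomial coefficients: constancy at value
#' `t = s_m + alpha_mw` requires
#' `(alpha_wm + alpha_mw) + t * alpha_wm = 0`. A constant coefficient is
#' then matched against the reference: `s` (maintenance), `-s` (mirroring),
#' `0` with `s_m != 0` (masking), or nonzero with `s_m = 0` (mimicry).
#'
#' @param dec A `game_decomposition`.
#' @param s_ref Reference intrinsic selection coefficient (usually
#'   `dec$s_m`, or the nonzero target for mimicry).
#' @param tol Tolerance for the polynomial-identity and value comparisons.
#' @return One of the regime labels or `"none"`.
#' @examples
#' classify_regime_dynamics(game_decomposition(0.2, 0.2, -0.2), 0.2) # masking
#' @export
classify_regime_dynamics <- function(dec, s_ref, tol = 1e-9) {
  dec <- as_game_decomposition(dec)
  t_const <- dec$s_m + dec$alpha_mw
  residual <- (dec$alpha_wm + dec$alpha_mw) + t_const * dec$alpha_wm
  if (abs(residual) > tol) return("none")
  if (abs(t_const) <= tol) {
    if (abs(dec$s_m) > tol) return("masking")
    return(if (abs(s_ref) <= tol) "maintenance" else "none")
  }
  if (abs(dec$s_m) <= tol) {
    return("mimicry")
  }
  if (abs(t_const - s_ref) <= tol) return("maintenance")
  if (abs(t_const + s_ref) <= tol) return("mirroring")
  "none"
}

#' Steady-state equivalence of an interacting game
#'
#' Determines the stable steady state reached from `x0` (by fixed-point
#' stability and basin membership) and compares it with the outcome of a
#' non-interacting system with selection `s_ref`: the same fixation
#' (`maintenance`, or `mimicry` when `s_m = 0`), the opposite fixation
#' (`mirroring`), or the half-half state 1/2 (`alternate-masking`, the
#' family `alpha_mw = alpha_wm - 2 s_m` with `alpha_wm + alpha_mw > 0`).
#'
#' @param dec A `game_decomposition`.
#' @param s_ref Nonzero reference selection coefficient of the
#'   non-interacting comparison system.
#' @param x0 Initial mutant fraction in `(0, 1)`.
#' @param tol Tolerance for matching steady states.
#' @return One of `"maintenance"`, `"mirroring"`, `"alternate-masking"`,
#'   `"mimicry"`, `"none"`. Degenerate (identically stationary) games
#'   return `"none"` with a `"diagnostic"` attribute.
#' @examples
#' steady_state_equivalence(game_decomposition(0.1, 0.5, 0.3), 0.1, 0.3)
#' @export
steady_state_equivalence <- function(dec, s_ref, x0, tol = 1e-9) {
  dec <- as_game_decomposition(dec)
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie in (0, 1)", call. = FALSE)
  fps <- fixed_points(dec)
  if (fps$degenerate) {
    out <- "none"
    attr(out, "diagnostic") <- paste(
      "replicator velocity vanishes identically; every state is stationary",
      "and no single steady state is reached")
    return(out)
  }
  v0 <- replicator_rhs(dec, x0)
  xs <- fps$points$x
  x_inf <- if (abs(v0) == 0 && any(abs(xs - x0) < tol)) {
    x0
  } else if (v0 > 0) {
    min(xs[xs > x0 + tol])
  } else {
    max(xs[xs < x0 - tol])
  }
  if (abs(x_inf - 0.5) <= tol) return("alternate-masking")
  x_ref <- if (s_ref > 0) 1 else if (s_ref < 0) 0 else NA_real_
  if (is.na(x_ref)) return("none")
  if (abs(x_inf - x_ref) <= tol) {
    return(if (dec$s_m == 0) "mimicry" else "maintenance")
  }
  if (abs(x_inf - (1 - x_ref)) <= tol) return("mirroring")
  "none"
}
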