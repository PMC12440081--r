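#' Modal mutant fraction under mutation-selection balance, no interactions
#'
#' For a non-interacting system with constant selection `sigma` and
#' symmetric per-generation mutation rate `mu`, the mode of the stationary
#' frequency distribution solves the mutation-selection equilibrium
#' `sigma x (1 - x) + mu (1 - 2 x) = 0`. Its root in `[0, 1]` is
#' `x_mode = (sigma - 2 mu + R) / (2 sigma)` with
#' `R = sqrt(sigma^2 + 4 mu^2)`, computed here in the cancellation-free
#' form `2 mu / (R + 2 mu - sigma)`, which is continuous through
#' `sigma = 0` (value 1/2). At `mu = 0` the balance degenerates to
#' fixation: 1 for `sigma > 0`, 0 for `sigma < 0`, and 1/2 (the neutral
#' convention) for `sigma = 0`.
#'
#' @param sigma Constant selection coefficient (any sign).
#' @param mu Symmetric per-generation mutation rate, `mu >= 0`.
#' @return The modal mutant fraction in `[0, 1]`.
#' @examples
#' mode_no_interaction(0.1, 0.001) # 0.99010
#' mode_no_interaction(0, 0.001)   # 0.5
#' @export
mode_no_interaction <- function(sigma, mu) {
  stopifnot(is.finite(sigma), is.finite(mu), mu >= 0)
  if (mu == 0) {
    return(if (sigma > 0) 1 else if (sigma < 0) 0 else 0.5)
  }
  R <- sqrt(sigma^2 + 4 * mu^2)
  2 * mu / (R + 2 * mu - sigma)
}

#' Selection coefficient evaluated at the non-interacting mode
#'
#' Closed form for `sigma_m(x_mode)`: the frequency-dependent selection
#' coefficient of a decomposed game evaluated at the modal frequency that
#' the system would occupy *without* interactions (the hypothetical
#' selection that appears when interactions are switched on in a system
#' equilibrated without them). Substituting
#' `x_mode = (s_m - 2 mu + R) / (2 s_m)`, `R = sqrt(s_m^2 + 4 mu^2)`, into
#' the selection coefficient and scaling numerator and denominator by
#' `2 s_m` gives
#'
#' \deqn{\sigma_m(x_{mode}) = \frac{2 s_m^2 + s_m(\alpha_{mw} -
#'   \alpha_{wm}) + (2\mu - R)(\alpha_{mw} + \alpha_{wm})}
#'   {2 s_m + \alpha_{wm}(s_m + R - 2\mu)}}
#'
#' which holds for either sign of `s_m` and reduces to `s_m` when both
#' interaction coefficients vanish. At `s_m = 0` the two-sided limit is
#' returned (direct evaluation at `x = 1/2`).
#'
#' @param dec A `game_decomposition`.
#' @param mu Symmetric per-generation mutation rate.
#' @return The selection coefficient at the non-interacting mode.
#' @examples
#' sigma_at_mode(game_decomposition(0.1, 0, 0), 0.001) # s_m itself
#' @export
sigma_at_mode <- function(dec, mu) {
  dec <- as_game_decomposition(dec)
  stopifnot(is.finite(mu), mu >= 0)
  s <- dec$s_m
  if (s == 0) {
    return(sigma_m(dec, 0.5))
  }
  R <- sqrt(s^2 + 4 * mu^2)
  den <- 2 * s + dec$alpha_wm * (s + R - 2 * mu)
  if (den == 0) {
    stop("sigma_at_mode is singular for these parameters (denominator 0)",
         call. = FALSE)
  }
  (2 * s^2 + s * (dec$alpha_mw - dec$alpha_wm) +
      (2 * mu - R) * (dec$alpha_mw + dec$alpha_wm)) / den
}

regime_target <- function(kind, s_m, sigma_target = NULL) {
  switch(kind,
    maintenance = s_m,
    masking = 0,
    mirroring = -s_m,
    mimicry = sigma_target
  )
}

check_stochastic_regime_args <- function(kind, s_m, sigma_target) {
  if (kind %in% c("maintenance", "masking", "mirroring") && s_m == 0) {
    stop(kind, " requires s_m != 0", call. = FALSE)
  }
  if (kind == "mimicry") {
    if (s_m != 0) stop("mimicry requires s_m = 0", call. = FALSE)
    if (is.null(sigma_target) || sigma_target == 0 || sigma_target == -1) {
      stop("mimicry requires a target sigma not in {0, -1}", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' First-order stochastic regime surfaces
#'
#' Constraints on one interaction coefficient, to first order in the
#' mutation rate `mu`, under which the selection coefficient evaluated at
#' the non-interacting modal frequency of the regime's reference system
#' equals the regime target (`s_m` for maintenance, 0 for masking, `-s_m`
#' for mirroring, a chosen `sigma` for mimicry with `s_m = 0`):
#'
#' * maintenance: `alpha_wm = mu * alpha_mw / (s_m (1 + s_m))`;
#' * masking: `alpha_wm = alpha_mw + 2 s_m` (exact and independent of
#'   `mu`, since the reference mode is 1/2);
#' * mirroring: `alpha_mw = -2 s_m + mu (alpha_wm (1 - s_m) - 2 s_m) /
#'   s_m` (solved for `alpha_mw`; solving for `alpha_wm` instead
#'   introduces a term of order `1/mu`);
#' * mimicry: `alpha_wm = -sigma/(1 + sigma) + mu (alpha_mw - sigma) /
#'   (sigma (1 + sigma))`.
#'
#' In the limit `mu -> 0` each surface reduces to the deterministic regime
#' pair of [regime_coefficients_deterministic()].
#'
#' @param kind Regime name.
#' @param s_m Intrinsic selection coefficient (0 for mimicry, nonzero
#'   otherwise).
#' @param mu Symmetric per-generation mutation rate.
#' @param free Value of the free interaction coefficient: `alpha_mw` for
#'   maintenance, masking and mimicry; `alpha_wm` for mirroring.
#' @param sigma_target Mimicry target selection coefficient.
#' @return The constrained coefficient, named `alpha_wm` (or `alpha_mw`
#'   for mirroring).
#' @examples
#' stochastic_surface_first_order("maintenance", 0.1, 0.001, free = 0.5)
#' @export
stochastic_surface_first_order <- function(kind, s_m, mu, free,
                                           sigma_target = NULL) {
  kind <- match.arg(kind, regime_kinds)
  check_stochastic_regime_args(kind, s_m, sigma_target)
  stopifnot(is.finite(mu), mu >= 0, is.finite(free))
  switch(kind,
    maintenance = c(alpha_wm = mu * free / (s_m * (1 + s_m))),
    masking = c(alpha_wm = free + 2 * s_m),
    mirroring = c(alpha_mw = -2 * s_m + mu * (free * (1 - s_m) - 2 * s_m) / s_m),
    mimicry = c(alpha_wm = -sigma_target / (1 + sigma_target) +
                  mu * (free - sigma_target) /
                  (sigma_target * (1 + sigma_target)))
  )
}

#' Exact stochastic regime surfaces by one-dimensional root finding
#'
#' Solves the implicit regime condition exactly: the selection coefficient
#' of the interacting game, evaluated at the non-interacting modal
#' frequency of the regime's *target* reference system
#' (`x_mode(s_m, mu)` for maintenance, 1/2 for masking, `x_mode(-s_m, mu)`
#' for mirroring, `x_mode(sigma, mu)` for mimicry), equals the target. The
#' root in the constrained coefficient is found by bracketed root finding
#' started around the first-order value. Serves as the reference against
#' which the printed first-order surfaces converge as `mu -> 0`.
#'
#' @inheritParams stochastic_surface_first_order
#' @return The constrained coefficient (same naming as the first-order
#'   surface).
#' @examples
#' stochastic_surface_exact("masking", 0.1, 0.001, free = 0.3) # alpha_mw + 2 s_m
#' @export
stochastic_surface_exact <- function(kind, s_m, mu, free,
                                     sigma_target = NULL) {
  kind <- match.arg(kind, regime_kinds)
  check_stochastic_regime_args(kind, s_m, sigma_target)
  stopifnot(is.finite(mu), mu >= 0, is.finite(free))
  target <- regime_target(kind, s_m, sigma_target)
  x_star <- mode_no_interaction(target, mu)
  fn <- function(z) {
    if (kind == "mirroring") {
      awm <- free; amw <- z
    } else {
      awm <- z; amw <- free
    }
    (s_m + amw - (awm + amw) * x_star) / (1 + awm * x_star) - target
  }
  z0 <- unname(stochastic_surface_first_order(kind, s_m, mu, free,
                                              sigma_target))
  h <- max(0.1, abs(z0) * 0.5)
  lo <- z0 - h
  hi <- z0 + h
  # keep the bracket inside the domain where the focal denominator is
  # positive when the unknown is alpha_wm
  repeat {
    if (kind != "mirroring" && x_star > 0) lo <- max(lo, -1 / x_star + 1e-9)
    flo <- fn(lo)
    fhi <- fn(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) break
    h <- h * 2
    lo <- z0 - h
    hi <- z0 + h
    if (h > 1e3) {
      stop("no sign change found while bracketing the exact surface in [",
           signif(z0 - h, 4), ", ", signif(z0 + h, 4), "]", call. = FALSE)
    }
  }
  root <- stats::uniroot(fn, c(lo, hi), tol = 1e-14)$root
  names(root) <- if (kind == "mirroring") "alpha_mw" else "alpha_wm"
  root
}

#' Stationary distribution of the frequency-dependent Wright-Fisher chain
#'
#' Builds the `(N + 1)`-state transition matrix of the Wright-Fisher model
#' with fitness-weighted sampling and symmetric mutation (selection
#' weighting first, then mutation of the expected frequency, then binomial
#' resampling — the identical event order used by the simulator) and
#' solves for its stationary probability vector by direct linear solve.
#' Requires `mu > 0` for irreducibility.
#'
#' @param dec A `game_decomposition`.
#' @param N Population size (integer, at least 2).
#' @param mu Symmetric per-generation mutation rate, strictly positive.
#' @return An object of class `stationary_distribution`: a list with a
#'   data frame `distribution` (columns `count`, `probability`), the
#'   population size `N`, and `mode` (the argmax mutant fraction
#'   `count / N`).
#' @examples
#' sd0 <- wf_stationary_distribution(game_decomposition(0, 0, 0), 100, 0.01)
#' sd0$mode # 0.5 by symmetry
#' @export
wf_stationary_distribution <- function(dec, N, mu) {
  dec <- as_game_decomposition(dec)
  stopifnot(N >= 2, N == as.integer(N))
  if (mu <= 0) {
    stop("mu = 0 makes fixation states absorbing and no stationary ",
         "distribution exists; use fixation-probability analysis instead",
         call. = FALSE)
  }
  x <- (0:N) / N
  p_succ <- wf_expected_frequency(dec, x, mu)
  # transition matrix row i -> binomial(N, p_succ[i])
  Tm <- t(vapply(p_succ, function(p) stats::dbinom(0:N, N, p),
                 numeric(N + 1)))
  # stationary row vector: pi (Tm - I) = 0 with sum(pi) = 1
  A <- t(Tm - diag(N + 1))
  A[N + 1, ] <- 1
  b <- c(rep(0, N), 1)
  pi_vec <- solve(A, b)
  pi_vec[pi_vec < 0] <- 0
  pi_vec <- pi_vec / sum(pi_vec)
  out <- list(
    distribution = data.frame(count = 0:N, probability = pi_vec),
    N = N,
    mode = (which.max(pi_vec) - 1L) / N
  )
  class(out) <- "stationary_distribution"
  out
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher stationary distribution over %d states (N = %d)\n",
    nrow(x$distribution), x$N))
  cat(sprintf("  mode at mutant fraction %.4f\n", x$mode))
  invisible(x)
}
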