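#' Game-space coordinates and quadrant of a payoff matrix
#'
#' Places a game in the classical two-player game space with coordinates
#' `u = c - a` (invasion fitness of the mutant into the wild-type) and
#' `v = b - d` (invasion fitness of the wild-type into the mutant). In
#' decomposition terms `u = s_m + alpha_mw` and `v = alpha_wm - s_m`. The
#' four sign quadrants determine the qualitative deterministic outcome:
#'
#' * `u > 0, v > 0`: stable coexistence (often called Harmony),
#' * `u > 0, v < 0`: the mutant dominates (Prisoner's Dilemma position),
#' * `u < 0, v < 0`: bistability with an unstable interior point (Snow
#'   Drift position),
#' * `u < 0, v > 0`: the wild-type dominates (Stag Hunt position).
#'
#' Exact zeros of `u` or `v` are classified as `"boundary"` rather than
#' being absorbed into a quadrant.
#'
#' @param P A `payoff_matrix` or `game_decomposition`.
#' @return A list of class `game_point` with elements `u`, `v`, `quadrant`
#'   (one of `"wild-type dominates"`, `"coexistence"`, `"mutant dominates"`,
#'   `"bistable"`, `"boundary"`) and `game_name` (quadrant name, `NA` on a
#'   boundary).
#' @examples
#' game_coordinates(payoff_matrix(1, 1.2, 1.4, 1.1))
#' @export
game_coordinates <- function(P) {
  if (inherits(P, "game_decomposition")) {
    u <- P$s_m + P$alpha_mw
    v <- P$alpha_wm - P$s_m
  } else {
    e <- payoff_entries(P)
    u <- e[["c"]] - e[["a"]]
    v <- e[["b"]] - e[["d"]]
  }
  if (u == 0 || v == 0) {
    quadrant <- "boundary"
    game_name <- NA_character_
  } else if (u > 0 && v > 0) {
    quadrant <- "coexistence"
    game_name <- "Harmony"
  } else if (u > 0 && v < 0) {
    quadrant <- "mutant dominates"
    game_name <- "Prisoner's Dilemma"
  } else if (u < 0 && v < 0) {
    quadrant <- "bistable"
    game_name <- "Snow Drift"
  } else {
    quadrant <- "wild-type dominates"
    game_name <- "Stag Hunt"
  }
  structure(list(u = unname(u), v = unname(v), quadrant = quadrant,
                 game_name = game_name),
            class = "game_point")
}

#' @export
print.game_point <- function(x, ...) {
  cat(sprintf("Game-space point: u = c - a = %g, v = b - d = %g\n", x$u, x$v))
  cat(sprintf("  quadrant: %s%s\n", x$quadrant,
              if (is.na(x$game_name)) "" else paste0(" (", x$game_name, ")")))
  invisible(x)
}

#' Interaction-selection coordinates of a decomposed game
#'
#' Scales the two ecological interaction coefficients by the intrinsic
#' selection coefficient, giving the point
#' `(rho_mw, rho_wm) = (alpha_mw / s_m, alpha_wm / s_m)`. Inside the unit
#' circle intrinsic selection dominates the dynamics; outside, ecological
#' interactions dominate. When `s_m = 0` the ratios are undefined and both
#' coordinates are returned non-finite with dominance `"undefined"`.
#'
#' @param dec A `game_decomposition` (or normalized `payoff_matrix`).
#' @return A list of class `interaction_selection_point` with elements
#'   `rho_mw`, `rho_wm` and `dominance` (one of `"intrinsic-dominated"`,
#'   `"ecology-dominated"`, `"boundary"`, `"undefined"`).
#' @examples
#' interaction_selection_point(game_decomposition(0.1, 0.05, 0.05))
#' @export
interaction_selection_point <- function(dec) {
  dec <- as_game_decomposition(dec)
  if (dec$s_m == 0) {
    rho_mw <- if (dec$alpha_mw == 0) NaN else dec$alpha_mw / 0
    rho_wm <- if (dec$alpha_wm == 0) NaN else dec$alpha_wm / 0
    dominance <- "undefined"
  } else {
    rho_mw <- dec$alpha_mw / dec$s_m
    rho_wm <- dec$alpha_wm / dec$s_m
    nrm2 <- rho_mw^2 + rho_wm^2
    dominance <- if (nrm2 < 1) "intrinsic-dominated"
                 else if (nrm2 > 1) "ecology-dominated"
                 else "boundary"
  }
  structure(list(rho_mw = rho_mw, rho_wm = rho_wm, dominance = dominance),
            class = "interaction_selection_point")
}

#' @export
print.interaction_selection_point <- function(x, ...) {
  cat(sprintf(
    "Interaction-selection point: (alpha_mw/s_m, alpha_wm/s_m) = (%g, %g)\n",
    x$rho_mw, x$rho_wm))
  cat("  dominance:", x$dominance, "\n")
  invisible(x)
}
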