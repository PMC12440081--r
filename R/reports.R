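#' Annotated decomposition table
#'
#' Takes a payoff table (a data frame with columns `label`, `condition`,
#' `a`, `b`, `c`, `d`, or a path readable by [import_payoff_table()]) and
#' appends, for every decomposable row, the decomposition
#' (`s_m`, `alpha_wm`, `alpha_mw`), the game-space quadrant, the
#' interaction-selection dominance, and the interaction-selection
#' coordinates. Rows that cannot be normalized or decomposed keep their
#' diagnostics and `NA` annotations; the run continues.
#'
#' @param table A data frame or a file path.
#' @return The input table with appended columns `s_m`, `alpha_wm`,
#'   `alpha_mw`, `quadrant`, `dominance`, `rho_mw`, `rho_wm` (plus the
#'   per-row validity diagnostics).
#' @export
decompose_table <- function(table) {
  if (is.character(table)) {
    table <- import_payoff_table(table)
  } else if (!"decomposable" %in% names(table)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    utils::write.csv(table, tmp, row.names = FALSE)
    table <- import_payoff_table(tmp)
  }
  n <- nrow(table)
  table$s_m <- NA_real_
  table$alpha_wm <- NA_real_
  table$alpha_mw <- NA_real_
  table$quadrant <- NA_character_
  table$dominance <- NA_character_
  table$rho_mw <- NA_real_
  table$rho_wm <- NA_real_
  for (i in seq_len(n)) {
    if (!table$decomposable[i]) next
    P <- normalize_payoff(payoff_matrix(table$a[i], table$b[i],
                                        table$c[i], table$d[i]))
    dec <- decompose_payoff(P)
    gp <- game_coordinates(P)
    isp <- interaction_selection_point(dec)
    table$s_m[i] <- dec$s_m
    table$alpha_wm[i] <- dec$alpha_wm
    table$alpha_mw[i] <- dec$alpha_mw
    table$quadrant[i] <- gp$quadrant
    table$dominance[i] <- isp$dominance
    table$rho_mw[i] <- isp$rho_mw
    table$rho_wm[i] <- isp$rho_wm
  }
  table
}

#' Regime coefficients with automatic verification
#'
#' Computes the interaction-coefficient pair for a requested regime —
#' deterministic (constant selection coefficient in `x`) or stochastic
#' (selection matched at the reference mode) — and verifies it: for
#' deterministic regimes the maximum deviation of `sigma_m(x)` from the
#' target over a 101-point grid; for stochastic regimes the residual of
#' the selection-at-mode condition.
#'
#' @param kind Regime kind.
#' @param s_m Intrinsic selection coefficient.
#' @param framework `"deterministic"` or `"stochastic"`.
#' @param mu Mutation rate (stochastic framework).
#' @param free Free coefficient value (stochastic framework; see
#'   [stochastic_surface_first_order()]).
#' @param sigma_target Mimicry target.
#' @param method Stochastic surface solver.
#' @return A list with `alpha_mw`, `alpha_wm`, `target`, `residual` and
#'   the echoed request.
#' @export
regime_report <- function(kind, s_m,
                          framework = c("deterministic", "stochastic"),
                          mu = 1e-3, free = 0.3, sigma_target = NULL,
                          method = c("first_order", "exact")) {
  kind <- match.arg(kind, regime_kinds)
  framework <- match.arg(framework)
  method <- match.arg(method)
  if (framework == "deterministic") {
    pair <- regime_coefficients_deterministic(kind, s_m, target = sigma_target)
    dec <- game_decomposition(s_m, pair$alpha_wm, pair$alpha_mw)
    target <- switch(kind, maintenance = s_m, masking = 0,
                     mirroring = -s_m, mimicry = sigma_target)
    grid <- seq(0, 1, length.out = 101)
    residual <- max(abs(sigma_m(dec, grid) - target))
    alpha_mw <- pair$alpha_mw
    alpha_wm <- pair$alpha_wm
  } else {
    solver <- if (method == "exact") stochastic_surface_exact
              else stochastic_surface_first_order
    constrained <- solver(kind, s_m, mu, free, sigma_target = sigma_target)
    if (kind == "mirroring") {
      alpha_mw <- unname(constrained)
      alpha_wm <- free
    } else {
      alpha_mw <- free
      alpha_wm <- unname(constrained)
    }
    target <- regime_target(kind, s_m, sigma_target)
    dec <- game_decomposition(s_m, alpha_wm, alpha_mw)
    residual <- sigma_m(dec, mode_no_interaction(target, mu)) - target
  }
  list(kind = kind, framework = framework, s_m = s_m, mu = mu,
       alpha_mw = alpha_mw, alpha_wm = alpha_wm,
       target = target, residual = residual, method = method)
}

#' Distance table for decomposed experiments
#'
#' Runs [rank_experiments()] on an annotated decomposition table (the
#' output of [decompose_table()]), skipping rows without a valid
#' decomposition, and returns the per-experiment, per-regime distance
#' table with closest-experiment flags. An empty or fully invalid input
#' yields an empty table with a warning rather than an error.
#'
#' @param decomp A data frame with `label`, `s_m`, `alpha_mw`, `alpha_wm`
#'   (extra columns ignored).
#' @inheritParams rank_experiments
#' @return See [rank_experiments()].
#' @export
distance_table <- function(decomp, regimes = distance_regimes, mu = 1e-3,
                           method = c("first_order", "exact")) {
  method <- match.arg(method)
  if ("decomposable" %in% names(decomp)) {
    decomp <- decomp[decomp$decomposable %in% TRUE, , drop = FALSE]
  }
  decomp <- decomp[is.finite(decomp$s_m), , drop = FALSE]
  if (nrow(decomp) == 0) {
    warning("no valid decompositions to rank; returning empty table",
            call. = FALSE)
    return(data.frame(label = character(), regime = character(),
                      d_min = numeric(), proj_s_m = numeric(),
                      proj_alpha_mw = numeric(), proj_alpha_wm = numeric(),
                      converged = logical(), diagnostic = character(),
                      closest = logical(), stringsAsFactors = FALSE))
  }
  rank_experiments(decomp, regimes = regimes, mu = mu, method = method)
}

#' Provenance record for a reproducible run
#'
#' @param config Named list of resolved parameters to echo.
#' @param seed The seed in effect.
#' @return A list with the package version, timestamp-free config echo
#'   and seed, suitable for writing next to any output.
#' @export
provenance_record <- function(config = list(), seed = NA_integer_) {
  list(package = "ecoevogames",
       version = as.character(utils::packageVersion("ecoevogames")),
       seed = seed,
       config = config)
}

#' Write a trajectory, fixed-point report or table to disk
#'
#' Small writers for the package's tabular contracts: trajectories as CSV
#' `[t, x]`, fixed points as JSON with stability labels, stationary
#' distributions as CSV `[count, probability]`.
#'
#' @param x The object (`replicator_trajectory`, `fixed_point_set`,
#'   `stationary_distribution`, or data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "fixed_point_set")) {
    jsonlite::write_json(
      list(degenerate = x$degenerate, points = x$points),
      path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "replicator_trajectory")) {
    utils::write.csv(data.frame(t = x$time, x = x$x), path,
                     row.names = FALSE)
  } else if (inherits(x, "stationary_distribution")) {
    utils::write.csv(x$distribution, path, row.names = FALSE)
  } else if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    stop("no writer for objects of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  invisible(path)
}
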