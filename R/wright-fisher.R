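#' Expected next-generation mutant frequency
#'
#' The deterministic part of one Wright-Fisher generation: selection
#' weighting first, `p* = x f_m / (x f_m + (1 - x) f_w)`, then symmetric
#' mutation of the expected frequency,
#' `p** = p* (1 - mu) + (1 - p*) mu`. The next generation is a binomial
#' sample of size `N` with success probability `p**`.
#'
#' @param dec A `game_decomposition`.
#' @param x Current mutant fraction(s) in `[0, 1]`.
#' @param mu Symmetric per-generation mutation rate.
#' @return The post-selection, post-mutation expected frequency.
#' @export
wf_expected_frequency <- function(dec, x, mu) {
  f <- fitnesses(dec, x)
  if (any(f$f_w < 0) || any(f$f_m < 0)) {
    stop("non-positive fitness encountered; payoff parameters invalid",
         call. = FALSE)
  }
  denom <- x * f$f_m + (1 - x) * f$f_w
  if (any(denom <= 0)) {
    stop("mean population fitness is non-positive; payoff parameters invalid",
         call. = FALSE)
  }
  p_star <- x * f$f_m / denom
  p_star * (1 - 2 * mu) + mu
}

#' One Wright-Fisher generation step
#'
#' Draws the next mutant count from `Binomial(N, p**)` where `p**` is the
#' selection-weighted, mutated expected frequency of
#' [wf_expected_frequency()]. Uses the current R random number stream.
#'
#' @param count Current mutant count in `0..N`.
#' @param dec A `game_decomposition`.
#' @param N Population size.
#' @param mu Symmetric per-generation mutation rate.
#' @return The next mutant count.
#' @export
wf_step <- function(count, dec, N, mu) {
  stopifnot(count >= 0, count <= N)
  p <- wf_expected_frequency(dec, count / N, mu)
  stats::rbinom(1L, N, p)
}

#' Simulation parameter set
#'
#' Bundles and validates the parameters of a Wright-Fisher ensemble run.
#' Defaults follow the regime-validation protocol: start from a 50:50
#' population, discard 1000 burn-in generations, average the next 3000,
#' and run 50 independent replicates.
#'
#' @param dec A `game_decomposition`.
#' @param N Population size (positive integer; typical range 100-10000).
#' @param mu Symmetric per-generation mutation rate, `mu >= 0`.
#' @param x0 Initial mutant fraction in `[0, 1]`.
#' @param generations Total generations simulated per replicate.
#' @param burn_in Generations discarded before averaging
#'   (`burn_in < generations`).
#' @param replicates Number of independent replicates.
#' @param seed Master RNG seed (integer); per-replicate streams are
#'   derived from it by a counter scheme so ensembles are reproducible and
#'   independent of evaluation order.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(dec, N = 1000, mu = 1e-3, x0 = 0.5,
                       generations = 4000, burn_in = 1000,
                       replicates = 50, seed = 1L) {
  dec <- as_game_decomposition(dec)
  stopifnot(N >= 2, N == as.integer(N), mu >= 0, mu <= 0.5,
            generations >= 1, burn_in >= 0, burn_in < generations,
            replicates >= 1)
  check_fraction(x0, "x0")
  structure(list(dec = dec, N = as.integer(N), mu = mu, x0 = x0,
                 generations = as.integer(generations),
                 burn_in = as.integer(burn_in),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# deterministic, order-independent per-replicate sub-seed
replicate_seed <- function(master, i) {
  as.integer((as.numeric(master) + i * 1299709) %% 2147483647)
}

#' Simulate one Wright-Fisher replicate
#'
#' Runs `generations` steps of the frequency-dependent Wright-Fisher chain
#' and returns the full trajectory of mutant fractions. Bit-reproducible
#' for a fixed seed.
#'
#' @param params A `sim_params` object.
#' @param seed Seed for this replicate; defaults to the master seed in
#'   `params`.
#' @return A data frame with columns `generation` (`0..generations`) and
#'   `x` (mutant fraction).
#' @export
run_replicate <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  dec <- params$dec
  N <- params$N
  mu <- params$mu
  s <- dec$s_m
  awm <- dec$alpha_wm
  amw <- dec$alpha_mw
  G <- params$generations
  counts <- integer(G + 1L)
  counts[1L] <- as.integer(round(params$x0 * N))
  k <- counts[1L]
  for (g in seq_len(G)) {
    x <- k / N
    f_w <- 1 + awm * x
    f_m <- 1 + s + amw * (1 - x)
    p <- x * f_m / (x * f_m + (1 - x) * f_w)
    p <- p * (1 - 2 * mu) + mu
    k <- stats::rbinom(1L, N, p)
    counts[g + 1L] <- k
  }
  data.frame(generation = 0:G, x = counts / N)
}

#' Pooled stationary samples from a replicate-vectorized engine
#'
#' Runs many Wright-Fisher replicates simultaneously (one binomial draw
#' per replicate per generation) and pools the post-burn-in mutant
#' fractions. This is the same stochastic process as [run_replicate()]
#' (identical event order and sampling law) organised for large pooled
#' sample sizes, e.g. for histogram or total-variation comparisons against
#' the stationary distribution.
#'
#' @param dec A `game_decomposition`.
#' @param N Population size.
#' @param mu Mutation rate.
#' @param x0 Initial mutant fraction.
#' @param generations,burn_in Total and discarded generations.
#' @param replicates Number of simultaneous replicates.
#' @param seed RNG seed.
#' @param thin Keep every `thin`-th post-burn-in generation.
#' @return Numeric vector of pooled mutant fractions, length
#'   `replicates * floor((generations - burn_in) / thin)`.
#' @export
wf_pooled_sample <- function(dec, N, mu, x0 = 0.5, generations = 2000,
                             burn_in = 500, replicates = 100, seed = 1L,
                             thin = 1L) {
  dec <- as_game_decomposition(dec)
  stopifnot(burn_in < generations)
  set.seed(seed)
  s <- dec$s_m
  awm <- dec$alpha_wm
  amw <- dec$alpha_mw
  k <- rep.int(as.integer(round(x0 * N)), replicates)
  keep <- seq.int(burn_in + 1L, generations, by = thin)
  out <- matrix(0, nrow = length(keep), ncol = replicates)
  row <- 0L
  next_keep <- 1L
  for (g in seq_len(generations)) {
    x <- k / N
    f_w <- 1 + awm * x
    f_m <- 1 + s + amw * (1 - x)
    p <- x * f_m / (x * f_m + (1 - x) * f_w)
    p <- p * (1 - 2 * mu) + mu
    k <- stats::rbinom(replicates, N, p)
    if (next_keep <= length(keep) && g == keep[next_keep]) {
      row <- row + 1L
      out[row, ] <- k / N
      next_keep <- next_keep + 1L
    }
  }
  as.vector(out)
}

#' Histogram mode of pooled fractions
#'
#' Argmax of a fixed-bin histogram on `[0, 1]`. Ties are broken toward the
#' bin nearest `prefer` when given (e.g. the analytic prediction under
#' test); the tie-break, if any, is recorded in the `"ties"` attribute.
#'
#' @param x Numeric vector of fractions in `[0, 1]`.
#' @param bins Number of equal-width bins (default 101).
#' @param prefer Optional value toward which exact count ties are broken.
#' @return The midpoint of the modal bin.
#' @export
histogram_mode <- function(x, bins = 101L, prefer = NULL) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  counts <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                               1L), bins), nbins = bins)
  top <- which(counts == max(counts))
  if (length(top) > 1L && !is.null(prefer)) {
    pick <- top[which.min(abs(mids[top] - prefer))]
  } else {
    pick <- top[1L]
  }
  out <- mids[pick]
  attr(out, "ties") <- length(top)
  out
}

#' Run a Wright-Fisher replicate ensemble
#'
#' Runs `replicates` independent chains (per-replicate seeds derived from
#' the master seed), discards the burn-in, and summarises the remainder:
#' per-replicate time-averaged mutant fraction, their grand mean and
#' inter-replicate standard deviation, and the histogram mode of the
#' pooled post-burn-in fractions.
#'
#' @param params A `sim_params` object.
#' @param mode_prefer Optional analytic prediction used only to break
#'   exact histogram ties in the mode estimate.
#' @return An object of class `ensemble_summary` with elements
#'   `per_replicate_mean`, `grand_mean`, `dispersion`, `mode_estimate`,
#'   `pooled` (the pooled post-burn-in fractions) and `params`.
#' @examples
#' p <- sim_params(game_decomposition(0, 0, 0), N = 200, mu = 0.01,
#'                 generations = 300, burn_in = 100, replicates = 5)
#' run_ensemble(p)$grand_mean
#' @export
run_ensemble <- function(params, mode_prefer = NULL) {
  stopifnot(inherits(params, "sim_params"))
  keep <- seq.int(params$burn_in + 2L, params$generations + 1L)
  pooled <- vector("list", params$replicates)
  means <- numeric(params$replicates)
  for (i in seq_len(params$replicates)) {
    tr <- run_replicate(params, seed = replicate_seed(params$seed, i))
    xs <- tr$x[keep]
    means[i] <- mean(xs)
    pooled[[i]] <- xs
  }
  pooled <- unlist(pooled, use.names = FALSE)
  out <- list(
    per_replicate_mean = means,
    grand_mean = mean(means),
    dispersion = stats::sd(means),
    mode_estimate = as.numeric(histogram_mode(pooled, prefer = mode_prefer)),
    pooled = pooled,
    params = params
  )
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher ensemble: %d replicates, N = %d, mu = %g\n",
    x$params$replicates, x$params$N, x$params$mu))
  cat(sprintf("  grand mean mutant fraction: %.4f (sd %.4f)\n",
              x$grand_mean, x$dispersion))
  cat(sprintf("  pooled histogram mode:      %.4f\n", x$mode_estimate))
  invisible(x)
}

#' Paired regime-validation experiment
#'
#' For every combination of regime kind, intrinsic selection value and
#' mutation rate, runs a selection-only ensemble (no interactions; for
#' mimicry the neutral system) and a with-interaction ensemble whose
#' coefficients lie on the requested regime surface, and tabulates the
#' summaries next to the analytic modal predictions.
#'
#' @param kinds Character vector of regime kinds.
#' @param s_values Intrinsic selection coefficients (interpreted as the
#'   mimicry target `sigma` for mimicry cells, where `s_m = 0`).
#' @param mu_values Mutation rates.
#' @param free_alpha_mw Free `alpha_mw` used for maintenance, masking and
#'   mimicry surfaces.
#' @param surface `"exact"` or `"first_order"` surface solver.
#' @param N,x0,generations,burn_in,replicates,seed Simulation protocol
#'   passed to [sim_params()].
#' @return A tidy data frame, one row per (kind, s, mu, arm), with the
#'   interaction coefficients, ensemble summaries, pooled standard error
#'   and the analytic modal value for that arm.
#' @export
regime_experiment <- function(kinds = regime_kinds,
                              s_values = c(0.05, 0.1, 0.2),
                              mu_values = c(1e-2, 1e-3),
                              free_alpha_mw = 0.3,
                              surface = c("exact", "first_order"),
                              N = 1000, x0 = 0.5, generations = 4000,
                              burn_in = 1000, replicates = 50, seed = 1L) {
  surface <- match.arg(surface)
  solver <- if (surface == "exact") stochastic_surface_exact
            else stochastic_surface_first_order
  rows <- list()
  cell <- 0L
  for (kind in kinds) {
    for (s in s_values) {
      for (mu in mu_values) {
        cell <- cell + 1L
        if (kind == "mimicry") {
          s_m <- 0
          pair <- c(alpha_mw = free_alpha_mw,
                    solver("mimicry", 0, mu, free_alpha_mw, sigma_target = s))
          target <- s
        } else if (kind == "mirroring") {
          s_m <- s
          awm_free <- 2 * s / (1 - s)
          pair <- c(solver("mirroring", s, mu, awm_free),
                    alpha_wm = awm_free)
          target <- -s
        } else {
          s_m <- s
          pair <- c(alpha_mw = free_alpha_mw,
                    solver(kind, s, mu, free_alpha_mw))
          target <- if (kind == "masking") 0 else s
        }
        dec_int <- game_decomposition(s_m, pair[["alpha_wm"]],
                                      pair[["alpha_mw"]])
        dec_sel <- game_decomposition(s_m, 0, 0)
        for (arm in c("selection_only", "with_interaction")) {
          dec_arm <- if (arm == "selection_only") dec_sel else dec_int
          analytic <- if (arm == "selection_only") {
            mode_no_interaction(s_m, mu)
          } else {
            mode_no_interaction(target, mu)
          }
          ens <- run_ensemble(
            sim_params(dec_arm, N = N, mu = mu, x0 = x0,
                       generations = generations, burn_in = burn_in,
                       replicates = replicates,
                       seed = replicate_seed(seed, cell)),
            mode_prefer = analytic)
          rows[[length(rows) + 1L]] <- data.frame(
            kind = kind, s = s, mu = mu, arm = arm,
            alpha_mw = if (arm == "selection_only") 0 else pair[["alpha_mw"]],
            alpha_wm = if (arm == "selection_only") 0 else pair[["alpha_wm"]],
            grand_mean = ens$grand_mean,
            dispersion = ens$dispersion,
            se = ens$dispersion / sqrt(replicates),
            mode_estimate = ens$mode_estimate,
            analytic_mode = analytic,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
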