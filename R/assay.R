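#' Generate a synthetic growth-frequency assay
#'
#' Emulates a mono-/co-culture game assay: each type's per-capita growth
#' rate is measured at a set of seeding mutant fractions. Under the
#' decomposed game the noise-free rates are linear in the mutant fraction
#' `x`: wild-type `g_w(x) = 1 + alpha_wm * x` and mutant
#' `g_m(x) = (1 + s_m + alpha_mw) - alpha_mw * x`. Independent Gaussian
#' measurement noise of standard deviation `noise_sd` is added to every
#' observation.
#'
#' @param dec The generating `game_decomposition` (ground truth).
#' @param fractions Seeding mutant fractions in `[0, 1]`.
#' @param noise_sd Standard deviation of the measurement noise (same units
#'   as the growth rates), `>= 0`.
#' @param replicates Replicate measurements per type and fraction.
#' @param seed RNG seed for reproducibility.
#' @param experiment Label stored in the `experiment` column.
#' @return A data frame with columns `experiment`, `type` (`"wild-type"` /
#'   `"mutant"`), `mutant_fraction`, `growth_rate`, `replicate`.
#' @examples
#' a <- generate_synthetic_assay(game_decomposition(0.1, 0.2, 0.3),
#'                               noise_sd = 0, replicates = 1)
#' decompose_payoff(normalize_payoff(payoff_from_fits(fit_growth_frequency(a))))
#' @export
generate_synthetic_assay <- function(dec,
                                     fractions = c(0, 0.25, 0.5, 0.75, 1),
                                     noise_sd = 0.02, replicates = 3,
                                     seed = NULL,
                                     experiment = "synthetic") {
  dec <- as_game_decomposition(dec)
  check_fraction(fractions, "fractions")
  stopifnot(noise_sd >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      mutant_fraction = fractions,
                      type = c("wild-type", "mutant"),
                      stringsAsFactors = FALSE)
  truth <- ifelse(grid$type == "wild-type",
                  1 + dec$alpha_wm * grid$mutant_fraction,
                  (1 + dec$s_m + dec$alpha_mw) -
                    dec$alpha_mw * grid$mutant_fraction)
  data.frame(experiment = experiment,
             type = grid$type,
             mutant_fraction = grid$mutant_fraction,
             growth_rate = truth + stats::rnorm(nrow(grid), 0, noise_sd),
             replicate = grid$replicate,
             stringsAsFactors = FALSE)
}

#' Fit growth-frequency lines to assay measurements
#'
#' Ordinary least squares of growth rate against seeding mutant fraction,
#' one line per type (the model assumes linear frequency dependence;
#' wild-type monoculture sits at `x = 0`, mutant monoculture at `x = 1`).
#' A quadratic curvature check is run per type: if a squared-fraction term
#' is significant at the 0.05 level a warning is issued, since non-linear
#' frequency dependence is outside the payoff-matrix model.
#'
#' @param data A data frame with columns `type`, `mutant_fraction`,
#'   `growth_rate` (the schema of [generate_synthetic_assay()]).
#' @param weighted If `TRUE`, fits replicate-mean values weighted by
#'   replicate counts instead of raw observations.
#' @return An object of class `assay_fit`: per-type `intercept`, `slope`,
#'   their standard errors, residual SD and the curvature p-value.
#' @export
fit_growth_frequency <- function(data, weighted = FALSE) {
  needed <- c("type", "mutant_fraction", "growth_rate")
  if (!all(needed %in% names(data))) {
    stop("assay data must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  fits <- lapply(c("wild-type", "mutant"), function(tp) {
    d <- data[data$type == tp, , drop = FALSE]
    if (nrow(d) == 0) {
      stop("insufficient data: no measurements for type '", tp, "'",
           call. = FALSE)
    }
    if (length(unique(d$mutant_fraction)) < 2) {
      stop("insufficient data: type '", tp, "' needs measurements at ",
           ">= 2 distinct seeding fractions for a line fit", call. = FALSE)
    }
    if (weighted) {
      agg <- stats::aggregate(growth_rate ~ mutant_fraction, data = d, mean)
      w <- stats::aggregate(growth_rate ~ mutant_fraction, data = d, length)
      fit <- stats::lm(growth_rate ~ mutant_fraction, data = agg,
                       weights = w$growth_rate)
    } else {
      fit <- stats::lm(growth_rate ~ mutant_fraction, data = d)
    }
    co <- suppressWarnings(summary(fit)$coefficients)
    curv_p <- NA_real_
    if (length(unique(d$mutant_fraction)) >= 3 && nrow(d) >= 4) {
      fit2 <- stats::lm(growth_rate ~ mutant_fraction + I(mutant_fraction^2),
                        data = d)
      co2 <- suppressWarnings(summary(fit2)$coefficients)
      if ("I(mutant_fraction^2)" %in% rownames(co2) &&
          abs(co2["I(mutant_fraction^2)", "Estimate"]) > 1e-8) {
        curv_p <- co2["I(mutant_fraction^2)", "Pr(>|t|)"]
      }
    }
    list(type = tp,
         intercept = unname(co["(Intercept)", "Estimate"]),
         slope = unname(co["mutant_fraction", "Estimate"]),
         intercept_se = unname(co["(Intercept)", "Std. Error"]),
         slope_se = unname(co["mutant_fraction", "Std. Error"]),
         residual_sd = suppressWarnings(summary(fit)$sigma),
         curvature_p = curv_p)
  })
  names(fits) <- c("wild_type", "mutant")
  for (f in fits) {
    if (!is.na(f$curvature_p) && f$curvature_p < 0.05) {
      warning("significant quadratic frequency dependence for the ", f$type,
              " line (p = ", signif(f$curvature_p, 3),
              "); the linear payoff model may be inadequate", call. = FALSE)
    }
  }
  structure(fits, class = "assay_fit")
}

#' @export
print.assay_fit <- function(x, ...) {
  cat("Growth-frequency line fits (growth rate ~ mutant fraction)\n")
  for (f in x) {
    cat(sprintf("  %-9s intercept %.4f (se %.4f), slope %.4f (se %.4f)\n",
                f$type, f$intercept, f$intercept_se, f$slope, f$slope_se))
  }
  invisible(x)
}

#' Payoff matrix from growth-frequency fits
#'
#' Reads the four payoff entries off the fitted lines: `a` and `b` are the
#' wild-type line at `x = 0` and `x = 1`; `c` and `d` are the mutant line
#' at `x = 0` and `x = 1` (monoculture values at one boundary, co-culture
#' extrapolations at the other).
#'
#' @param fit An `assay_fit`.
#' @return A `payoff_matrix` (not yet normalized).
#' @export
payoff_from_fits <- function(fit) {
  stopifnot(inherits(fit, "assay_fit"))
  w <- fit$wild_type
  m <- fit$mutant
  payoff_matrix(a = w$intercept, b = w$intercept + w$slope,
                c = m$intercept, d = m$intercept + m$slope)
}

#' Recover a game decomposition from assay data
#'
#' Convenience pipeline: [fit_growth_frequency()], [payoff_from_fits()],
#' [normalize_payoff()], [decompose_payoff()].
#'
#' @inheritParams fit_growth_frequency
#' @return A `game_decomposition`.
#' @export
decomposition_from_assay <- function(data, weighted = FALSE) {
  decompose_payoff(normalize_payoff(payoff_from_fits(
    fit_growth_frequency(data, weighted = weighted))))
}

#' Import a payoff table with per-row diagnostics
#'
#' Reads a delimited table (columns `label`, `condition`, `a`, `b`, `c`,
#' `d`; or a JSON array of records with the same keys), validates every
#' row, and reports per-row diagnostics instead of silently dropping
#' malformed records.
#'
#' @param path Path to a CSV (or `.json`) payoff table.
#' @return A data frame with the input columns plus `row`, `normalizable`,
#'   `decomposable` and `diagnostic`; valid rows can be passed on to
#'   [decompose_table()].
#' @export
import_payoff_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c("label", "condition", "a", "b", "c", "d")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("payoff table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$row <- seq_len(nrow(raw))
  raw$normalizable <- FALSE
  raw$decomposable <- FALSE
  raw$diagnostic <- ""
  for (i in seq_len(nrow(raw))) {
    e <- suppressWarnings(as.numeric(raw[i, c("a", "b", "c", "d")]))
    if (any(!is.finite(e))) {
      raw$diagnostic[i] <- sprintf("row %d: non-numeric or missing entry", i)
      next
    }
    if (e[1] <= 0) {
      raw$diagnostic[i] <- sprintf(
        "row %d: a = %g is not positive; cannot normalize", i, e[1])
      next
    }
    raw$normalizable[i] <- TRUE
    dec <- tryCatch(
      decompose_payoff(normalize_payoff(payoff_matrix(e[1], e[2], e[3], e[4]))),
      error = function(err) err)
    if (inherits(dec, "error")) {
      raw$diagnostic[i] <- sprintf("row %d: %s", i, conditionMessage(dec))
    } else {
      raw$decomposable[i] <- TRUE
      if (isTRUE(attr(dec, "boundary"))) {
        raw$diagnostic[i] <- sprintf(
          "row %d: b = 0 convention (alpha_wm = -1)", i)
      }
    }
  }
  raw
}
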