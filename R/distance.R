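distance_regimes <- c("maintenance", "masking", "mirroring")

#' Signed residual of a regime surface constraint
#'
#' Residual of the constraint defining the maintenance, masking or
#' mirroring surface at a point `(s_m, alpha_mw, alpha_wm)` with the
#' mutation rate frozen. With the first-order surfaces (the default):
#'
#' * maintenance: `alpha_wm - mu * alpha_mw / (s_m (1 + s_m))`;
#' * masking: `alpha_wm - alpha_mw - 2 s_m` (exact and `mu`-free);
#' * mirroring: `alpha_mw + 2 s_m - mu (alpha_wm (1 - s_m) - 2 s_m) / s_m`.
#'
#' With `method = "exact"` the residual is the defect of the implicit
#' condition: selection at the target reference mode minus the target.
#' Mimicry is excluded (its target selection coefficient is arbitrary).
#'
#' @param regime `"maintenance"`, `"masking"` or `"mirroring"`.
#' @param point Numeric vector `c(s_m, alpha_mw, alpha_wm)` (names
#'   optional, this order).
#' @param mu Mutation rate frozen during the distance analysis.
#' @param method `"first_order"` (default, the printed surfaces) or
#'   `"exact"`.
#' @return The signed residual (0 on the surface).
#' @export
surface_residual <- function(regime, point, mu = 1e-3,
                             method = c("first_order", "exact")) {
  regime <- match.arg(regime, distance_regimes)
  method <- match.arg(method)
  point <- as_ssm_point(point)
  s <- point[[1]]
  amw <- point[[2]]
  awm <- point[[3]]
  if (regime != "masking" && s == 0) {
    stop("the ", regime, " surface is singular at s_m = 0", call. = FALSE)
  }
  if (method == "first_order") {
    switch(regime,
      maintenance = awm - mu * amw / (s * (1 + s)),
      masking = awm - amw - 2 * s,
      mirroring = amw + 2 * s - mu * (awm * (1 - s) - 2 * s) / s)
  } else {
    target <- switch(regime, maintenance = s, masking = 0, mirroring = -s)
    x_star <- mode_no_interaction(target, mu)
    (s + amw - (awm + amw) * x_star) / (1 + awm * x_star) - target
  }
}

as_ssm_point <- function(point) {
  if (inherits(point, "game_decomposition")) {
    return(c(s_m = point$s_m, alpha_mw = point$alpha_mw,
             alpha_wm = point$alpha_wm))
  }
  point <- unlist(point)
  if (!is.null(names(point)) &&
      all(c("s_m", "alpha_mw", "alpha_wm") %in% names(point))) {
    point <- point[c("s_m", "alpha_mw", "alpha_wm")]
  }
  stopifnot(length(point) == 3, all(is.finite(point)))
  stats::setNames(as.numeric(point), c("s_m", "alpha_mw", "alpha_wm"))
}

# At fixed s_m every regime surface is a straight line in the
# (alpha_mw, alpha_wm) plane: constrained = m(s) * free + b(s). The free
# coordinate is alpha_mw for maintenance/masking (constrained alpha_wm)
# and alpha_wm for mirroring (constrained alpha_mw).
surface_line <- function(regime, s, mu, method) {
  if (method == "first_order") {
    switch(regime,
      maintenance = c(m = mu / (s * (1 + s)), b = 0),
      masking = c(m = 1, b = 2 * s),
      mirroring = c(m = mu * (1 - s) / s, b = -2 * s - 2 * mu))
  } else {
    # exact condition: sigma at the target reference mode equals the target;
    # linear in both coefficients, rearranged for the constrained one
    target <- switch(regime, maintenance = s, masking = 0, mirroring = -s)
    xs <- mode_no_interaction(target, mu)
    if (regime == "mirroring") {
      # alpha_mw (1 - xs) = -2 s + alpha_wm xs (1 - s)
      c(m = xs * (1 - s) / (1 - xs), b = -2 * s / (1 - xs))
    } else {
      # alpha_wm xs (1 + target) = (s - target) + alpha_mw (1 - xs)
      c(m = (1 - xs) / (xs * (1 + target)),
        b = (s - target) / (xs * (1 + target)))
    }
  }
}

# point on the surface implied by the two free coordinates (s, free)
surface_point <- function(regime, free, mu, method) {
  s <- free[1]
  ln <- surface_line(regime, s, mu, method)
  if (any(!is.finite(ln))) {
    return(c(s_m = s, alpha_mw = NA_real_, alpha_wm = NA_real_))
  }
  con <- ln[["m"]] * free[2] + ln[["b"]]
  if (regime == "mirroring") {
    c(s_m = s, alpha_mw = con, alpha_wm = free[2])
  } else {
    c(s_m = s, alpha_mw = free[2], alpha_wm = con)
  }
}

#' Perpendicular distance from a point to a regime surface
#'
#' Minimizes the unitless Euclidean distance in `(s_m, alpha_mw,
#' alpha_wm)` space between a measured point and the chosen regime
#' surface, with the mutation rate frozen (default 0.001). The surface is
#' parameterized by its two free coordinates (the constrained coordinate
#' is eliminated through the surface formula) and the squared distance is
#' minimized by multi-start local optimization: at fixed `s_m` the
#' surface is a straight line in the interaction-coefficient plane, so a
#' dense closed-form profile of the distance over `s_m` (with a
#' log-spaced refinement near the singular sheet at `s_m = 0`) supplies
#' the candidate starts, each polished by a quasi-Newton local
#' optimization of the full two-parameter objective. The best converged
#' result is returned; if no start converges a diagnostic failure result
#' is returned, never a silent zero.
#'
#' @param regime `"maintenance"`, `"masking"` or `"mirroring"`.
#' @param point `c(s_m, alpha_mw, alpha_wm)` or a `game_decomposition`.
#' @param mu Frozen mutation rate.
#' @param method Surface family: `"first_order"` (default) or `"exact"`.
#' @param n_starts Number of profile candidates polished by the local
#'   optimizer.
#' @return An object of class `manifold_distance`: list with `regime`,
#'   `d_min`, `projected_point`, `residual` (surface constraint defect at
#'   the projection), `converged`, `n_starts`.
#' @examples
#' project_to_surface("masking", c(0.1, 0.3, 0.6))$d_min # |0.1|/sqrt(6)
#' @export
project_to_surface <- function(regime, point, mu = 1e-3,
                               method = c("first_order", "exact"),
                               n_starts = 16L) {
  regime <- match.arg(regime, distance_regimes)
  method <- match.arg(method)
  point <- as_ssm_point(point)
  objective <- function(free) {
    sp <- surface_point(regime, free, mu, method)
    if (any(!is.finite(sp))) return(1e10)
    sum((sp - point)^2)
  }
  # coordinates of the measured point in (free, constrained) order
  p_free <- if (regime == "mirroring") point[[3]] else point[[2]]
  p_con <- if (regime == "mirroring") point[[2]] else point[[3]]
  # profile of the squared distance over s: at fixed s the surface is the
  # line constrained = m f + b, whose nearest point to (p_free, p_con) is
  # closed form, so the profile is cheap to scan densely (including a
  # log-spaced refinement near the s -> 0 singular sheet of the
  # maintenance and mirroring surfaces)
  profile_free <- function(s) {
    ln <- surface_line(regime, s, mu, method)
    (p_free + ln[["m"]] * (p_con - ln[["b"]])) / (1 + ln[["m"]]^2)
  }
  profile_d2 <- function(s) {
    ln <- surface_line(regime, s, mu, method)
    if (any(!is.finite(ln))) return(Inf)
    (s - point[[1]])^2 +
      (ln[["m"]] * p_free + ln[["b"]] - p_con)^2 / (1 + ln[["m"]]^2)
  }
  s_grid <- sort(c(seq(-1.5, 1.5, length.out = 2001),
                   10^seq(-8, 0.17, length.out = 200),
                   -10^seq(-8, 0.17, length.out = 200)))
  if (regime != "masking") s_grid <- s_grid[s_grid != 0]
  prof <- vapply(s_grid, profile_d2, numeric(1))
  ord <- order(prof)
  n_cand <- min(max(4L, n_starts), length(ord))
  s_cand <- s_grid[ord[seq_len(n_cand)]]
  # the fixed-s line interpolates the point where the residual
  # m(s) p_free + b(s) - p_con crosses zero; those dips in the profile can
  # be much narrower than the grid spacing (the line slope varies as
  # mu / s^2 near the singular sheet), so locate them by a sign-change
  # scan and add the roots as candidates
  h_res <- function(s) {
    ln <- surface_line(regime, s, mu, method)
    ln[["m"]] * p_free + ln[["b"]] - p_con
  }
  hv <- vapply(s_grid, function(s) {
    r <- h_res(s)
    if (is.finite(r)) r else NA_real_
  }, numeric(1))
  flips <- which(!is.na(hv[-1]) & !is.na(hv[-length(hv)]) &
                   hv[-1] * hv[-length(hv)] < 0)
  if (regime != "masking") {
    flips <- flips[s_grid[flips] * s_grid[flips + 1] > 0] # not across s = 0
  }
  for (i in utils::head(flips, 8L)) {
    root <- tryCatch(
      stats::uniroot(h_res, c(s_grid[i], s_grid[i + 1]), tol = 1e-14)$root,
      error = function(e) NULL)
    if (!is.null(root)) s_cand <- c(s_cand, root)
  }
  # 1-D refinement of each candidate between its neighbouring grid points
  s_cand <- unique(vapply(s_cand, function(s0) {
    j <- findInterval(s0, s_grid)
    lo <- s_grid[max(j - 1L, 1L)]
    hi <- s_grid[min(j + 2L, length(s_grid))]
    if (regime != "masking" && lo * hi <= 0) return(s0)
    tryCatch(stats::optimize(profile_d2, c(lo, hi), tol = 1e-12)$minimum,
             error = function(e) s0)
  }, numeric(1)))
  # multi-start local polish in the (s, free) parameterization from the
  # refined candidates plus the point's own free coordinates
  starts <- rbind(
    t(vapply(s_cand, function(s) c(s, profile_free(s)), numeric(2))),
    matrix(c(point[[1]], p_free), nrow = 1)
  )
  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    st <- starts[i, ]
    if (regime != "masking" && st[1] == 0) st[1] <- 1e-7
    res <- tryCatch(
      stats::optim(st, objective, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 1000)),
      error = function(e) NULL)
    if (is.null(res)) {
      res <- tryCatch(
        stats::optim(st, objective, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 4000)),
        error = function(e) NULL)
    }
    if (is.null(res)) next
    converged <- res$convergence == 0 && is.finite(res$value) &&
      res$value < 1e9
    if (converged) any_converged <- TRUE
    if (converged && (is.null(best) || res$value < best$value)) best <- res
  }
  if (!any_converged || is.null(best)) {
    out <- list(regime = regime, d_min = NA_real_,
                projected_point = rep(NA_real_, 3),
                residual = NA_real_, converged = FALSE,
                n_starts = nrow(starts))
    class(out) <- "manifold_distance"
    return(out)
  }
  proj <- surface_point(regime, best$par, mu, method)
  out <- list(
    regime = regime,
    d_min = sqrt(best$value),
    projected_point = proj,
    residual = surface_residual(regime, proj, mu, method),
    converged = TRUE,
    n_starts = nrow(starts)
  )
  class(out) <- "manifold_distance"
  out
}

#' @export
print.manifold_distance <- function(x, ...) {
  cat(sprintf("Distance to the %s surface: d_min = %s\n", x$regime,
              if (is.na(x$d_min)) "NOT CONVERGED" else signif(x$d_min, 6)))
  if (x$converged) {
    cat(sprintf("  projection: s_m = %.5f, alpha_mw = %.5f, alpha_wm = %.5f\n",
                x$projected_point[1], x$projected_point[2],
                x$projected_point[3]))
  }
  invisible(x)
}

#' Rank experiments by distance to the regime surfaces
#'
#' Computes, for every decomposed experimental record, the perpendicular
#' distance to each of the maintenance, masking and mirroring surfaces,
#' and flags per regime the closest experiment. Records with `s_m = 0`
#' are excluded from the maintenance and mirroring columns (those
#' surfaces are singular there) with a diagnostic.
#'
#' @param records A data frame with columns `label` (or `experiment`),
#'   `s_m`, `alpha_mw`, `alpha_wm`.
#' @param regimes Surfaces to use.
#' @param mu Frozen mutation rate.
#' @param method Surface family, as in [project_to_surface()].
#' @return A data frame with one row per record x regime: `label`,
#'   `regime`, `d_min`, projected coordinates, `converged`, `closest`
#'   (flag), `diagnostic`.
#' @export
rank_experiments <- function(records, regimes = distance_regimes,
                             mu = 1e-3,
                             method = c("first_order", "exact")) {
  method <- match.arg(method)
  if (!"label" %in% names(records) && "experiment" %in% names(records)) {
    records$label <- records$experiment
  }
  needed <- c("label", "s_m", "alpha_mw", "alpha_wm")
  stopifnot(all(needed %in% names(records)))
  rows <- list()
  for (i in seq_len(nrow(records))) {
    pt <- c(records$s_m[i], records$alpha_mw[i], records$alpha_wm[i])
    for (rg in regimes) {
      if (rg != "masking" && pt[1] == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          label = records$label[i], regime = rg, d_min = NA_real_,
          proj_s_m = NA_real_, proj_alpha_mw = NA_real_,
          proj_alpha_wm = NA_real_, converged = FALSE,
          diagnostic = "s_m = 0: surface singular, record excluded",
          stringsAsFactors = FALSE)
        next
      }
      pr <- project_to_surface(rg, pt, mu = mu, method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        label = records$label[i], regime = rg, d_min = pr$d_min,
        proj_s_m = pr$projected_point[1],
        proj_alpha_mw = pr$projected_point[2],
        proj_alpha_wm = pr$projected_point[3],
        converged = pr$converged, diagnostic = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$closest <- FALSE
  for (rg in unique(out$regime)) {
    idx <- which(out$regime == rg & is.finite(out$d_min))
    if (length(idx) > 0) {
      out$closest[idx[which.min(out$d_min[idx])]] <- TRUE
    }
  }
  out
}
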