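#' Construct a 2x2 growth payoff matrix
#'
#' Builds the payoff matrix of a symmetric two-type game between a wild-type
#' and a mutant population. Entry `a` is the payoff (per-generation growth)
#' of wild-type against wild-type, `b` of wild-type against mutant, `c` of
#' mutant against wild-type and `d` of mutant against mutant.
#'
#' @param a,b,c,d Numeric scalars, the four payoff entries. All must be
#'   finite. Payoffs are per-generation growth rates, so they are expected
#'   to be non-negative; `a > 0` is required before [normalize_payoff()] can
#'   rescale the wild-type reference growth to 1.
#' @return An object of class `payoff_matrix`: a 2x2 numeric matrix with
#'   rows `wild-type`, `mutant` and columns `vs wild-type`, `vs mutant`.
#' @seealso [normalize_payoff()], [decompose_payoff()], [game_coordinates()]
#' @examples
#' payoff_matrix(1, 1.2, 1.4, 1.1)
#' @export
payoff_matrix <- function(a, b, c, d) {
  entries <- c(a = a, b = b, c = c, d = d)
  if (!is.numeric(entries) || length(entries) != 4L) {
    stop("payoff entries a, b, c, d must be numeric scalars", call. = FALSE)
  }
  if (any(!is.finite(entries))) {
    bad <- names(entries)[!is.finite(entries)]
    stop("payoff entries must be finite; offending entry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  P <- matrix(as.numeric(entries), nrow = 2, byrow = TRUE,
              dimnames = list(c("wild-type", "mutant"),
                              c("vs wild-type", "vs mutant")))
  class(P) <- c("payoff_matrix", "matrix")
  P
}

#' Coerce a 2x2 matrix to a payoff matrix
#'
#' @param x A 2x2 numeric matrix laid out as `[[a, b], [c, d]]`.
#' @return A `payoff_matrix`.
#' @export
as_payoff_matrix <- function(x) {
  if (inherits(x, "payoff_matrix")) return(x)
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) {
    stop("a payoff matrix must be 2x2", call. = FALSE)
  }
  payoff_matrix(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
}

payoff_entries <- function(P) {
  P <- as_payoff_matrix(P)
  c(a = P[1, 1], b = P[1, 2], c = P[2, 1], d = P[2, 2])
}

#' @export
print.payoff_matrix <- function(x, digits = 6, ...) {
  cat("Growth payoff matrix (rows: focal type, columns: opponent type)\n")
  y <- x
  class(y) <- "matrix"
  print(round(y, digits))
  invisible(x)
}

#' Normalize a payoff matrix to wild-type reference growth 1
#'
#' Divides every payoff entry by `a`, the wild-type-versus-wild-type growth
#' rate, so that the returned matrix has `a = 1`. Division (rather than
#' subtraction) preserves fitness ratios, which is what the frequency-
#' dependent selection coefficient depends on.
#'
#' @param P A `payoff_matrix` (or coercible 2x2 matrix).
#' @return A normalized `payoff_matrix` with unit wild-type reference growth.
#' @examples
#' normalize_payoff(payoff_matrix(2, 2.4, 2.8, 2.2))
#' @export
normalize_payoff <- function(P) {
  e <- payoff_entries(P)
  if (e[["a"]] <= 0) {
    stop("cannot normalize: entry a (wild-type vs wild-type payoff) is ",
         e[["a"]], " but must be > 0", call. = FALSE)
  }
  payoff_matrix(1, e[["b"]] / e[["a"]], e[["c"]] / e[["a"]],
                e[["d"]] / e[["a"]])
}

is_normalized <- function(P, tol = 0) {
  abs(payoff_entries(P)[["a"]] - 1) <= tol
}

#' Construct a decomposed game
#'
#' A `game_decomposition` holds the cell-intrinsic mutant selection
#' coefficient `s_m` and the two ecological interaction coefficients:
#' `alpha_wm`, the effect of the mutant on the wild-type's growth, and
#' `alpha_mw`, the effect of the wild-type on the mutant's growth. The
#' wild-type reference growth `g_w` is fixed at 1, so the corresponding
#' normalized payoff matrix is
#' `[[1, 1 + alpha_wm], [1 + s_m + alpha_mw, 1 + s_m]]`.
#'
#' Positivity of all payoff entries is required so that fitnesses remain
#' positive for every mutant fraction: `1 + s_m > 0` and
#' `1 + s_m + alpha_mw > 0` strictly, and `alpha_wm >= -1`. The boundary
#' `alpha_wm = -1` (payoff entry `b = 0`) is admitted because some published
#' payoff estimation conventions set `b` to zero; such decompositions carry
#' a `"boundary"` attribute since the wild-type fitness vanishes at `x = 1`.
#'
#' @param s_m Intrinsic mutant selection coefficient (dimensionless).
#' @param alpha_wm Interaction effect of the mutant on the wild-type.
#' @param alpha_mw Interaction effect of the wild-type on the mutant.
#' @return An object of class `game_decomposition`.
#' @seealso [decompose_payoff()], [compose_payoff()]
#' @examples
#' game_decomposition(s_m = 0.1, alpha_wm = 0.2, alpha_mw = 0.3)
#' @export
game_decomposition <- function(s_m, alpha_wm, alpha_mw) {
  vals <- c(s_m = s_m, alpha_wm = alpha_wm, alpha_mw = alpha_mw)
  if (any(!is.finite(vals))) {
    stop("decomposition coefficients must be finite", call. = FALSE)
  }
  if (1 + s_m <= 0) {
    stop("invalid decomposition: 1 + s_m must be > 0 (payoff entry d = ",
         1 + s_m, ")", call. = FALSE)
  }
  if (1 + s_m + alpha_mw <= 0) {
    stop("invalid decomposition: 1 + s_m + alpha_mw must be > 0 ",
         "(payoff entry c = ", 1 + s_m + alpha_mw, ")", call. = FALSE)
  }
  if (alpha_wm < -1) {
    stop("invalid decomposition: alpha_wm must be >= -1 ",
         "(payoff entry b = ", 1 + alpha_wm, " would be negative)",
         call. = FALSE)
  }
  dec <- structure(
    list(s_m = as.numeric(s_m), alpha_wm = as.numeric(alpha_wm),
         alpha_mw = as.numeric(alpha_mw), g_w = 1),
    class = "game_decomposition"
  )
  attr(dec, "boundary") <- (alpha_wm == -1)
  dec
}

#' @export
print.game_decomposition <- function(x, digits = 6, ...) {
  cat("Decomposed two-type game (wild-type reference growth g_w = 1)\n")
  cat(sprintf("  s_m      = %.*g  (intrinsic mutant selection)\n",
              digits, x$s_m))
  cat(sprintf("  alpha_wm = %.*g  (effect of mutant on wild-type)\n",
              digits, x$alpha_wm))
  cat(sprintf("  alpha_mw = %.*g  (effect of wild-type on mutant)\n",
              digits, x$alpha_mw))
  if (isTRUE(attr(x, "boundary"))) {
    cat("  note: alpha_wm = -1 boundary (payoff entry b = 0)\n")
  }
  invisible(x)
}

#' Decompose a normalized payoff matrix
#'
#' Separates a normalized payoff matrix into its cell-intrinsic and
#' ecological parts. Requiring each row of the payoff matrix to be constant
#' in the no-interaction limit forces the additive form
#' `a = 1`, `b = 1 + alpha_wm`, `c = 1 + s_m + alpha_mw`, `d = 1 + s_m`,
#' so `s_m = d - 1`, `alpha_wm = b - 1` and `alpha_mw = c - d`.
#'
#' @param P A normalized `payoff_matrix` (entry `a` equal to 1; use
#'   [normalize_payoff()] first otherwise).
#' @return A `game_decomposition`.
#' @examples
#' decompose_payoff(payoff_matrix(1, 1.2, 1.4, 1.1))
#' @export
decompose_payoff <- function(P) {
  e <- payoff_entries(P)
  if (!is_normalized(P)) {
    stop("payoff matrix is not normalized (a = ", e[["a"]],
         "); call normalize_payoff() first", call. = FALSE)
  }
  game_decomposition(s_m = e[["d"]] - 1,
                     alpha_wm = e[["b"]] - 1,
                     alpha_mw = e[["c"]] - e[["d"]])
}

#' Compose the payoff matrix of a decomposed game
#'
#' Inverse of [decompose_payoff()]: rebuilds the normalized payoff matrix
#' `[[1, 1 + alpha_wm], [1 + s_m + alpha_mw, 1 + s_m]]`. The round trip
#' `decompose_payoff(compose_payoff(dec))` is exact.
#'
#' @param dec A `game_decomposition`.
#' @return A normalized `payoff_matrix`.
#' @export
compose_payoff <- function(dec) {
  stopifnot(inherits(dec, "game_decomposition"))
  payoff_matrix(1, 1 + dec$alpha_wm,
                1 + dec$s_m + dec$alpha_mw, 1 + dec$s_m)
}

as_game_decomposition <- function(x) {
  if (inherits(x, "game_decomposition")) return(x)
  if (inherits(x, "payoff_matrix")) return(decompose_payoff(x))
  if (is.numeric(x) && !is.null(names(x)) &&
      all(c("s_m", "alpha_wm", "alpha_mw") %in% names(x))) {
    return(game_decomposition(x[["s_m"]], x[["alpha_wm"]], x[["alpha_mw"]]))
  }
  stop("cannot interpret input as a game decomposition", call. = FALSE)
}
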