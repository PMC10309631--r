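# Numeric phase-portrait exports: nullclines and direction-field grids.
# The tested artifact is the exported data, not any rendering of it.

#' Nullclines of the reduced system
#'
#' For each grid column `x_A` the nontrivial branch of each nullcline is
#' obtained by a bracketed root search in `x_B` on the nontrivial factor of
#' the corresponding field component (the trivial factors are the axes,
#' which are returned as labelled branches of their own). For superlinear
#' exponents the `dx_B/dt = 0` branch is a hyperbola-like curve that may
#' intersect a column zero or several times; all roots found by the
#' per-column sign scan are kept.
#'
#' @inheritParams rhs_reduced
#' @param resolution number of grid columns (>= 16).
#' @return A data frame with columns `branch` (`"dxA=0 (axis x_A=0)"`,
#'   `"dxA=0"`, `"dxB=0 (axis x_B=0)"`, `"dxB=0"`), `x_A`, `x_B`. Every
#'   nontrivial vertex satisfies `|field component| < 1e-10`.
#' @export
nullclines <- function(coeffs, a, resolution = 128) {
  stopifnot(resolution >= 16)
  xs <- seq(0, 1, length.out = resolution)
  a1 <- coeffs$a1; a2 <- coeffs$a2; a3 <- coeffs$a3; a4 <- coeffs$a4
  rows <- list(
    data.frame(branch = "dxA=0 (axis x_A=0)", x_A = 0, x_B = xs),
    data.frame(branch = "dxB=0 (axis x_B=0)", x_A = xs, x_B = 0))
  for (x_A in xs[xs > 0 & xs < 1]) {
    # nontrivial factor of dx_A/dt: a1 (1 - x_A - x_B) x_A^(a-1) - a2 x_B^a
    fA <- function(x_B) a1 * (1 - x_A - x_B) * x_A^(a - 1) - a2 * x_B^a
    # nontrivial factor of dx_B/dt: a3 (1 - x_A - x_B) x_B^(a-1) - a4 x_A^a
    fB <- function(x_B) a3 * (1 - x_A - x_B) * x_B^(a - 1) - a4 * x_A^a
    top <- 1 - x_A
    sub <- seq(0, top, length.out = 128)
    rA <- .scan_roots(fA, sub, vapply(sub, fA, 0), tol = 1e-14)
    if (length(rA)) {
      rows[[length(rows) + 1L]] <-
        data.frame(branch = "dxA=0", x_A = x_A, x_B = rA)
    }
    subB <- if (a < 1) sub[sub > 0] else sub
    rB <- .scan_roots(fB, subB, vapply(subB, fB, 0), tol = 1e-14)
    if (length(rB)) {
      rows[[length(rows) + 1L]] <-
        data.frame(branch = "dxB=0", x_A = x_A, x_B = rB)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direction-field grid over the simplex
#'
#' Samples the vector field on a barycentric lattice of the triangle
#' (which, unlike a clipped square grid, never evaluates the field outside
#' the domain - relevant for fractional exponents). Each sample stores the
#' unit direction, the field magnitude, the active regime, and a
#' stationarity flag for (near-)zero field points, which mark equilibrium
#' candidates.
#'
#' @param model either a `"reduced_coeffs"` object (smooth system; `a`
#'   required) or a [filippov_model()] (the regime at each grid point is
#'   chosen by the `x_B >= ET` rule).
#' @param a attractiveness exponent; ignored (taken from the model) for a
#'   Filippov model.
#' @param resolution lattice subdivisions per edge (>= 4).
#' @return A data frame with columns `x_A`, `x_B`, `u`, `v` (unit
#'   direction; zero for stationary points), `magnitude`, `regime`,
#'   `stationary`.
#' @export
vector_field_grid <- function(model, a = NULL, resolution = 16) {
  stopifnot(resolution >= 4)
  is_fil <- inherits(model, "filippov_model")
  if (is_fil) a <- model$a
  if (is.null(a)) stop("'a' is required for a plain coefficient set")
  ij <- expand.grid(i = 0:resolution, j = 0:resolution)
  ij <- ij[ij$i + ij$j <= resolution, ]
  x_A <- ij$i / resolution
  x_B <- ij$j / resolution
  if (is_fil) {
    regime <- ifelse(x_B >= model$ET, "free", "controlled")
    f <- matrix(NA_real_, nrow = length(x_A), ncol = 2)
    up <- regime == "free"
    f[up, ] <- .rhs_core(x_A[up], x_B[up], model$free, a)
    f[!up, ] <- .rhs_core(x_A[!up], x_B[!up], model$controlled, a)
  } else {
    regime <- "free"
    f <- .rhs_core(x_A, x_B, model, a)
  }
  mag <- sqrt(f[, 1]^2 + f[, 2]^2)
  stationary <- mag < 1e-14
  u <- ifelse(stationary, 0, f[, 1] / mag)
  v <- ifelse(stationary, 0, f[, 2] / mag)
  data.frame(x_A = x_A, x_B = x_B, u = u, v = v, magnitude = mag,
             regime = regime, stationary = stationary,
             stringsAsFactors = FALSE)
}
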