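# Equilibria of the planar system, their Jacobians, and trace-determinant
# stability classification.

#' Trivial (boundary) equilibria
#'
#' The three equilibria present for every positive coefficient set:
#' `E0 = (0, 0)` (everyone bilingual), `E1 = (0, 1)` (only language B),
#' `E2 = (1, 0)` (only language A).
#'
#' @return A 3 x 2 matrix with rownames `E0`, `E1`, `E2` and columns
#'   `x_A`, `x_B`.
#' @export
trivial_equilibria <- function() {
  matrix(c(0, 0,
           0, 1,
           1, 0),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("E0", "E1", "E2"), c("x_A", "x_B")))
}

#' Interior (coexistence-candidate) equilibrium
#'
#' Closed-form interior equilibrium of the planar system. Dividing the two
#' stationarity conditions yields the ratio identity
#' `(x_A*/x_B*)^(2a - 1) = a2 a3 / (a1 a4)`; writing
#' `rho = (a2 a3 / (a1 a4))^(1 / (2a - 1))` gives
#' `x_B* = 1 / (rho + 1 + (a2 / a1) rho^(1 - a))` and `x_A* = rho x_B*`.
#' For `a = 1` this reduces to the rational forms
#' `x_A* = a2 a3 / D`, `x_B* = a1 a4 / D` with `D = a1 a4 + a2 a3 + a2 a4`.
#'
#' For strictly positive coefficients the point always lies strictly inside
#' the simplex; this is asserted, not assumed.
#'
#' @inheritParams rhs_reduced
#' @param method `"auto"` (rational form at `a = 1`, ratio form otherwise),
#'   or force `"rational"` (`a = 1` only) / `"general"`. The two forms agree
#'   to machine precision at `a = 1`; both are kept so they can be checked
#'   against each other.
#' @return Named vector `c(x_A, x_B)`, strictly inside the simplex.
#' @export
interior_equilibrium <- function(coeffs, a,
                                 method = c("auto", "rational", "general")) {
  method <- match.arg(method)
  cf <- unlist(coeffs[c("a1", "a2", "a3", "a4")])
  if (any(cf <= 0)) {
    stop("interior equilibrium requires strictly positive coefficients")
  }
  if (abs(2 * a - 1) < 1e-12) {
    stop("unsupported exponent a = 1/2: the ratio exponent 2a - 1 vanishes")
  }
  if (a < 1) {
    warning("interior equilibrium evaluated with a < 1; theory assumes a >= 1",
            call. = FALSE)
  }
  use_rational <- switch(method,
                         auto = abs(a - 1) < 1e-15,
                         rational = TRUE,
                         general = FALSE)
  if (use_rational && abs(a - 1) > 1e-15) {
    stop("the rational closed form is only valid for a = 1")
  }
  if (use_rational) {
    D <- cf[1] * cf[4] + cf[2] * cf[3] + cf[2] * cf[4]
    pt <- c(x_A = unname(cf[2] * cf[3] / D), x_B = unname(cf[1] * cf[4] / D))
  } else {
    r <- (cf[2] * cf[3]) / (cf[1] * cf[4])
    rho <- r^(1 / (2 * a - 1))
    x_B <- 1 / (rho + 1 + (cf[2] / cf[1]) * rho^(1 - a))
    pt <- c(x_A = unname(rho * x_B), x_B = unname(x_B))
  }
  stopifnot(all(pt > 0), sum(pt) < 1)
  pt
}

#' Jacobian of the reduced system
#'
#' Analytic Jacobian of the planar field, valid on all of the simplex for
#' `a >= 1`. The boundary terms `x^(a - 1)` follow the one-sided limits
#' used throughout the stability analysis: `0^0 = 1` when `a = 1`, `0` when
#' `a > 1`; for `a < 1` the term diverges at the boundary and evaluation is
#' refused there.
#'
#' @inheritParams rhs_reduced
#' @return A 2 x 2 numeric matrix.
#' @export
jacobian_reduced <- function(coeffs, a, point) {
  x <- .clamp_coords(as.numeric(point)[1:2])
  if (x[1] + x[2] > 1 + 1e-9) stop("point lies outside the simplex")
  if (a < 1 && any(x == 0)) {
    stop("Jacobian diverges on the boundary for a < 1 (x^(a-1) unbounded)")
  }
  x_A <- x[1]; x_B <- x[2]
  a1 <- coeffs$a1; a2 <- coeffs$a2; a3 <- coeffs$a3; a4 <- coeffs$a4
  xA1 <- x_A^(a - 1); xB1 <- x_B^(a - 1)    # 0^0 = 1 covers the a = 1 case
  xAa <- x_A^a;       xBa <- x_B^a
  matrix(c(a1 * a * (1 - x_B) * xA1 - a1 * (a + 1) * xAa - a2 * xBa,
           -a1 * xAa - a2 * a * x_A * xB1,
           -a3 * xBa - a4 * a * x_B * xA1,
           a3 * a * (1 - x_A) * xB1 - a3 * (a + 1) * xBa - a4 * xAa),
         nrow = 2, byrow = TRUE)
}

#' Trace-determinant stability indicators
#'
#' For a planar Jacobian `J`, `p = -trace(J)` and `q = det(J)`. The sign
#' pattern of `(p, q)` classifies hyperbolic equilibria: `q < 0` saddle;
#' `q > 0` with `p > 0` stable (node when `p^2 >= 4q`, focus otherwise),
#' with `p < 0` unstable.
#'
#' @param J a 2 x 2 numeric matrix.
#' @return Named vector `c(p, q)`.
#' @export
pq_indicators <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == c(2, 2)))
  c(p = -(J[1, 1] + J[2, 2]),
    q = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
}

.classify_pq <- function(p, q, tol = 1e-12) {
  if (abs(p) <= tol && abs(q) <= tol) return("degenerate/non-hyperbolic")
  if (q < -tol) return("saddle (unstable)")
  if (q > tol) {
    if (p > tol) return(if (p^2 >= 4 * q) "stable node" else "stable focus")
    if (p < -tol) return(if (p^2 >= 4 * q) "unstable node" else "unstable focus")
    return("center (degenerate)")
  }
  "degenerate/non-hyperbolic"
}

# Numeric probe used when linearization is silent (p = q = 0, e.g. the
# all-bilingual corner for a > 1): integrate from 8 small perturbations and
# flag the point unstable if any trajectory leaves a 10*delta neighbourhood.
.perturbation_probe <- function(coeffs, a, point, delta = 1e-4, t_end = 1e6) {
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  for (th in theta) {
    p0 <- point + delta * c(cos(th), sin(th))
    if (p0[1] < 0 || p0[2] < 0 || sum(p0) > 1) next
    traj <- .integrate_core(coeffs, a, p0, 0, t_end, n_out = 64)
    dev <- sqrt((traj[, 2] - point[1])^2 + (traj[, 3] - point[2])^2)
    if (max(dev) > 10 * delta) return(TRUE)
  }
  FALSE
}

#' Classify an equilibrium of the reduced system
#'
#' Builds a full stability report at a stationary point: Jacobian, the
#' `(p, q)` indicators, eigenvalues, a classification label, and - when the
#' point is non-hyperbolic so that linearization says nothing - a numerical
#' perturbation probe that reports whether nearby trajectories escape.
#'
#' @inheritParams rhs_reduced
#' @param resid_tol largest acceptable field residual for `point` to count
#'   as an equilibrium.
#' @param probe run the perturbation probe on degenerate points?
#' @return An object of class `"equilibrium_report"`: list with `point`,
#'   `jacobian`, `p`, `q`, `eigenvalues`, `classification`,
#'   `numerically_unstable` (logical, `NA` unless the point is degenerate
#'   and the probe ran).
#' @export
classify_equilibrium <- function(coeffs, a, point, resid_tol = 1e-10,
                                 probe = TRUE) {
  point <- .clamp_coords(as.numeric(point)[1:2])
  res <- rhs_reduced(coeffs, a, point)
  if (max(abs(res)) > resid_tol) {
    stop("point is not an equilibrium: field residual ", format(max(abs(res))))
  }
  J <- jacobian_reduced(coeffs, a, point)
  pq <- pq_indicators(J)
  cls <- .classify_pq(pq[["p"]], pq[["q"]])
  num_unst <- NA
  if (probe && cls %in% c("degenerate/non-hyperbolic", "center (degenerate)")) {
    num_unst <- .perturbation_probe(coeffs, a, point)
  }
  structure(list(point = c(x_A = point[1], x_B = point[2]),
                 jacobian = J,
                 p = unname(pq["p"]), q = unname(pq["q"]),
                 eigenvalues = eigen(J, only.values = TRUE)$values,
                 classification = cls,
                 numerically_unstable = num_unst),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, digits = 4, ...) {
  cat(sprintf("Equilibrium (%s, %s): %s\n",
              format(round(x$point[1], digits)),
              format(round(x$point[2], digits)),
              x$classification))
  cat(sprintf("  p = %g, q = %g, eigenvalues = %s\n", x$p, x$q,
              paste(format(x$eigenvalues, digits = 4), collapse = ", ")))
  if (!is.na(x$numerically_unstable)) {
    cat("  perturbation probe:",
        if (x$numerically_unstable) "unstable" else "no escape detected", "\n")
  }
  invisible(x)
}

#' Check positive invariance of the simplex along its boundary
#'
#' Samples each edge of the triangle `Omega` and verifies that the field
#' never points outward: on `x_A = 0`, `dx_A/dt = 0` and `dx_B/dt >= 0`; on
#' `x_B = 0`, symmetrically; on the hypotenuse `x_A + x_B = 1`, the outward
#' flux `d(x_A + x_B)/dt` is nonpositive. Failures are reported, not
#' raised.
#'
#' @inheritParams rhs_reduced
#' @param n_samples number of sample points per edge (>= 2).
#' @return A data frame with one row per checked quantity: `edge`,
#'   `quantity`, `worst` (the extreme sampled value) and `pass`.
#' @export
boundary_inflow_check <- function(coeffs, a, n_samples = 101) {
  stopifnot(n_samples >= 2)
  s <- seq(0, 1, length.out = n_samples)
  tol <- 1e-12
  fA0 <- .rhs_core(rep(0, n_samples), s, coeffs, a)
  fB0 <- .rhs_core(s, rep(0, n_samples), coeffs, a)
  fH  <- .rhs_core(s, 1 - s, coeffs, a)
  out <- data.frame(
    edge = c("x_A=0", "x_A=0", "x_B=0", "x_B=0", "x_A+x_B=1"),
    quantity = c("max |dx_A/dt|", "min dx_B/dt",
                 "max |dx_B/dt|", "min dx_A/dt",
                 "max d(x_A+x_B)/dt"),
    worst = c(max(abs(fA0[, 1])), min(fA0[, 2]),
              max(abs(fB0[, 2])), min(fB0[, 1]),
              max(fH[, 1] + fH[, 2])),
    stringsAsFactors = FALSE)
  out$pass <- c(out$worst[1] <= tol, out$worst[2] >= -tol,
                out$worst[3] <= tol, out$worst[4] >= -tol,
                out$worst[5] <= tol)
  out
}
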