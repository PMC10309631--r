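# Parameterization, transfer rates, full vector field and its reduction to
# the four-coefficient planar system.

# Clamp coordinates marginally below zero (adaptive-stepper overshoot) and
# refuse anything genuinely negative. Powers then follow R's conventions,
# which match the model's: 0^p = 0 for p > 0.
.clamp_coords <- function(x, guard = 1e-12) {
  bad <- x < -guard
  if (any(bad)) {
    stop("coordinate ", format(min(x)), " is below -1e-12: outside the simplex",
         call. = FALSE)
  }
  pmax(x, 0)
}

#' Full parameterization of the bilingual competition model
#'
#' Bundles the demographic turnover rate `mu`, the attractiveness exponent
#' `a`, the statuses of the two languages and the four interaction values
#' that weight the flows between the monolingual pools and the bilingual
#' pool.
#'
#' @param mu turnover rate, strictly between 0 and 1. The bounds guarantee
#'   that all four reduced coefficients are positive.
#' @param a attractiveness exponent (> 0): a language's pull is proportional
#'   to its speaker proportion raised to `a`. `a = 1` is linear; empirical
#'   estimates across cultures cluster around 1.31. Values below 1 are
#'   permitted (sublinear attractiveness) but flagged with a warning, since
#'   the stability theory assumes `a >= 1`.
#' @param s_A,s_B status (socio-economic attractiveness weight) of language
#'   A and B; both must be positive. The statuses are *not* required to sum
#'   to one, but a warning is issued when they do not, since every worked
#'   scenario uses complementary values.
#' @param I_wA,I_wB interaction value for the bilingual-to-monolingual flow
#'   towards A resp. B (nonnegative).
#' @param I_Aw,I_Bw interaction value for the monolingual-to-bilingual flow
#'   out of A resp. B (nonnegative).
#'
#' @return An object of class `"model_params"`: a list with the eight
#'   parameters plus a logical `sublinear` flag (`a < 1`).
#' @seealso [reduced_coefficients()], [transfer_rates()], [rhs_full()]
#' @examples
#' p <- model_params(mu = 0.02, a = 1, s_A = 0.8, s_B = 0.2,
#'                   I_Aw = 0.03, I_Bw = 0.03)
#' reduced_coefficients(p)
#' @export
model_params <- function(mu, a, s_A, s_B,
                         I_wA = 1, I_wB = 1, I_Aw = 1, I_Bw = 1) {
  vals <- c(mu = mu, a = a, s_A = s_A, s_B = s_B,
            I_wA = I_wA, I_wB = I_wB, I_Aw = I_Aw, I_Bw = I_Bw)
  if (length(vals) != 8L || !is.numeric(vals) || any(!is.finite(vals))) {
    stop("all model parameters must be finite scalars")
  }
  if (mu <= 0 || mu >= 1) {
    stop("'mu' must lie strictly between 0 and 1")
  }
  if (a <= 0) stop("'a' must be positive")
  if (s_A <= 0 || s_B <= 0) stop("language statuses must be positive")
  if (any(c(I_wA, I_wB, I_Aw, I_Bw) < 0)) {
    stop("interaction values must be nonnegative")
  }
  sublinear <- a < 1
  if (sublinear) {
    warning("a < 1 (sublinear attractiveness): the stability analysis assumes a >= 1",
            call. = FALSE)
  }
  if (abs(s_A + s_B - 1) > 1e-9) {
    warning("s_A + s_B differs from 1 by ", format(s_A + s_B - 1),
            "; statuses are usually complementary", call. = FALSE)
  }
  structure(list(mu = mu, a = a, s_A = s_A, s_B = s_B,
                 I_wA = I_wA, I_wB = I_wB, I_Aw = I_Aw, I_Bw = I_Bw,
                 sublinear = sublinear),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bilingual competition model parameters\n")
  cat(sprintf("  mu = %g, a = %g%s\n", x$mu, x$a,
              if (x$sublinear) " (sublinear, flagged)" else ""))
  cat(sprintf("  status:      s_A = %g, s_B = %g\n", x$s_A, x$s_B))
  cat(sprintf("  interaction: I_wA = %g, I_wB = %g, I_Aw = %g, I_Bw = %g\n",
              x$I_wA, x$I_wB, x$I_Aw, x$I_Bw))
  invisible(x)
}

#' A point on the population simplex
#'
#' Validates (and optionally renormalizes) a triple of population
#' proportions `(x_A, x_B, w)`. The bilingual share `w` is stored
#' redundantly and checked against `1 - x_A - x_B` rather than integrated
#' independently, since it carries no dynamics of its own.
#'
#' @param x_A,x_B monolingual proportions (>= 0, up to a 1e-12 clamping
#'   guard for integrator overshoot).
#' @param w bilingual proportion; defaults to `1 - x_A - x_B`.
#' @param normalize if `TRUE`, a triple whose sum differs from 1 by more
#'   than `1e-9` is rescaled to sum exactly 1 (with a warning) instead of
#'   raising an error.
#' @return A named numeric vector `c(x_A, x_B, w)` of class
#'   `"population_state"`.
#' @export
population_state <- function(x_A, x_B, w = NULL, normalize = FALSE) {
  if (is.null(w)) w <- 1 - x_A - x_B
  v <- .clamp_coords(c(x_A = x_A, x_B = x_B, w = w))
  s <- sum(v)
  if (abs(s - 1) > 1e-9) {
    if (!normalize) {
      stop("proportions sum to ", format(s), ", not 1 (within 1e-9)")
    }
    warning("proportions sum to ", format(s), "; renormalizing to 1",
            call. = FALSE)
    v <- v / s
  }
  structure(v, class = "population_state")
}

# Coerce numeric input (length 2 or 3, population_state, ...) to a
# normalized c(x_A, x_B, w) vector.
.as_state <- function(x0, normalize = TRUE) {
  if (inherits(x0, "population_state")) return(unclass(x0))
  x0 <- as.numeric(x0)
  if (length(x0) == 2L) x0 <- c(x0, 1 - sum(x0))
  if (length(x0) != 3L) stop("a population state needs 2 or 3 coordinates")
  unclass(population_state(x0[1], x0[2], x0[3], normalize = normalize))
}

#' Reduced coefficients of the planar system
#'
#' Collapses the eight model parameters into the four positive coefficients
#' of the planar system: `a1 = mu * I_wA * s_A` (bilingual -> A inflow),
#' `a2 = (1 - mu) * I_Aw * s_B` (A -> bilingual outflow),
#' `a3 = mu * I_wB * s_B`, `a4 = (1 - mu) * I_Bw * s_A`. Positivity of all
#' four is exactly the condition `0 < mu < 1` with positive statuses and
#' interaction values.
#'
#' @param params a [model_params()] object.
#' @return A `"reduced_coeffs"` object (list with `a1..a4`).
#' @export
reduced_coefficients <- function(params) {
  if (!inherits(params, "model_params")) {
    stop("'params' must be a model_params object")
  }
  coeff_set(a1 = params$mu * params$I_wA * params$s_A,
            a2 = (1 - params$mu) * params$I_Aw * params$s_B,
            a3 = params$mu * params$I_wB * params$s_B,
            a4 = (1 - params$mu) * params$I_Bw * params$s_A)
}

#' Construct a reduced coefficient set directly
#'
#' For analyses that start from the planar system itself (for instance the
#' hyperbolic-nullcline illustration with `a1 = 10`, `a2 = a3 = a4 = 1`)
#' the four coefficients can be supplied without going through a full
#' parameterization.
#'
#' @param a1,a2,a3,a4 positive reals (per unit model time).
#' @return A `"reduced_coeffs"` object.
#' @export
coeff_set <- function(a1, a2, a3, a4) {
  v <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  if (any(!is.finite(v))) stop("coefficients must be finite")
  if (any(v < 0)) stop("reduced coefficients must be positive")
  if (any(v == 0)) {
    warning("zero reduced coefficient: the system is degenerate", call. = FALSE)
  }
  structure(as.list(v), class = "reduced_coeffs")
}

#' @export
print.reduced_coeffs <- function(x, ...) {
  cat(sprintf("Reduced coefficients: a1 = %g, a2 = %g, a3 = %g, a4 = %g\n",
              x$a1, x$a2, x$a3, x$a4))
  invisible(x)
}

#' Transfer rates between the bilingual and monolingual pools
#'
#' Evaluates the four per-capita transfer rates at a population state:
#' `P_wA = I_wA * s_A * x_A^a` and `P_wB = I_wB * s_B * x_B^a` (bilinguals
#' adopting a single language, pulled by that language's status and speaker
#' share) and `P_Aw = I_Aw * s_B * x_B^a`, `P_Bw = I_Bw * s_A * x_A^a`
#' (monolinguals becoming bilingual, pulled by the *other* language). A
#' language with no speakers exerts no attraction: `0^a = 0` for `a > 0`.
#'
#' @param params a [model_params()] object.
#' @param state a simplex point (see [population_state()]).
#' @return Named vector `c(P_wA, P_Aw, P_wB, P_Bw)`, all nonnegative.
#' @export
transfer_rates <- function(params, state) {
  st <- .as_state(state, normalize = FALSE)
  x_A <- unname(st[1]); x_B <- unname(st[2]); a <- params$a
  c(P_wA = params$I_wA * params$s_A * x_A^a,
    P_Aw = params$I_Aw * params$s_B * x_B^a,
    P_wB = params$I_wB * params$s_B * x_B^a,
    P_Bw = params$I_Bw * params$s_A * x_A^a)
}

#' Full vector field of the bilingual competition model
#'
#' Time derivatives of the monolingual proportions under the full
#' parameterization:
#' `dx_A/dt = mu * w * I_wA * s_A * x_A^a - (1 - mu) * x_A * I_Aw * s_B * x_B^a`
#' and symmetrically for `x_B`. The bilingual share obeys
#' `dw/dt = -(dx_A/dt + dx_B/dt)` and is not integrated separately. The
#' result is algebraically identical to [rhs_reduced()] applied to
#' [reduced_coefficients()].
#'
#' @inheritParams transfer_rates
#' @return Named vector `c(dx_A, dx_B)`.
#' @export
rhs_full <- function(params, state) {
  st <- .as_state(state, normalize = FALSE)
  P <- transfer_rates(params, st)
  mu <- params$mu; w <- unname(st[3])
  c(dx_A = mu * w * P[["P_wA"]] - (1 - mu) * unname(st[1]) * P[["P_Aw"]],
    dx_B = mu * w * P[["P_wB"]] - (1 - mu) * unname(st[2]) * P[["P_Bw"]])
}

# Scalar/vectorized core of the planar field; no domain checking so the
# integrators can call it cheaply.
.rhs_core <- function(x_A, x_B, cf, a) {
  w <- 1 - x_A - x_B
  cbind(dx_A = cf$a1 * w * x_A^a - cf$a2 * x_A * x_B^a,
        dx_B = cf$a3 * w * x_B^a - cf$a4 * x_B * x_A^a)
}

#' Planar vector field of the reduced system
#'
#' Evaluates `dx_A/dt = a1 (1 - x_A - x_B) x_A^a - a2 x_A x_B^a` and
#' `dx_B/dt = a3 (1 - x_A - x_B) x_B^a - a4 x_B x_A^a` at a point of the
#' triangle `Omega`. Coordinates within `1e-12` below zero are clamped to
#' zero; anything further outside `Omega` raises an error.
#'
#' @param coeffs a `"reduced_coeffs"` object.
#' @param a attractiveness exponent (> 0).
#' @param point numeric `c(x_A, x_B)`.
#' @return Named vector `c(dx_A, dx_B)`.
#' @export
rhs_reduced <- function(coeffs, a, point) {
  x <- .clamp_coords(as.numeric(point)[1:2])
  if (x[1] + x[2] > 1 + 1e-9) {
    stop("point (", x[1], ", ", x[2], ") lies outside the simplex")
  }
  drop(.rhs_core(x[1], x[2], coeffs, a))
}
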