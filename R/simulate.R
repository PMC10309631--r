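# Forward integration of the smooth planar system and convergence
# detection.

# Raw deSolve wrapper. Returns the output matrix (t, x_A, x_B);
# coordinates are clamped to >= 0 inside the call so that fractional
# exponents never see the integrator's tiny overshoots. Plain runs use
# vode (lsoda's stiffness switching can fail with a spurious interpolation
# error once a coordinate has decayed to underflow); event-detected runs
# need lsodar, the only root-finding stepper.
.integrate_core <- function(coeffs, a, y0, t0, t1, n_out = 500,
                            rtol = 1e-9, atol = 1e-12, rootfun = NULL) {
  func <- function(t, y, parms) {
    y <- pmax(y, 0)
    w <- max(1 - y[1] - y[2], 0)
    list(c(coeffs$a1 * w * y[1]^a - coeffs$a2 * y[1] * y[2]^a,
           coeffs$a3 * w * y[2]^a - coeffs$a4 * y[2] * y[1]^a))
  }
  times <- seq(t0, t1, length.out = max(2L, n_out))
  y0 <- setNames(as.numeric(y0[1:2]), c("x_A", "x_B"))
  if (is.null(rootfun)) {
    deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                 rtol = rtol, atol = atol, method = "vode")
  } else {
    deSolve::lsodar(y = y0, times = times, func = func, parms = NULL,
                    rtol = rtol, atol = atol, rootfunc = rootfun)
  }
}

# Project a slightly-off integrator endpoint back into the simplex before
# residual evaluation.
.clamp_simplex <- function(x) {
  x <- pmax(x[1:2], 0)
  s <- x[1] + x[2]
  if (s > 1) x <- x / s
  x
}

.make_trajectory <- function(df, converged) {
  df$x_A <- pmin(pmax(df$x_A, 0), 1)
  df$x_B <- pmin(pmax(df$x_B, 0), 1)
  df$w <- pmin(pmax(1 - df$x_A - df$x_B, 0), 1)
  df <- df[c("t", "x_A", "x_B", "w", "regime")]
  fin <- df[nrow(df), ]
  structure(list(data = df,
                 converged = converged,
                 final_state = c(x_A = fin$x_A, x_B = fin$x_B, w = fin$w)),
            class = "ling_trajectory")
}

#' @export
print.ling_trajectory <- function(x, ...) {
  d <- x$data
  cat(sprintf("Trajectory: %d samples over t = [%g, %g]; regimes: %s\n",
              nrow(d), d$t[1], d$t[nrow(d)],
              paste(unique(d$regime), collapse = ", ")))
  cat(sprintf("  final state (x_A, x_B, w) = (%.6f, %.6f, %.6f)%s\n",
              x$final_state[1], x$final_state[2], x$final_state[3],
              if (isTRUE(x$converged)) "  [converged]" else ""))
  invisible(x)
}

#' Integrate the smooth bilingual competition system
#'
#' Error-controlled adaptive integration of the reduced planar field from an
#' initial simplex point, with dense output. Initial states whose
#' coordinates do not sum to one are renormalized with a warning before
#' integration.
#'
#' @inheritParams rhs_reduced
#' @param x0 initial state: a [population_state()], or a numeric vector of
#'   2 (`x_A`, `x_B`) or 3 (`x_A`, `x_B`, `w`) coordinates.
#' @param t_max integration horizon in model-time units.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param n_out number of evenly spaced output samples (>= 500 by default,
#'   matching the resolution used for the time-series figures).
#' @return A `"ling_trajectory"`: list with `data` (data frame `t`, `x_A`,
#'   `x_B`, `w`, `regime`), `converged` (field residual below 1e-10 at the
#'   final sample) and `final_state`.
#' @export
integrate_smooth <- function(coeffs, a, x0, t_max = 1e4,
                             rtol = 1e-9, atol = 1e-12, n_out = 500) {
  stopifnot(t_max > 0)
  st <- .as_state(x0)
  out <- .integrate_core(coeffs, a, st[1:2], 0, t_max, n_out, rtol, atol)
  df <- data.frame(t = out[, 1], x_A = out[, 2], x_B = out[, 3],
                   regime = "free", stringsAsFactors = FALSE)
  fin <- .clamp_simplex(c(out[nrow(out), 2], out[nrow(out), 3]))
  resid <- max(abs(rhs_reduced(coeffs, a, fin)))
  .make_trajectory(df, converged = resid < 1e-10)
}

#' Long-run attractor of a trajectory
#'
#' Integrates in restartable chunks until the state is stationary (field
#' residual below `rhs_tol` *and* displacement over the last chunk below
#' `disp_tol`) or the time budget is exhausted. The limit is matched
#' against the known equilibria: the three boundary points and, when it
#' exists, the interior equilibrium.
#'
#' @inheritParams integrate_smooth
#' @param t_chunk length of one integration chunk.
#' @param t_budget total model-time budget; non-convergence within it is
#'   reported (`converged = FALSE`), never raised.
#' @param rhs_tol,disp_tol stationarity thresholds.
#' @return List with `state` (`x_A`, `x_B`, `w`), `label` (`"E0"`..`"E3"`
#'   or `"none"`, matched within 1e-4), `converged`, and `time` (model time
#'   at which integration stopped).
#' @export
attractor_of <- function(coeffs, a, x0, t_chunk = 2000, t_budget = 2e5,
                         rhs_tol = 1e-10, disp_tol = 1e-8,
                         rtol = 1e-9, atol = 1e-12) {
  st <- .as_state(x0)
  y <- st[1:2]
  t_now <- 0
  converged <- FALSE
  while (t_now < t_budget) {
    out <- .integrate_core(coeffs, a, y, t_now, t_now + t_chunk,
                           n_out = 50, rtol = rtol, atol = atol)
    y_new <- .clamp_simplex(c(out[nrow(out), 2], out[nrow(out), 3]))
    t_now <- t_now + t_chunk
    resid <- max(abs(rhs_reduced(coeffs, a, y_new)))
    disp <- sqrt(sum((y_new - pmax(y, 0))^2))
    y <- y_new
    if (resid < rhs_tol && disp < disp_tol) {
      converged <- TRUE
      break
    }
  }
  candidates <- trivial_equilibria()
  e3 <- tryCatch(interior_equilibrium(coeffs, a), error = function(e) NULL,
                 warning = function(w) NULL)
  if (!is.null(e3)) candidates <- rbind(candidates, E3 = e3)
  d <- sqrt((candidates[, 1] - y[1])^2 + (candidates[, 2] - y[2])^2)
  label <- if (min(d) < 1e-4) rownames(candidates)[which.min(d)] else "none"
  list(state = c(x_A = unname(y[1]), x_B = unname(y[2]),
                 w = unname(max(1 - sum(y), 0))),
       label = label, converged = converged, time = t_now)
}

#' First-passage time below an extinction threshold
#'
#' Model time at which a trajectory coordinate first drops below a
#' threshold (default 0.01, the working definition of "extinct"), located
#' by linear interpolation between the two bracketing samples. Returns `NA`
#' if the coordinate never crosses.
#'
#' @param traj a `"ling_trajectory"`.
#' @param coordinate which coordinate to monitor (`"x_A"`, `"x_B"` or
#'   `"w"`).
#' @param threshold extinction threshold.
#' @return A scalar time, or `NA`.
#' @export
first_passage_time <- function(traj, coordinate = "x_B", threshold = 0.01) {
  stopifnot(inherits(traj, "ling_trajectory"),
            coordinate %in% c("x_A", "x_B", "w"))
  v <- traj$data[[coordinate]]
  tt <- traj$data$t
  if (v[1] < threshold) return(0)
  i <- which(v < threshold)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- tt[i - 1]; t1 <- tt[i]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (v0 - threshold) / (v0 - v1) * (t1 - t0)
}
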