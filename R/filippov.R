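# Piecewise-smooth (Filippov) extension: a parameter switch below the
# endangerment threshold ET creates a discontinuity line Sigma = {x_B = ET}
# which can carry a sliding segment and a pseudo-equilibrium.

#' Piecewise-smooth controlled competition model
#'
#' Couples two reduced coefficient sets across the switching line
#' `Sigma = {x_B = ET}`: the `free` regime governs `x_B >= ET`, the
#' `controlled` regime (built from the post-intervention "hat" parameters)
#' governs `x_B < ET`. Both regimes share the attractiveness exponent `a`.
#' Exactly on `Sigma` the dynamics are governed by the Filippov convention,
#' not by the inequality.
#'
#' @param free,controlled `"reduced_coeffs"` objects (see
#'   [reduced_coefficients()], [coeff_set()]).
#' @param a attractiveness exponent shared by both regimes.
#' @param ET endangerment threshold, strictly between 0 and 1: the `x_B`
#'   level below which the intervention parameters take over.
#' @return An object of class `"filippov_model"`.
#' @export
filippov_model <- function(free, controlled, a, ET) {
  stopifnot(inherits(free, "reduced_coeffs"),
            inherits(controlled, "reduced_coeffs"))
  if (!is.numeric(ET) || length(ET) != 1L || ET <= 0 || ET >= 1) {
    stop("'ET' must lie strictly between 0 and 1")
  }
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("'a' must be positive")
  structure(list(free = free, controlled = controlled, a = a, ET = ET),
            class = "filippov_model")
}

#' @export
print.filippov_model <- function(x, ...) {
  cat(sprintf("Filippov model on Sigma = {x_B = %g}, a = %g\n", x$ET, x$a))
  cat("  free:       "); print(x$free)
  cat("  controlled: "); print(x$controlled)
  invisible(x)
}

# Normal (x_B) components of both regimes' fields on Sigma, as functions of
# the position x_A along the line.
.sigma_pair <- function(fm, x_A) {
  c(free = .rhs_core(x_A, fm$ET, fm$free, fm$a)[, 2],
    ctrl = .rhs_core(x_A, fm$ET, fm$controlled, fm$a)[, 2])
}

.fa_pair <- function(fm, x_A) {
  c(free = .rhs_core(x_A, fm$ET, fm$free, fm$a)[, 1],
    ctrl = .rhs_core(x_A, fm$ET, fm$controlled, fm$a)[, 1])
}

#' Classify a point of the switching line
#'
#' At `(x_A, ET)` the signs of the two regimes' normal components
#' `sigma_free = f_B^free`, `sigma_ctrl = f_B^ctrl` determine the local
#' behaviour: `"sliding"` when both fields point towards `Sigma`
#' (`sigma_free < 0 < sigma_ctrl`), `"escaping"` when both point away,
#' `"upward crossing"` / `"downward crossing"` when they agree in sign, and
#' `"tangency"` when either vanishes (within `tol`).
#'
#' @param fm a [filippov_model()].
#' @param x_A position along the switching line, in `[0, 1 - ET]`.
#' @param tol tangency tolerance on the normal components.
#' @return A single classification string.
#' @export
classify_sigma_point <- function(fm, x_A, tol = 1e-14) {
  if (x_A < -1e-12 || x_A > 1 - fm$ET + 1e-12) {
    stop("x_A = ", x_A, " lies outside the switching line [0, ", 1 - fm$ET, "]")
  }
  s <- .sigma_pair(fm, min(max(x_A, 0), 1 - fm$ET))
  if (abs(s[1]) <= tol || abs(s[2]) <= tol) return("tangency")
  if (s[1] < 0 && s[2] > 0) return("sliding")
  if (s[2] < 0 && s[1] > 0) return("escaping")
  if (s[1] > 0) "upward crossing" else "downward crossing"
}

# All sign-change roots of f on the grid xs (f already evaluated as fv).
.scan_roots <- function(f, xs, fv, tol = 1e-12) {
  roots <- xs[fv == 0]
  idx <- which(fv[-1] * fv[-length(fv)] < 0)
  for (i in idx) {
    roots <- c(roots, uniroot(f, c(xs[i], xs[i + 1]), tol = tol)$root)
  }
  sort(unique(roots))
}

#' Sliding segment(s) on the switching line
#'
#' Locates the maximal sub-intervals of `[0, 1 - ET]` on which both
#' regimes' fields point towards the switching line. Endpoints are the
#' roots of the two normal components, bracketed on a scan grid and
#' polished to `tol`.
#'
#' @inheritParams classify_sigma_point
#' @param n_scan resolution of the root-bracketing scan.
#' @param tol root-polishing tolerance.
#' @return A matrix with columns `lo`, `hi`; zero rows when no sliding
#'   occurs (a valid result, e.g. when the intervention is too weak to turn
#'   the controlled field upward anywhere).
#' @export
sliding_segment <- function(fm, n_scan = 1024, tol = 1e-12) {
  hi <- 1 - fm$ET
  xs <- seq(0, hi, length.out = n_scan)
  sf_fun <- function(x) unname(.sigma_pair(fm, x)[1])
  sc_fun <- function(x) unname(.sigma_pair(fm, x)[2])
  sf <- vapply(xs, sf_fun, 0)
  sc <- vapply(xs, sc_fun, 0)
  brk <- sort(unique(c(0, .scan_roots(sf_fun, xs, sf, tol),
                       .scan_roots(sc_fun, xs, sc, tol), hi)))
  segs <- NULL
  for (i in seq_len(length(brk) - 1)) {
    mid <- (brk[i] + brk[i + 1]) / 2
    s <- .sigma_pair(fm, mid)
    if (s[1] < 0 && s[2] > 0) segs <- rbind(segs, c(lo = brk[i], hi = brk[i + 1]))
  }
  if (is.null(segs)) {
    segs <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lo", "hi")))
  } else {
    # merge adjacent intervals sharing an endpoint (spurious interior break)
    keep <- list(segs[1, ])
    if (nrow(segs) > 1) {
      for (i in 2:nrow(segs)) {
        last <- keep[[length(keep)]]
        if (abs(segs[i, 1] - last[2]) < tol * 10) {
          keep[[length(keep)]][2] <- segs[i, 2]
        } else keep[[length(keep) + 1]] <- segs[i, ]
      }
    }
    segs <- do.call(rbind, keep)
    colnames(segs) <- c("lo", "hi")
  }
  segs
}

# Sliding vector field without admissibility checking (used by the hybrid
# integrator, which clamps into the segment).
.sliding_rhs <- function(fm, x_A) {
  s <- .sigma_pair(fm, x_A)
  fa <- .fa_pair(fm, x_A)
  lambda <- unname(s[2] / (s[2] - s[1]))
  c(dx_A = unname(lambda * fa[1] + (1 - lambda) * fa[2]), lambda = lambda)
}

#' Filippov sliding vector field on the switching line
#'
#' Inside a sliding segment the motion follows the unique convex
#' combination of the two regimes' fields that is tangent to the switching
#' line: with `lambda = sigma_ctrl / (sigma_ctrl - sigma_free)` the
#' combined normal component vanishes and
#' `dx_A/dt = lambda * f_A^free + (1 - lambda) * f_A^ctrl`. The sliding
#' sign pattern guarantees `lambda` lies in `[0, 1]`.
#'
#' @inheritParams classify_sigma_point
#' @return Named vector `c(dx_A, lambda)`.
#' @export
sliding_field <- function(fm, x_A) {
  if (classify_sigma_point(fm, x_A) != "sliding") {
    stop("x_A = ", x_A, " is not inside a sliding segment")
  }
  .sliding_rhs(fm, x_A)
}

#' Sliding analysis: segments, pseudo-equilibrium, regime map
#'
#' A pseudo-equilibrium is a zero of the sliding field inside a sliding
#' segment: a stationary state of the controlled system that is an
#' equilibrium of neither smooth regime. It solves
#' `H(x_A) = f_A^free * sigma_ctrl - f_A^ctrl * sigma_free = 0` with
#' Filippov weight strictly inside `(0, 1)`. Roots are located by a
#' bracketed sign scan of `H` on each sliding interval.
#'
#' @inheritParams sliding_segment
#' @param n_scan resolution of the sign scan for roots of `H` (per
#'   interval) and of the regime map sample.
#' @return An object of class `"sliding_analysis"`: list with `segments`
#'   (matrix from [sliding_segment()]), `pseudo_equilibrium` (named vector
#'   `c(x_A, x_B, w)` or `NULL`), `lambda_at_pe` (or `NULL`), `all_roots`,
#'   and `regime_map` (data frame sampling [classify_sigma_point()] along
#'   the switching line).
#' @export
pseudo_equilibrium <- function(fm, n_scan = 512, tol = 1e-12) {
  segs <- sliding_segment(fm, tol = tol)
  Hfun <- function(x) {
    s <- .sigma_pair(fm, x)
    fa <- .fa_pair(fm, x)
    unname(fa[1] * s[2] - fa[2] * s[1])
  }
  roots <- numeric(0)
  lambdas <- numeric(0)
  if (nrow(segs) > 0) {
    for (k in seq_len(nrow(segs))) {
      eps <- (segs[k, 2] - segs[k, 1]) * 1e-9
      xs <- seq(segs[k, 1] + eps, segs[k, 2] - eps, length.out = n_scan)
      hv <- vapply(xs, Hfun, 0)
      rts <- .scan_roots(Hfun, xs, hv, tol = tol)
      for (r in rts) {
        lam <- .sliding_rhs(fm, r)[["lambda"]]
        if (lam > 0 && lam < 1) {
          roots <- c(roots, r)
          lambdas <- c(lambdas, lam)
        }
      }
    }
  }
  xg <- seq(0, 1 - fm$ET, length.out = 101)
  rmap <- data.frame(x_A = xg,
                     label = vapply(xg, function(x)
                       classify_sigma_point(fm, x), ""),
                     stringsAsFactors = FALSE)
  pe <- NULL; lam <- NULL
  if (length(roots) > 0) {
    pe <- c(x_A = roots[1], x_B = fm$ET, w = 1 - roots[1] - fm$ET)
    lam <- lambdas[1]
  }
  structure(list(segments = segs, pseudo_equilibrium = pe,
                 lambda_at_pe = lam, all_roots = roots, regime_map = rmap),
            class = "sliding_analysis")
}

#' @export
print.sliding_analysis <- function(x, digits = 4, ...) {
  if (nrow(x$segments) == 0) {
    cat("No sliding segment on the switching line.\n")
  } else {
    cat("Sliding segment(s):\n")
    for (k in seq_len(nrow(x$segments))) {
      cat(sprintf("  x_A in (%.5f, %.5f)\n", x$segments[k, 1], x$segments[k, 2]))
    }
  }
  if (is.null(x$pseudo_equilibrium)) {
    cat("No pseudo-equilibrium: the sliding motion (if any) exits the segment.\n")
  } else {
    cat(sprintf("Pseudo-equilibrium (x_A, x_B, w) = (%s, %s, %s), lambda = %.4f\n",
                format(round(x$pseudo_equilibrium[1], digits)),
                format(round(x$pseudo_equilibrium[2], digits)),
                format(round(x$pseudo_equilibrium[3], digits)),
                x$lambda_at_pe))
  }
  invisible(x)
}

#' Integrate the piecewise-smooth controlled model
#'
#' Event-detected hybrid integration. The active smooth regime is
#' integrated with root finding on `x_B - ET`; each hit of the switching
#' line is classified, leading either to a regime switch (crossing) or to
#' one-dimensional integration of the Filippov sliding field along the
#' line. Sliding ends at the pseudo-equilibrium (convergence) or at a
#' segment endpoint, where the continuation regime is the one whose field
#' points away from the line. Regime labels (`free` / `controlled` /
#' `sliding`) are recorded per sample.
#'
#' @inheritParams classify_sigma_point
#' @inheritParams integrate_smooth
#' @param max_switches chattering guard: abort if the number of regime
#'   switches exceeds this.
#' @return A `"ling_trajectory"` (see [integrate_smooth()]); `converged` is
#'   `TRUE` when the final state is stationary for its active (possibly
#'   sliding) dynamics.
#' @export
integrate_hybrid <- function(fm, x0, t_max = 1e4, rtol = 1e-9, atol = 1e-12,
                             n_out = 500, max_switches = 1e4) {
  st <- .as_state(x0)
  ET <- fm$ET
  segs <- sliding_segment(fm)
  seg_of <- function(x) {
    if (nrow(segs) == 0) return(NA_integer_)
    i <- which(segs[, 1] - 1e-10 <= x & x <= segs[, 2] + 1e-10)
    if (length(i)) i[1] else NA_integer_
  }
  decide_smooth <- function(x_A) {
    s <- .sigma_pair(fm, min(max(x_A, 0), 1 - ET))
    if (sum(s) > 0) "free" else "controlled"
  }
  y <- st[1:2]
  if (abs(y[2] - ET) < 1e-9) {
    cls <- classify_sigma_point(fm, min(max(y[1], 0), 1 - ET))
    mode <- if (cls == "sliding") "sliding" else decide_smooth(y[1])
  } else {
    mode <- if (y[2] >= ET) "free" else "controlled"
  }
  pieces <- list()
  t_now <- 0
  switches <- 0L
  converged <- FALSE
  nudge <- 1e-11
  while (t_now < t_max * (1 - 1e-12)) {
    n_seg <- max(8L, ceiling((t_max - t_now) / t_max * n_out))
    if (mode == "sliding") {
      si <- seg_of(y[1])
      if (is.na(si)) {           # landed at/beyond an endpoint: leave Sigma
        mode <- decide_smooth(y[1])
        next
      }
      lo <- segs[si, 1]; hi <- segs[si, 2]
      slide_fun <- function(t, z, parms) {
        x <- min(max(z[1], lo), hi)
        list(.sliding_rhs(fm, x)[["dx_A"]])
      }
      root_fun <- function(t, z, parms) c(z[1] - lo, hi - z[1])
      out <- deSolve::lsodar(y = c(x_A = unname(y[1])),
                             times = seq(t_now, t_max, length.out = n_seg),
                             func = slide_fun, parms = NULL,
                             rtol = rtol, atol = atol, rootfunc = root_fun)
      pieces[[length(pieces) + 1L]] <-
        data.frame(t = out[, 1], x_A = out[, 2], x_B = ET,
                   regime = "sliding", stringsAsFactors = FALSE)
      t_now <- out[nrow(out), 1]
      y <- c(out[nrow(out), 2], ET)
      if (t_now < t_max * (1 - 1e-12)) {      # exited through an endpoint
        switches <- switches + 1L
        mode <- decide_smooth(y[1])
        y[2] <- if (mode == "free") ET + nudge else ET - nudge
      } else {
        converged <- abs(.sliding_rhs(fm, min(max(y[1], lo), hi))[["dx_A"]]) < 1e-10
      }
    } else {
      cf <- if (mode == "free") fm$free else fm$controlled
      root_fun <- function(t, z, parms) z[2] - ET
      out <- .integrate_core(cf, fm$a, y, t_now, t_max, n_out = n_seg,
                             rtol = rtol, atol = atol, rootfun = root_fun)
      pieces[[length(pieces) + 1L]] <-
        data.frame(t = out[, 1], x_A = out[, 2], x_B = out[, 3],
                   regime = mode, stringsAsFactors = FALSE)
      t_now <- out[nrow(out), 1]
      y <- .clamp_simplex(c(out[nrow(out), 2], out[nrow(out), 3]))
      if (t_now < t_max * (1 - 1e-12)) {      # hit the switching line
        switches <- switches + 1L
        y[2] <- ET
        cls <- classify_sigma_point(fm, min(max(y[1], 0), 1 - ET))
        if (cls == "sliding") {
          mode <- "sliding"
        } else {
          mode <- switch(cls,
                         "upward crossing" = "free",
                         "downward crossing" = "controlled",
                         decide_smooth(y[1]))
          y[2] <- if (mode == "free") ET + nudge else ET - nudge
        }
      } else {
        converged <- max(abs(rhs_reduced(cf, fm$a, y))) < 1e-10
      }
    }
    if (switches > max_switches) {
      stop("chattering: more than ", max_switches,
           " regime switches before t = ", format(t_now))
    }
  }
  df <- do.call(rbind, pieces)
  df <- df[!duplicated(df$t), , drop = FALSE]
  .make_trajectory(df, converged = converged)
}
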