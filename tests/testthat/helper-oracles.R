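# Independent oracles used to freeze or cross-check expected values.

# Stationarity conditions solved by nested bisection, independently of the
# closed forms: for a column x_A, solve the dx_A/dt = 0 factor for x_B,
# then search x_A for a zero of dx_B/dt along that curve.
oracle_interior_root <- function(cf, a, tol = 1e-13) {
  xB_on_A_nullcline <- function(x_A) {
    f <- function(x_B) cf$a1 * (1 - x_A - x_B) * x_A^(a - 1) - cf$a2 * x_B^a
    uniroot(f, c(0, 1 - x_A), tol = tol)$root
  }
  g <- function(x_A) {
    x_B <- xB_on_A_nullcline(x_A)
    cf$a3 * (1 - x_A - x_B) * x_B^(a - 1) - cf$a4 * x_A^a
  }
  # bracket g on a grid of interior columns
  xs <- seq(1e-6, 1 - 1e-6, length.out = 2000)
  gv <- vapply(xs, g, 0)
  i <- which(gv[-1] * gv[-length(gv)] < 0)[1]
  stopifnot(!is.na(i))
  x_A <- uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root
  c(x_A = x_A, x_B = xB_on_A_nullcline(x_A))
}

# For a = 1 the pseudo-equilibrium condition H(x_A)/x_A is an exact
# quadratic; fit it from three evaluations and take polyroot - a route
# fully independent of the package's bracketed sign scan.
oracle_pe_quadratic <- function(fm) {
  stopifnot(abs(fm$a - 1) < 1e-15)
  ET <- fm$ET
  fa <- function(cf, x) cf$a1 * (1 - x - ET) * x - cf$a2 * x * ET
  sg <- function(cf, x) cf$a3 * (1 - x - ET) * ET - cf$a4 * ET * x
  H <- function(x) fa(fm$free, x) * sg(fm$controlled, x) -
    fa(fm$controlled, x) * sg(fm$free, x)
  xs <- c(0.01, 0.02, 0.03)
  co <- solve(outer(xs, 0:2, "^"), H(xs) / xs)
  rt <- polyroot(co)
  sort(Re(rt[abs(Im(rt)) < 1e-9]))
}

rand_coeffs <- function() {
  coeff_set(a1 = runif(1, 0.001, 2), a2 = runif(1, 0.001, 2),
            a3 = runif(1, 0.001, 2), a4 = runif(1, 0.001, 2))
}

rand_simplex <- function(n) {
  u <- matrix(runif(2 * n), ncol = 2)
  flip <- rowSums(u) > 1
  u[flip, ] <- 1 - u[flip, ]
  u
}

table_params <- function(which) {
  switch(which,
         t1 = model_params(0.02, 1.31, 0.4, 0.6, I_wA = 10),
         t2 = model_params(0.02, 1.31, 0.6, 0.4, I_wA = 10),
         t3 = model_params(0.02, 1.00, 0.8, 0.2, I_Aw = 0.03, I_Bw = 0.03),
         t4 = model_params(0.02, 1.00, 0.6, 0.4, I_Aw = 0.03, I_Bw = 0.03),
         t5 = model_params(0.02, 1.00, 0.8, 0.2, I_Aw = 0.06, I_Bw = 0.06),
         t6 = model_params(0.02, 1.00, 0.6, 0.4, I_Aw = 0.06, I_Bw = 0.06),
         stop("unknown table"))
}

fig8_model <- function(ctrl_table) {
  filippov_model(reduced_coefficients(table_params("t3")),
                 reduced_coefficients(table_params(ctrl_table)),
                 a = 1, ET = 0.3)
}
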