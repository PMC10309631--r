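test_that("the three boundary equilibria are stationary for any coefficients", {
  pts <- trivial_equilibria()
  expect_equal(rownames(pts), c("E0", "E1", "E2"))
  expect_equal(unname(pts), matrix(c(0, 0, 0, 1, 1, 0), ncol = 2, byrow = TRUE))
  cf3 <- reduced_coefficients(table_params("t3"))
  set.seed(21)
  for (k in 1:5) {
    cf <- rand_coeffs()
    for (i in 1:3) {
      expect_equal(unname(rhs_reduced(cf3, 1, pts[i, ])), c(0, 0))
      expect_equal(unname(rhs_reduced(cf, 2, pts[i, ])), c(0, 0))
    }
  }
})

test_that("interior equilibrium matches its closed forms and a root-search oracle", {
  cf3 <- reduced_coefficients(table_params("t3"))
  e3 <- interior_equilibrium(cf3, 1)
  expect_equal(round(unname(e3), 4), c(0.0437, 0.6993))
  expect_equal(unname(e3), c(0.043706, 0.699300), tolerance = 1e-5)
  expect_equal(unname(e3), unname(oracle_interior_root(cf3, 1)),
               tolerance = 1e-10)
  # full symmetry pins the equilibrium at the centroid for any exponent
  sym <- coeff_set(0.7, 0.7, 0.7, 0.7)
  for (a in c(1, 1.5, 2)) {
    expect_equal(unname(interior_equilibrium(sym, a)), c(1, 1) / 3,
                 tolerance = 1e-12)
  }
  # hyperbolic-nullcline configuration, a = 2; frozen from the nested
  # bisection oracle: rho = 0.1^(1/3), x_B = 1/(rho + 1 + 0.1/rho)
  hyp <- coeff_set(10, 1, 1, 1)
  e <- interior_equilibrium(hyp, 2)
  expect_equal(unname(e), c(0.27635, 0.59538), tolerance = 1e-5)
  expect_equal(unname(e), unname(oracle_interior_root(hyp, 2)),
               tolerance = 1e-10)
})

test_that("general-exponent formula reduces to the rational form at a = 1", {
  set.seed(22)
  for (k in 1:25) {
    cf <- rand_coeffs()
    expect_equal(unname(interior_equilibrium(cf, 1, method = "rational")),
                 unname(interior_equilibrium(cf, 1, method = "general")),
                 tolerance = 1e-14)
  }
})

test_that("interior equilibrium satisfies the ratio identity and is stationary", {
  set.seed(23)
  for (a in c(1, 1.31, 1.7, 2.5)) {
    for (k in 1:10) {
      cf <- rand_coeffs()
      e <- interior_equilibrium(cf, a)
      expect_lt(max(abs(rhs_reduced(cf, a, e))), 1e-12)
      r <- (cf$a2 * cf$a3) / (cf$a1 * cf$a4)
      expect_equal((e[["x_A"]] / e[["x_B"]])^(2 * a - 1), r,
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate parameterizations are rejected", {
  cf <- reduced_coefficients(table_params("t3"))
  expect_error(interior_equilibrium(cf, 0.5), "a = 1/2")
  degenerate <- structure(list(a1 = 1, a2 = 1, a3 = 1, a4 = 0),
                          class = "reduced_coeffs")
  expect_error(interior_equilibrium(degenerate, 1), "positive")
})

test_that("Jacobian matches the boundary limits and finite differences", {
  cf <- reduced_coefficients(table_params("t3"))
  a1 <- cf$a1; a2 <- cf$a2; a3 <- cf$a3; a4 <- cf$a4
  # all-bilingual corner: diagonal growth rates at a = 1, zero matrix above
  expect_equal(jacobian_reduced(cf, 1, c(0, 0)),
               matrix(c(a1, 0, 0, a3), 2, byrow = TRUE))
  expect_equal(jacobian_reduced(cf, 2, c(0, 0)), matrix(0, 2, 2))
  # monolingual corners
  expect_equal(jacobian_reduced(cf, 1, c(0, 1)),
               matrix(c(-a2, 0, -a3 - a4, -a3), 2, byrow = TRUE))
  expect_equal(jacobian_reduced(cf, 1.31, c(0, 1)),
               matrix(c(-a2, 0, -a3, -a3), 2, byrow = TRUE))
  expect_equal(jacobian_reduced(cf, 1.31, c(1, 0)),
               matrix(c(-a1, -a1, 0, -a4), 2, byrow = TRUE))
  # interior: central differences of the field
  set.seed(24)
  for (a in c(1, 1.31, 2)) {
    p <- c(0.3, 0.4)
    J <- jacobian_reduced(cf, a, p)
    h <- 1e-6
    num <- matrix(0, 2, 2)
    for (j in 1:2) {
      ep <- p; em <- p
      ep[j] <- ep[j] + h; em[j] <- em[j] - h
      num[, j] <- (rhs_reduced(cf, a, ep) - rhs_reduced(cf, a, em)) / (2 * h)
    }
    expect_equal(J, num, tolerance = 1e-7)
  }
  expect_error(jacobian_reduced(cf, 0.9, c(0, 0.5)), "diverges")
})

test_that("p-q indicators and their closed forms at the interior saddle", {
  expect_equal(unname(pq_indicators(matrix(c(2, 0, 0, 3), 2))), c(-5, 6))
  expect_equal(unname(pq_indicators(matrix(0, 2, 2))), c(0, 0))
  cf <- reduced_coefficients(table_params("t3"))
  pq <- pq_indicators(jacobian_reduced(cf, 1, interior_equilibrium(cf, 1)))
  D <- cf$a1 * cf$a4 + cf$a2 * cf$a3 + cf$a2 * cf$a4
  # p = a1 x_A* + a3 x_B* = a1 a3 (a2 + a4) / D, verified against central
  # finite differences of the field (the q closed form is -a1a2a3a4 / D)
  expect_equal(unname(pq["p"]), cf$a1 * cf$a3 * (cf$a2 + cf$a4) / D,
               tolerance = 1e-12)
  expect_equal(unname(pq["q"]), -cf$a1 * cf$a2 * cf$a3 * cf$a4 / D,
               tolerance = 1e-12)
  expect_equal(unname(pq["q"]), -1.6447e-5, tolerance = 1e-4)
})

test_that("equilibria classify per the trace-determinant taxonomy", {
  set.seed(25)
  for (a in c(1, 2)) {
    for (k in 1:10) {
      cf <- rand_coeffs()
      r1 <- classify_equilibrium(cf, a, c(0, 1))
      r2 <- classify_equilibrium(cf, a, c(1, 0))
      expect_equal(r1$classification, "stable node")
      expect_equal(r2$classification, "stable node")
      # discriminants are perfect squares: nodes, never foci
      expect_equal(r1$p^2 - 4 * r1$q, (cf$a2 - cf$a3)^2, tolerance = 1e-10)
      expect_equal(r2$p^2 - 4 * r2$q, (cf$a1 - cf$a4)^2, tolerance = 1e-10)
      e3 <- classify_equilibrium(cf, a, interior_equilibrium(cf, a))
      expect_equal(e3$classification, "saddle (unstable)")
      expect_lt(e3$q, 0)
    }
  }
  # all-bilingual corner: unstable node at a = 1, degenerate above with the
  # perturbation probe detecting escape
  cf3 <- reduced_coefficients(table_params("t3"))
  expect_equal(classify_equilibrium(cf3, 1, c(0, 0))$classification,
               "unstable node")
  e0 <- classify_equilibrium(cf3, 2, c(0, 0))
  expect_equal(e0$classification, "degenerate/non-hyperbolic")
  expect_true(e0$numerically_unstable)
  expect_error(classify_equilibrium(cf3, 1, c(0.4, 0.4)), "not an equilibrium")
})

test_that("the simplex boundary admits no outward flow", {
  cf <- reduced_coefficients(table_params("t3"))
  chk <- boundary_inflow_check(cf, 1.31, n_samples = 101)
  expect_true(all(chk$pass))
  # hand values on the edges: pure outflow along the hypotenuse
  f <- rhs_reduced(cf, 2, c(0.4, 0.6))
  expect_equal(unname(f[1]), -cf$a2 * 0.4 * 0.6^2, tolerance = 1e-14)
  expect_equal(unname(f[2]), -cf$a4 * 0.6 * 0.4^2, tolerance = 1e-14)
  f0 <- rhs_reduced(cf, 2, c(0, 0.5))
  expect_identical(unname(f0[1]), 0)
  expect_equal(unname(f0[2]), cf$a3 * 0.5^3, tolerance = 1e-14)
  # property sweep over random parameterizations
  set.seed(26)
  for (a in c(1, 1.31, 2)) {
    for (k in 1:200) {
      expect_true(all(boundary_inflow_check(rand_coeffs(), a, 21)$pass))
    }
  }
})
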