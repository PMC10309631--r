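# The fig8-style policy studies: free regime from the uncontrolled policy
# table, controlled regime from one of the three intervention tables,
# switching at the endangerment threshold ET = 0.3 with a = 1.

test_that("points of the switching line classify by the two normal components", {
  fm <- fig8_model("t6")
  expect_equal(classify_sigma_point(fm, 0.115), "sliding")
  expect_equal(classify_sigma_point(fm, 0.05), "upward crossing")
  expect_equal(classify_sigma_point(fm, 0.5), "downward crossing")
  expect_error(classify_sigma_point(fm, 0.8), "outside")
  # swapping the regimes turns the sliding window into an escaping one
  fm_swap <- filippov_model(fm$controlled, fm$free, a = 1, ET = 0.3)
  expect_equal(classify_sigma_point(fm_swap, 0.115), "escaping")
})

test_that("sliding segments match the linear-root arithmetic", {
  fm <- fig8_model("t6")
  seg <- sliding_segment(fm)
  expect_equal(nrow(seg), 1L)
  # a = 1 makes both normal components linear in x_A; the endpoints are
  # their roots, computed here from the coefficient arithmetic directly
  lo <- (fm$free$a3 * 0.7) / (fm$free$a3 + fm$free$a4)
  hi <- (fm$controlled$a3 * 0.7) / (fm$controlled$a3 + fm$controlled$a4)
  expect_equal(unname(seg[1, ]), c(lo, hi), tolerance = 1e-10)
  expect_equal(unname(seg[1, ]), c(0.101744, 0.129390), tolerance = 1e-5)

  # status-only intervention: wider window reaching to its own root
  segb <- sliding_segment(fig8_model("t4"))
  expect_equal(unname(segb[1, ]), c(0.101744, 0.218409), tolerance = 1e-5)

  # interaction-only intervention: the sign pattern never occurs
  expect_equal(nrow(sliding_segment(fig8_model("t5"))), 0L)
  # no discontinuity, no sliding
  cf3 <- reduced_coefficients(table_params("t3"))
  expect_equal(nrow(sliding_segment(filippov_model(cf3, cf3, 1, 0.3))), 0L)
})

test_that("the sliding field is the tangent convex combination", {
  fm <- fig8_model("t6")
  s <- sliding_field(fm, 0.115)
  expect_equal(s[["lambda"]], 0.63062, tolerance = 1e-4)
  expect_equal(s[["dx_A"]], 5.4935e-4, tolerance = 1e-4)
  expect_error(sliding_field(fm, 0.05), "not inside")
  # lambda in [0,1] and zero normal component across the whole segment
  seg <- sliding_segment(fm)
  for (x in seq(seg[1, 1] + 1e-6, seg[1, 2] - 1e-6, length.out = 33)) {
    sf <- sliding_field(fm, x)
    expect_gte(sf[["lambda"]], 0); expect_lte(sf[["lambda"]], 1)
    sig <- c(rhs_reduced(fm$free, 1, c(x, 0.3))[2],
             rhs_reduced(fm$controlled, 1, c(x, 0.3))[2])
    resid <- sf[["lambda"]] * sig[1] + (1 - sf[["lambda"]]) * sig[2]
    expect_lt(abs(resid), 1e-14)
  }
})

test_that("the combined intervention admits a pseudo-equilibrium", {
  fm <- fig8_model("t6")
  an <- pseudo_equilibrium(fm)
  expect_false(is.null(an$pseudo_equilibrium))
  expect_equal(round(unname(an$pseudo_equilibrium), 2), c(0.13, 0.30, 0.57))
  # full precision against the independent quadratic-root oracle
  oracle <- oracle_pe_quadratic(fm)
  oracle <- oracle[oracle > an$segments[1, 1] & oracle < an$segments[1, 2]]
  expect_length(oracle, 1L)
  expect_equal(an$pseudo_equilibrium[["x_A"]], oracle, tolerance = 1e-9)
  expect_equal(an$pseudo_equilibrium[["x_A"]], 0.128914, tolerance = 1e-5)
  expect_equal(an$lambda_at_pe, 0.0268, tolerance = 1e-2)
  # the sliding field vanishes there
  expect_lt(abs(sliding_field(fm, an$pseudo_equilibrium[["x_A"]])[["dx_A"]]),
            1e-12)
})

test_that("the weaker interventions fail to create a pseudo-equilibrium", {
  an_b <- pseudo_equilibrium(fig8_model("t4"))
  expect_gt(nrow(an_b$segments), 0L)
  expect_null(an_b$pseudo_equilibrium)
  an_c <- pseudo_equilibrium(fig8_model("t5"))
  expect_equal(nrow(an_c$segments), 0L)
  expect_null(an_c$pseudo_equilibrium)
})

test_that("regime geometry brackets the switching line as designed", {
  # the controlled regime's own interior saddle sits below the threshold,
  # the free regime's above - the geometry that makes sliding control work
  e3_free <- interior_equilibrium(reduced_coefficients(table_params("t3")), 1)
  e3_ctrl <- interior_equilibrium(reduced_coefficients(table_params("t6")), 1)
  expect_equal(round(unname(e3_ctrl), 4), c(0.1305, 0.2937))
  expect_gt(e3_free[["x_B"]], 0.3)
  expect_lt(e3_ctrl[["x_B"]], 0.3)
})

test_that("hybrid trajectories slide into the pseudo-equilibrium locally", {
  fm <- fig8_model("t6")
  pe <- pseudo_equilibrium(fm)$pseudo_equilibrium
  # start exactly on the line inside the segment: sliding from t = 0,
  # perturbed starts on either side along the line converge back
  for (x0 in list(c(0.11, 0.3), c(0.128, 0.3))) {
    tr <- integrate_hybrid(fm, c(x0, 1 - sum(x0)), t_max = 3000)
    expect_equal(tr$data$regime[1], "sliding")
    expect_true(tr$converged)
    expect_equal(unname(tr$final_state),
                 unname(c(pe[["x_A"]], 0.3, 0.7 - pe[["x_A"]])),
                 tolerance = 1e-4)
  }
  # approach from the controlled region below the segment
  tr_lo <- integrate_hybrid(fm, c(0.115, 0.28, 0.605), t_max = 3000)
  expect_true(all(c("controlled", "sliding") %in% tr_lo$data$regime))
  expect_equal(tr_lo$final_state[["x_A"]], pe[["x_A"]], tolerance = 1e-4)
  expect_equal(tr_lo$final_state[["x_B"]], 0.3, tolerance = 1e-6)
})

test_that("trajectories crossing right of the window still lose language B", {
  # From the uniform-ish start the free flow crosses the line at
  # x_A ~ 0.35, right of the sliding window, and the controlled regime
  # carries it to monolingual A - the global basin of the pseudo-
  # equilibrium is limited (the policy guarantees only local coexistence)
  fm <- fig8_model("t6")
  tr <- integrate_hybrid(fm, c(0.33, 0.33, 0.34), t_max = 5000)
  expect_equal(unname(tr$final_state), c(1, 0, 0), tolerance = 1e-3)
  expect_true(all(c("free", "controlled") %in% tr$data$regime))
})

test_that("with identical regimes the hybrid integrator is the smooth one", {
  cf3 <- reduced_coefficients(table_params("t3"))
  fm <- filippov_model(cf3, cf3, 1, 0.3)
  trh <- integrate_hybrid(fm, c(0.5, 0.2, 0.3), t_max = 4000)
  trs <- integrate_smooth(cf3, 1, c(0.5, 0.2, 0.3), t_max = 4000)
  expect_equal(unname(trh$final_state), unname(trs$final_state),
               tolerance = 1e-8)
  expect_equal(unname(trh$final_state), c(1, 0, 0), tolerance = 1e-3)
})

test_that("hybrid trajectories respect the simplex in both regimes", {
  set.seed(41)
  fm <- fig8_model("t6")
  starts <- rand_simplex(5)
  for (i in seq_len(nrow(starts))) {
    tr <- integrate_hybrid(fm, c(starts[i, ], 1 - sum(starts[i, ])),
                           t_max = 2000)
    m <- as.matrix(tr$data[c("x_A", "x_B", "w")])
    expect_gte(min(m), -1e-6)
    expect_lt(max(abs(rowSums(m) - 1)), 1e-6)
  }
})

test_that("model construction validates the threshold and exponent", {
  cf <- reduced_coefficients(table_params("t3"))
  expect_error(filippov_model(cf, cf, 1, 0), "ET")
  expect_error(filippov_model(cf, cf, 1, 1), "ET")
  expect_error(filippov_model(cf, cf, -1, 0.3), "'a'")
})
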