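test_that("closed-form steady state matches hand substitution", {
  cases <- list(
    list(p = c(1, 0, 2, 1, 1), dal80 = 0, mep2 = 1),      # repressor off
    list(p = c(0, 0.4, 2, 1, 1), dal80 = 0, mep2 = 0),    # no activation
    list(p = c(1, 0.4, 2, 1, 1), dal80 = 0.4, mep2 = 0.2),
    list(p = c(1, 0.5, 2, 1, 1), dal80 = 0.5, mep2 = 0))  # X = c/R boundary
  for (cs in cases) {
    ss <- analytic_steady_state(do.call(ffl_params, as.list(cs$p)))
    expect_equal(ss$dal80_ss, cs$dal80)
    expect_equal(ss$mep2_ss, cs$mep2)
    expect_identical(ss$residual, 0)
    expect_identical(ss$method, "analytic")
  }
})

test_that("parameter validation rejects degenerate rates", {
  expect_error(ffl_params(c = 0), "positive")
  expect_error(ffl_params(c = -1), "positive")
  expect_error(ffl_params(A = -0.1), "non-negative")
  expect_error(ffl_params(A = Inf), "finite")
})

test_that("negative MEP2 steady states are reported raw and flagged", {
  ss <- analytic_steady_state(ffl_params(1, 0.8, 2, 1, 1))
  expect_lt(ss$mep2_ss, 0)
  expect_true(ss$negative_mep2)
})

test_that("numeric integration agrees with the closed form across parameters", {
  for (A in c(0.3, 1, 1.7)) for (X in c(0, 0.25, 0.6))
    for (Rc in list(c(2, 1), c(1, 0.5))) {
      p <- ffl_params(A, X, Rc[1], Rc[2], gat1 = 1)
      ana <- analytic_steady_state(p)
      num <- integrate_ffl(p, t_end = 60 / Rc[2])$steady_state
      expect_true(num$converged)
      expect_lt(abs(num$dal80_ss - ana$dal80_ss), 1e-6)
      expect_lt(abs(num$mep2_ss - ana$mep2_ss), 1e-6)
    }
})

test_that("trajectory respects conservation and degenerate end time", {
  p <- ffl_params(1, 0.4, 2, 1, gat1 = 1.7)
  tr0 <- integrate_ffl(p, initial = c(gat1 = 1.7, dal80 = 0, mep2 = 0),
                       t_end = 0)
  expect_equal(nrow(tr0$trajectory), 1L)
  expect_equal(tr0$trajectory$mep2, 0)
  tr <- integrate_ffl(p, initial = c(gat1 = 1.7, dal80 = 0, mep2 = 0),
                      t_end = 30)
  expect_equal(tr$trajectory$gat1, rep(1.7, nrow(tr$trajectory)),
               tolerance = 1e-9)
})

test_that("MEP2 pulses above its steady state for X in (0, c/R)", {
  for (X in c(0.1, 0.25, 0.4, 0.45)) {
    p <- ffl_params(1, X, 2, 1)
    tr <- integrate_ffl(p, t_end = 40)
    expect_gt(max(tr$trajectory$mep2), tr$steady_state$mep2_ss)
  }
})

test_that("sweep grid exposes the increased-expression region", {
  sw <- sweep_parameter_grid(seq(0, 2, by = 0.05), seq(0, 1, by = 0.05),
                             R = 2, c = 1, gat1 = 1, reference = c(1, 0.4))
  expect_equal(dim(sw$mep2_matrix),
               c(length(sw$a_values), length(sw$x_values)))
  # reference cell lies on the grid: relative = 1 there, mask FALSE
  ia <- which(sw$a_values == 1); ix <- which(sw$x_values == 0.4)
  expect_equal(sw$relative_matrix[ia, ix], 1)
  expect_false(sw$increased_mask[ia, ix])
  # a mutant with both activations reduced can still raise MEP2
  ja <- which(sw$a_values == 0.8); jx <- which(sw$x_values == 0.2)
  expect_equal(sw$relative_matrix[ja, jx], 2.4)
  expect_true(sw$increased_mask[ja, jx])
  # beyond X = c/R = 0.5 repression wins: MEP2 negative wherever A > 0
  beyond <- sw$mep2_matrix[sw$a_values > 0, sw$x_values > 0.5]
  expect_true(all(beyond < 0))
})

test_that("sweep with a zero reference flags instead of dividing", {
  expect_warning(
    sw <- sweep_parameter_grid(c(0.5, 1), c(0.2, 0.4), reference = c(1, 0.5)),
    "reference")
  expect_true(sw$reference_undefined)
  expect_null(sw$relative_matrix)
  expect_false(is.null(sw$mep2_matrix))
})

test_that("relative MEP2 expression follows the closed form", {
  anc <- ffl_params(1, 0.4, 2, 1)
  expect_equal(relative_mep2(anc, anc), 1)
  expect_equal(relative_mep2(ffl_params(0.8, 0.2, 2, 1), anc), 2.4)
  expect_equal(relative_mep2(ffl_params(0.8, 0.4, 2, 1), anc), 0.8)
  expect_error(relative_mep2(anc, ffl_params(1, 0.5, 2, 1)), "undefined")
})

test_that("steady state is exactly linear in the GAT1 level", {
  p <- ffl_params(1, 0.4, 2, 1)
  expect_equal(gat1_dose_response(p, c(1, 2, 4)), c(0.2, 0.4, 0.8))
  expect_equal(gat1_dose_response(p, 0), 0)
  g <- runif(10, 0, 5)
  expect_equal(gat1_dose_response(p, 2 * g), 2 * gat1_dose_response(p, g))
  expect_error(gat1_dose_response(p, c(1, -1)), "non-negative")
})

test_that("the increased/decreased sign pattern depends only on A and R*X/c", {
  # rescaling (R, c) while holding R*X/c fixed leaves the relative surface
  # unchanged: the phase diagram is robust to those parameters
  a_vals <- seq(0.1, 2, length.out = 15)
  x_vals <- seq(0, 0.9, length.out = 15)
  base <- sweep_parameter_grid(a_vals, x_vals, R = 2, c = 1,
                               reference = c(1, 0.4))
  for (sc in c(0.5, 3)) {
    # R' = 2*sc, c' = sc keeps R*X/c invariant for every X
    alt <- sweep_parameter_grid(a_vals, x_vals, R = 2 * sc, c = sc,
                                reference = c(1, 0.4))
    expect_equal(alt$relative_matrix, base$relative_matrix,
                 tolerance = 1e-12)
    # masks compared away from relative = 1, where floating-point ties
    # between the two parameterizations can flip the strict inequality
    off_tie <- abs(base$relative_matrix - 1) > 1e-9
    expect_identical(alt$increased_mask[off_tie],
                     base$increased_mask[off_tie])
  }
})
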