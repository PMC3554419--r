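test_that("irreversible MM rate matches hand arithmetic and scales linearly", {
  law <- rate_law("irreversible_mm", vmax_ref = 20, km_substrates = c(A = 2))
  conc <- c(A = 18 / 11)
  # 20 * (18/11) / (2 + 18/11) = 9 exactly
  expect_equal(evaluate_rate(law, conc), 9, tolerance = 1e-12)
  expect_equal(evaluate_rate(law, conc, scale = 0), 0)
  for (s in c(0.25, 0.5, 2, 7.3))
    expect_equal(evaluate_rate(law, conc, scale = s), 9 * s,
                 tolerance = 1e-12)
})

test_that("reversible rate vanishes at equilibrium and follows sign(1 - Gamma/Keq)", {
  law <- rate_law("reversible_mm", vmax_ref = 100,
                  km_substrates = c(G6P = 1.4), km_products = c(F6P = 0.3),
                  keq_ref = 0.29)
  rx <- reaction("PGI", c(G6P = -1, F6P = 1), law, 1)
  eq <- c(G6P = 2, F6P = 0.58) # Gamma = 0.29 = Keq
  expect_equal(mass_action_ratio(rx, eq), 0.29, tolerance = 1e-12)
  expect_equal(evaluate_rate(rx, eq), 0, tolerance = 1e-12)
  fwd <- c(G6P = 2, F6P = 0.29) # Gamma < Keq
  bwd <- c(G6P = 2, F6P = 1.16) # Gamma > Keq
  expect_gt(evaluate_rate(rx, fwd), 0)
  expect_lt(evaluate_rate(rx, bwd), 0)
})

test_that("mass-action ratio follows stoichiometry", {
  ab <- reaction("r", c(A = -1, B = 1),
                 rate_law("mass_action", 1), 1)
  expect_equal(mass_action_ratio(ab, c(A = 2, B = 1)), 0.5)
  fba <- reaction("FBA", c(FBP = -1, TRIO = 2),
                  rate_law("reversible_mm", 1, km_substrates = c(FBP = 0.3),
                           km_products = c(TRIO = 1), keq_ref = 1.4), 1)
  expect_equal(mass_action_ratio(fba, c(FBP = 1, TRIO = 2)), 4.0)
  # consistency: concentrations with Gamma = Keq give zero net rate
  at_eq <- c(FBP = 1, TRIO = sqrt(1.4))
  expect_equal(mass_action_ratio(fba, at_eq), 1.4, tolerance = 1e-12)
  expect_equal(evaluate_rate(fba, at_eq), 0, tolerance = 1e-12)
})

test_that("rate and Gamma evaluation signal missing/invalid input distinctly", {
  law <- rate_law("irreversible_mm", vmax_ref = 20, km_substrates = c(A = 2))
  expect_error(evaluate_rate(law, c(B = 1)), class = "gt_config_error")
  expect_error(evaluate_rate(law, c(A = -1)), class = "gt_domain_error")
  expect_error(evaluate_rate(law, c(A = 1), scale = -1),
               class = "gt_domain_error")
  ab <- reaction("r", c(A = -1, B = 1), rate_law("mass_action", 1), 1)
  expect_error(mass_action_ratio(ab, c(A = 0, B = 1)),
               class = "gt_gamma_undefined")
})

test_that("facilitated diffusion is symmetric and vanishes at equal levels", {
  law <- rate_law("facilitated_diffusion", vmax_ref = 130,
                  km_substrates = c(GLCo = 0.05), km_products = c(GLCi = 0.05))
  rx <- reaction("GLT", c(GLCo = -1, GLCi = 1), law, 1)
  expect_equal(evaluate_rate(rx, c(GLCo = 3, GLCi = 3)), 0)
  expect_equal(evaluate_rate(rx, c(GLCo = 3, GLCi = 1)),
               -evaluate_rate(rx, c(GLCo = 1, GLCi = 3)), tolerance = 1e-12)
})
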