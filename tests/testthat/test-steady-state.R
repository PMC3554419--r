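test_that("toy pathway steady state matches the closed-form MM inversion", {
  toy <- toy_pathway()
  ss <- solve_steady_state(toy, toy_clamp(9))
  # J = 10*9/10 = 9; A = B = J*K/(Vmax-J) = 18/11
  expect_equal(unname(ss$concentrations[["A"]]), 18 / 11, tolerance = 1e-8)
  expect_equal(unname(ss$concentrations[["B"]]), 18 / 11, tolerance = 1e-8)
  expect_equal(unname(ss$fluxes[["v1"]]), 9, tolerance = 1e-8)
  expect_lte(ss$residual_norm, 1e-9)
  expect_true(all(ss$concentrations >= 0))
})

test_that("uniform capacity scaling preserves concentrations and scales fluxes", {
  toy <- toy_pathway()
  base <- solve_steady_state(toy, toy_clamp(9))
  for (r in c(0.25, 0.5, 2, 5)) {
    ss <- solve_steady_state(toy, toy_clamp(9), scales = r)
    expect_equal(ss$concentrations, base$concentrations, tolerance = 1e-6)
    expect_equal(ss$fluxes, base$fluxes * r, tolerance = 1e-6)
  }
  m <- reduced_glycolysis()
  gbase <- solve_steady_state(m, glyco_clamp())
  for (r in c(1 / 6, 0.5, 2)) {
    ss <- solve_steady_state(m, glyco_clamp(), scales = r,
                             initial_guess = gbase$concentrations)
    expect_equal(ss$concentrations, gbase$concentrations, tolerance = 1e-6)
    expect_equal(ss$fluxes, gbase$fluxes * r, tolerance = 1e-6)
  }
})

test_that("imposed-flux state at scale r equals the state at scale 1 and flux/r", {
  toy <- toy_pathway()
  half <- steady_state_at_flux(toy, 3, substrate_id = "S",
                               flux_reaction = "v1", scales = 0.5)
  expect_equal(unname(attr(half, "substrate")), 1.5, tolerance = 1e-8)
  expect_equal(unname(half$concentrations[["A"]]), 6 / 7, tolerance = 1e-8)
  full <- steady_state_at_flux(toy, 6, substrate_id = "S",
                               flux_reaction = "v1", scales = 1)
  expect_equal(half$concentrations, full$concentrations, tolerance = 1e-8)
})

test_that("solver agrees with dense 1-D bisection over each pool", {
  toy <- toy_pathway()
  ss <- solve_steady_state(toy, toy_clamp(9))
  J <- 10 * 9 / (1 + 9)
  a_star <- bisect(function(a) 20 * a / (2 + a) - J, 0, 100)
  b_star <- bisect(function(b) 20 * b / (2 + b) - J, 0, 100)
  expect_equal(unname(ss$concentrations[["A"]]), a_star, tolerance = 1e-8)
  expect_equal(unname(ss$concentrations[["B"]]), b_star, tolerance = 1e-8)
})

test_that("all-zero capacities yield the trivial state with a warning", {
  toy <- toy_pathway(vmax = c(0, 0, 0))
  expect_warning(ss <- solve_steady_state(toy, toy_clamp(9)),
                 "zero-flux")
  expect_true(all(ss$fluxes == 0))
})

test_that("time-course simulation relaxes to the algebraic steady state", {
  toy <- toy_pathway()
  traj <- simulate_network(toy, clamped_profiles = list(S = 9, P = 0),
                           t_span = c(0, 50), t_eval = c(0, 1, 50),
                           initial = c(A = 0.1, B = 0.1))
  ss <- solve_steady_state(toy, toy_clamp(9))
  last <- traj[nrow(traj), ]
  expect_equal(last$A, unname(ss$concentrations[["A"]]), tolerance = 1e-6)
  expect_equal(last$B, unname(ss$concentrations[["B"]]), tolerance = 1e-6)
  expect_equal(last$flux_v1, 9, tolerance = 1e-6)
})

test_that("t_eval = 0 returns the initial condition exactly", {
  toy <- toy_pathway()
  traj <- simulate_network(toy, list(S = 9, P = 0), t_span = c(0, 1),
                           t_eval = 0, initial = c(A = 0.3, B = 0.7))
  expect_identical(nrow(traj), 1L)
  expect_equal(traj$A, 0.3)
  expect_equal(traj$B, 0.7)
})

test_that("halving all capacities mid-run restores the same pools after a transient", {
  toy <- toy_pathway()
  scale_fn <- function(t) if (t < 5) 1 else 0.5
  traj <- simulate_network(toy, list(S = 9, P = 0),
                           scale_profiles = scale_fn,
                           t_span = c(0, 30),
                           t_eval = c(0, 4.9, 5.2, 30),
                           initial = c(A = 18 / 11, B = 18 / 11))
  expect_equal(traj$A[traj$time_h == 30], 18 / 11, tolerance = 1e-6)
  expect_equal(traj$B[traj$time_h == 30], 18 / 11, tolerance = 1e-6)
  expect_equal(traj$flux_v1[traj$time_h == 30], 4.5, tolerance = 1e-6)
})
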