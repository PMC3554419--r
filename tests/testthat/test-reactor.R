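cfg_chem <- reactor_config("chemostat")
cfg_batch <- reactor_config("batch", evaporation_k = 0)

test_that("mass balances vanish without biomass and flow", {
  m <- reduced_glycolysis()
  cfg <- reactor_config("batch")
  intr <- species_ids(m, "intracellular")
  state <- c(stats::setNames(rep(0.5, length(intr)), intr),
             n_GLCo = 100, n_ETOH = 0, n_GLYC = 0, n_CO2 = 0,
             n_X = 0, n_CO2cum = 0)
  d <- reactor_derivative(state, 0, m, scales = 1, config = cfg)
  expect_equal(unname(d$derivative[c("n_GLCo", "n_ETOH", "n_GLYC")]),
               c(0, 0, 0))
  expect_equal(unname(d$derivative[["n_X"]]), 0)
})

test_that("chemostat steady state balances uptake against feed flow", {
  m <- reduced_glycolysis()
  cs <- chemostat_steady_state(m, cfg_chem, 30)
  d <- reactor_derivative(cs$state, 0, m, scales = 1, config = cfg_chem)
  steady_part <- setdiff(names(d$derivative), "n_CO2cum") # off-gas accumulates
  expect_lt(max(abs(d$derivative[steady_part])), 1e-5)
  # q_i N_x = F (C_in - C_out) for glucose at steady state
  feed <- cfg_chem$feed_concentrations[["GLCo"]]
  lhs <- d$q[["glc_consumed"]] * cs$state[["n_X"]]
  rhs <- cfg_chem$f_in * (feed - cs$glucose_mM)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  expect_equal(d$mu, cfg_chem$dilution_rate, tolerance = 1e-6)
})

test_that("a simulated chemostat run holds mu = D at the imposed dilution rate", {
  m <- reduced_glycolysis()
  tr <- run_reactor(m, cfg_chem, temperature_profile("constant", constant = 30),
                    t_span = c(0, 50), t_eval = seq(0, 50, 5))
  expect_lt(abs(tr$mu[nrow(tr)] - 0.03), 1e-4)
  expect_false(attr(tr, "washout"))
  # off-gas rate of a steady chemostat is constant
  og <- co2_offgas_rate(tr)
  expect_lt(diff(range(og)) / mean(og), 1e-5)
})

test_that("the carbon balance of a closed batch closes within 0.5%", {
  m <- reduced_glycolysis()
  tr <- run_reactor(m, cfg_batch, temperature_profile("constant", constant = 30),
                    t_span = c(0, 24), t_eval = seq(0, 24, 0.1))
  cb <- carbon_balance(tr)
  expect_lt(cb$relative_gap, 0.005)
})

test_that("glucose-excess batches at 12 and 30 degC share intracellular pools and a six-fold rate gap", {
  m <- reduced_glycolysis()
  t30 <- run_reactor(m, cfg_batch, temperature_profile("constant", constant = 30),
                     t_span = c(0, 24), t_eval = seq(0, 24, 0.05))
  t12 <- run_reactor(m, cfg_batch, temperature_profile("constant", constant = 12),
                     t_span = c(0, 150), t_eval = seq(0, 150, 0.25))
  # compare at identical extracellular glucose (60 % of the initial charge)
  g_ref <- cfg_batch$feed_concentrations[["GLCo"]] * 0.6
  pick <- function(tr, col) stats::approx(rev(tr$GLCo), rev(tr[[col]]),
                                          xout = g_ref, ties = "ordered")$y
  for (met in glyco_metabolites)
    expect_equal(pick(t12, met), pick(t30, met), tolerance = 1e-3)
  rk <- ratkowsky_params()
  ratio_expected <- ratkowsky_scale(rk, 30) / ratkowsky_scale(rk, 12)
  expect_equal(pick(t30, "q_CO2") / pick(t12, "q_CO2"), ratio_expected,
               tolerance = 1e-3)
})

test_that("doubling biomass at equal specific flux doubles the off-gas rate", {
  m <- reduced_glycolysis()
  cs <- chemostat_steady_state(m, cfg_chem, 30)
  s1 <- cs$state
  s2 <- s1; s2[["n_X"]] <- 2 * s1[["n_X"]]
  d1 <- reactor_derivative(s1, 0, m, 1, cfg_chem)
  d2 <- reactor_derivative(s2, 0, m, 1, cfg_chem)
  expect_equal(d2$q[["CO2"]], d1$q[["CO2"]]) # specific rate unchanged
  expect_equal(d2$q[["CO2"]] * s2[["n_X"]], 2 * d1$q[["CO2"]] * s1[["n_X"]])
  # zero flux gives zero off-gas
  s0 <- s1; s0[["n_X"]] <- 0
  expect_equal(unname(reactor_derivative(s0, 0, m, 0, cfg_chem)$q[["CO2"]]), 0)
})

test_that("residual glucose rises monotonically while the temperature falls", {
  m <- reduced_glycolysis()
  lts <- temperature_profile("linear_shift", start_T = 30, target_T = 12,
                             ramp_rate = 0.2)
  tr <- run_reactor(m, cfg_chem, lts, t_span = c(0, 1.5),
                    t_eval = seq(0, 1.5, 0.05))
  expect_true(all(diff(tr$GLCo) > -1e-9))
})

test_that("washout is flagged when the dilution rate exceeds attainable growth", {
  m <- reduced_glycolysis()
  cfg <- reactor_config("chemostat", dilution_rate = 0.3)
  cs30 <- chemostat_steady_state(m, cfg_chem, 30)
  init <- cs30$state
  tr <- run_reactor(m, cfg, temperature_profile("constant", constant = 30),
                    t_span = c(0, 40), t_eval = seq(0, 40, 2), init = init)
  expect_true(attr(tr, "washout"))
  expect_true(all(is.finite(tr$biomass_gdw_l))) # run continued to the horizon
  # and an infeasible algebraic steady state errors out explicitly
  expect_error(chemostat_steady_state(m, cfg, 30), "infeasible")
})

test_that("without biomass a chemostat relaxes its glucose to the feed level", {
  m <- reduced_glycolysis()
  intr <- species_ids(m, "intracellular")
  init <- c(stats::setNames(rep(0.01, length(intr)), intr),
            n_GLCo = 10, n_ETOH = 0, n_GLYC = 0, n_CO2 = 0,
            n_X = 0, n_CO2cum = 0)
  tr <- run_reactor(m, cfg_chem, temperature_profile("constant", constant = 30),
                    t_span = c(0, 400), t_eval = seq(0, 400, 20), init = init)
  feed <- cfg_chem$feed_concentrations[["GLCo"]]
  expect_equal(tr$GLCo[nrow(tr)], feed, tolerance = 1e-3)
  expect_equal(tr$biomass_gdw_l[nrow(tr)], 0)
})
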