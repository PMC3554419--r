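test_that("Ratkowsky scale is normalized at t_ref, zero at t_min, six-fold over 12-30", {
  rk <- ratkowsky_params()
  expect_equal(ratkowsky_scale(rk, 30), 1)
  expect_equal(ratkowsky_scale(rk, rk$t_min), 0)
  expect_equal(ratkowsky_scale(rk, 12), (12.42 / 30.42)^2, tolerance = 1e-12)
  expect_equal(ratkowsky_scale(rk, 30) / ratkowsky_scale(rk, 12), 6.0,
               tolerance = 0.01)
  T <- seq(rk$t_min, 30, length.out = 50)
  expect_true(all(diff(ratkowsky_scale(rk, T)) > 0))
  expect_error(ratkowsky_scale(rk, -5), class = "gt_domain_error")
})

test_that("flux-proportional coefficients follow the reference flux share", {
  expect_equal(compute_b(0.02, 5, 5), 0.02)
  expect_equal(compute_b(0.02, 2.5, 5), 0.01)
  expect_equal(compute_b(0.02, 0, 5), 0)
  expect_error(compute_b(0.02, 1, 0), class = "gt_domain_error")
})

test_that("Van't Hoff inversion recovers the anchor pair and is symmetric", {
  # printed pair 20 (12 degC) and 16 (30 degC)
  dh <- vant_hoff_delta_h(20, celsius_to_kelvin(12), 16, celsius_to_kelvin(30))
  oracle <- log(16 / 20) * 8.314 /
    ((303.15 - 285.15) / (285.15 * 303.15))
  expect_equal(dh, oracle, tolerance = 1e-12)
  expect_equal(dh / 1000, -8.91, tolerance = 0.01) # kJ/mol
  expect_equal(vant_hoff_delta_h(16, celsius_to_kelvin(30),
                                 20, celsius_to_kelvin(12)), dh,
               tolerance = 1e-12)
  expect_equal(vant_hoff_delta_h(5, 285, 5, 300), 0)
  expect_error(vant_hoff_delta_h(-1, 285, 5, 300), class = "gt_domain_error")
  expect_error(vant_hoff_delta_h(1, 285, 5, 285), class = "gt_domain_error")
})

test_that("Keq propagation round-trips both anchors for all packaged reactions", {
  tab <- keq_table()
  vh <- keq_params_from_table(t_ref = 30)
  for (i in seq_len(nrow(tab))) {
    p <- vh[[tab$reaction[i]]]
    expect_equal(keq_at_temperature(p, celsius_to_kelvin(30)), tab$keq_30[i],
                 tolerance = 1e-10)
    expect_equal(keq_at_temperature(p, celsius_to_kelvin(12)), tab$keq_12[i],
                 tolerance = 1e-10)
  }
  flat <- vant_hoff_params(2, 0)
  expect_equal(keq_at_temperature(flat, c(280, 290, 310)), rep(2, 3))
})

test_that("packaged Keq pairs reproduce the printed fold changes per convention", {
  tab <- keq_table()
  vh <- keq_params_from_table(t_ref = 30)
  for (i in seq_len(nrow(tab))) {
    k12 <- keq_at_temperature(vh[[tab$reaction[i]]], celsius_to_kelvin(12))
    k30 <- tab$keq_30[i]
    fold <- if (tab$fold_convention[i] == "12/30") k12 / k30 else k30 / k12
    # printed to 2-3 significant digits: allow half an ULP of the print
    expect_lt(abs(fold - tab$fold_printed[i]) / tab$fold_printed[i], 0.012)
  }
})

test_that("sensitivity perturbation halves the exponent and keeps normalization", {
  rk <- ratkowsky_params()
  rx <- c("GLT", "PFK", "TDHL")
  base <- apply_sensitivity(rk, NULL, rx)
  pert <- apply_sensitivity(rk, sensitivity_spec("TDHL", 2), rx)
  expect_equal(scales_at_temperature(pert, 17),
               scales_at_temperature(apply_sensitivity(rk,
                 sensitivity_spec("TDHL", 1), rx), 17)^c(1, 1, 0.5),
               tolerance = 1e-12)
  expect_equal(pert$TDHL(12), 12.42 / 30.42, tolerance = 1e-12)
  expect_equal(pert$PFK(12), (12.42 / 30.42)^2, tolerance = 1e-12)
  # factor 1 leaves everything at baseline; huge factor approaches insensitivity
  f1 <- apply_sensitivity(rk, sensitivity_spec("PFK", 1), rx)
  expect_equal(scales_at_temperature(f1, 21), scales_at_temperature(base, 21))
  finf <- apply_sensitivity(rk, sensitivity_spec("PFK", 1e12), rx)
  expect_equal(finf$PFK(12), 1, tolerance = 1e-9)
  # every returned function is exactly 1 at the reference temperature
  for (fn in pert) expect_equal(fn(30), 1)
  expect_error(apply_sensitivity(rk, sensitivity_spec("NOPE", 2), rx),
               class = "gt_config_error")
})

test_that("temperature profiles match their printed definitions", {
  ctc <- temperature_profile("sinoid")
  expect_equal(round(profile_temperature(ctc, 0), 2), 30.00)
  t <- seq(0, 48, by = 0.01)
  T <- profile_temperature(ctc, t)
  expect_equal(max(T), 30, tolerance = 1e-6)
  expect_equal(min(T), 12, tolerance = 1e-6)
  expect_equal(profile_temperature(ctc, t + 24), T, tolerance = 1e-12)

  lts <- temperature_profile("linear_shift", start_T = 30, target_T = 12,
                             ramp_rate = 0.2)
  expect_equal(shift_duration(lts), 3) # 18 degC per leg at 12 degC/h
  expect_equal(profile_temperature(lts, 1.5), 12)
  expect_equal(profile_temperature(lts, c(0, 3, 5)), c(30, 30, 30))
  expect_equal(profile_temperature(lts, 0.5), 24)
  # continuity: increments bounded by ramp_rate * dt
  tt <- seq(0, 4, by = 0.001)
  dT <- abs(diff(profile_temperature(lts, tt)))
  expect_true(all(dT <= 0.2 * 60 * 0.001 + 1e-9))

  const <- temperature_profile("constant", constant = 18)
  expect_equal(profile_temperature(const, c(0, 7, 100)), rep(18, 3))
})

test_that("scale table tabulates every reaction at every temperature", {
  rk <- ratkowsky_params()
  fns <- apply_sensitivity(rk, NULL, c("GLT", "PFK"))
  tab <- scale_table(fns, temperatures = c(12, 30))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$scale[tab$T_C == 30], c(1, 1))
})
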