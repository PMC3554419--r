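test_that("isotonic reference curve reproduces monotone data exactly", {
  s <- 10^seq(-1, 1, length.out = 12)
  a <- 2 * s / (2 + s) # toy-pathway manifold shape, strictly increasing
  fit <- fit_reference_curve(s, a)
  expect_equal(max(abs(predict_curve(fit, s) - a)), 0, tolerance = 1e-12)
  # constant level gives a constant curve
  cfit <- fit_reference_curve(s, rep(3, 12))
  expect_equal(predict_curve(cfit, c(0.2, 2, 8)), rep(3, 3))
  # decreasing data are fitted with the direction from the rank correlation
  dfit <- fit_reference_curve(s, rev(a))
  expect_equal(max(abs(predict_curve(dfit, s) - rev(a))), 0, tolerance = 1e-12)
  expect_error(fit_reference_curve(s[1:4], a[1:4]), class = "gt_domain_error")
  expect_error(fit_reference_curve(rep(1, 6), a[1:6]),
               class = "gt_domain_error")
})

test_that("noise-free collapsed regimes score zero and raise no flag", {
  fx <- make_fixture("collapsed")
  sc <- collapse_scores(fx, n_perm = 0)
  expect_lt(sc$c_pooled, 1e-12)
  expect_lt(sc$c_regime_max, 1e-12)
  expect_identical(sc$flagged_regimes, "")
})

test_that("a 1.5x offset regime is flagged with the exact constructed score", {
  fx <- make_fixture("offset_regime")
  sc <- collapse_scores(fx, n_perm = 0)
  # pooled curve at each glucose level is (2 g + 1.5 g)/3 = 7/6 g, so
  # residuals are -1/7 (regime A) and +2/7 (regime B)
  expect_equal(sc$c_pooled, 1 / 7, tolerance = 1e-12)
  expect_equal(sc$c_regime_max, 2 / 7, tolerance = 1e-12)
  expect_identical(sc$flagged_regimes, "B")
  # variant with equal point counts: both regimes sit 0.2 from the
  # pooled mean curve
  eq <- fx[!duplicated(paste(fx$regime, fx$time_h)) | fx$regime == "B", ]
  sc_eq <- collapse_scores(eq, n_perm = 0)
  expect_equal(sc_eq$c_regime_max, 0.2, tolerance = 1e-12)
  expect_true(grepl("B", sc_eq$flagged_regimes))
})

test_that("collapse scores are invariant to rescaling a metabolite", {
  fx <- make_fixture("offset_regime")
  fx2 <- fx; fx2$level <- fx2$level * 7.3
  a <- collapse_scores(fx, n_perm = 200, seed = 42)
  b <- collapse_scores(fx2, n_perm = 200, seed = 42)
  expect_equal(a$c_pooled, b$c_pooled, tolerance = 1e-12)
  expect_equal(a$c_regime_max, b$c_regime_max, tolerance = 1e-12)
  expect_identical(a$flagged_regimes, b$flagged_regimes)
})

test_that("permutation p-values are valid, deterministic, and seed-sensitive", {
  tab <- make_null_table(7)
  a <- collapse_scores(tab, n_perm = 500, seed = 3)
  b <- collapse_scores(tab, n_perm = 500, seed = 3)
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)
})

test_that("the boundary rule localizes, rejects, and validates patterns", {
  m <- reduced_glycolysis()
  flags <- c(G6P = TRUE, F6P = TRUE, FBP = TRUE, TRIO = TRUE,
             PEP = FALSE, PYR = FALSE)
  res <- localize_deviant_enzyme(flags, m)
  expect_identical(res$candidate, "TDHL")
  expect_true(res$consistent)
  # PEP-deep deviation points at PYK; F6P-only at PFK
  expect_identical(localize_deviant_enzyme(
    c(G6P = TRUE, F6P = TRUE, FBP = TRUE, TRIO = TRUE, PEP = TRUE,
      PYR = FALSE), m)$candidate, "PYK")
  all_ok <- localize_deviant_enzyme(
    c(G6P = FALSE, F6P = FALSE, FBP = FALSE, TRIO = FALSE, PEP = FALSE,
      PYR = FALSE), m)
  expect_null(all_ok$candidate)
  expect_true(all_ok$consistent)
  bad <- localize_deviant_enzyme(
    c(G6P = FALSE, F6P = TRUE, FBP = FALSE, TRIO = FALSE, PEP = FALSE,
      PYR = FALSE), m)
  expect_null(bad$candidate)
  expect_false(bad$consistent)
  expect_identical(unname(bad$pattern["F6P"]), "deviant")
  expect_error(localize_deviant_enzyme(c(XXX = TRUE, G6P = TRUE, F6P = TRUE), m),
               class = "gt_config_error")
  expect_error(localize_deviant_enzyme(c(G6P = TRUE, F6P = TRUE), m),
               class = "gt_domain_error")
})

test_that("the deviant-pattern fixture localizes to its constructed boundary", {
  m <- reduced_glycolysis()
  fd <- make_fixture("deviant_enzyme_pattern")
  rep <- analyze_collapse(fd, pathway = m, n_perm = 0)
  expect_identical(rep$localization$candidate, "TDHL")
  expect_true(all(rep$scores$flag_excess[rep$scores$metabolite %in%
                                           c("G6P", "F6P", "FBP", "TRIO")]))
  expect_false(any(rep$scores$flag_excess[rep$scores$metabolite %in%
                                            c("PEP", "PYR")]))
})

test_that("the threshold is raised to twice the replicate CV when that is larger", {
  fd <- make_fixture("deviant_enzyme_pattern")
  rep <- analyze_collapse(fd, theta = 0.15, replicate_cv = 0.2, n_perm = 0)
  expect_equal(rep$theta, 0.4)
})
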