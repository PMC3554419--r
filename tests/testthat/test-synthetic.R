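# a small fabricated scenario result (true values) used across blocks
fake_result <- function() {
  grid <- expand.grid(time_h = c(1, 2, 3, 4), metabolite = glyco_metabolites,
                      stringsAsFactors = FALSE)
  data.frame(regime = "SBR", sample_id = paste0("s", grid$time_h),
             time_h = grid$time_h,
             temperature_C = rep(c(12, 18, 24, 30), times = 6),
             glucose_mM = 100,
             metabolite = grid$metabolite,
             level = rep(c(4.9, 0.87, 2.4, 1.1, 1.6, 2.7), each = 4),
             stratum = "excess", stringsAsFactors = FALSE)
}

test_that("zero noise reproduces the true values with zero standard error", {
  tab <- synthesize_measurements(fake_result(), noise_model(cv = 0, seed = 1))
  truth <- fake_result()
  key <- paste(truth$time_h, truth$metabolite)
  expect_equal(tab$level[match(key, paste(tab$time_h, tab$metabolite))],
               truth$level, tolerance = 1e-12)
  expect_true(all(tab$sem == 0))
})

test_that("identical seeds give byte-identical tables, different seeds differ", {
  a <- synthesize_measurements(fake_result(), noise_model(seed = 11))
  b <- synthesize_measurements(fake_result(), noise_model(seed = 11))
  expect_identical(a, b)
  c2 <- synthesize_measurements(fake_result(), noise_model(seed = 12))
  expect_false(isTRUE(all.equal(a$level, c2$level)))
})

test_that("reported levels are unbiased within 3% over 50 seeds", {
  truth <- fake_result()
  ratios <- sapply(1:50, function(s) {
    tab <- synthesize_measurements(truth, noise_model(cv = 0.10, seed = s))
    key <- paste(truth$time_h, truth$metabolite)
    tab$level[match(key, paste(tab$time_h, tab$metabolite))] / truth$level
  })
  per_met <- tapply(rowMeans(ratios), truth$metabolite, mean)
  expect_true(all(per_met > 0.97 & per_met < 1.03))
})

test_that("the standard error tracks cv * level / sqrt(replicates) in expectation", {
  truth <- fake_result()
  truth <- truth[truth$time_h == 1, ] # one sample per metabolite
  cv <- 0.10; k <- 3
  sems <- sapply(1:200, function(s)
    synthesize_measurements(truth,
                            noise_model(cv = cv, replicates = k,
                                        seed = s))$sem)
  expected <- cv * truth$level[order(truth$metabolite)] / sqrt(k)
  got <- rowMeans(matrix(sems, nrow = 6))
  expect_true(all(abs(got / expected - 1) < 0.20))
})

test_that("glucose readings below the limit of quantification are censored", {
  r <- fake_result()[1:2, ]
  r$glucose_mM <- 1e-5
  tab <- synthesize_measurements(r, noise_model(cv = 0, seed = 1,
                                                glucose_loq = 0.01))
  expect_true(all(tab$glucose_mM == 0.005))
})

test_that("fixtures carry their designed structure", {
  fx <- make_fixture("collapsed")
  expect_lte(nrow(fx), 60)
  expect_identical(sort(unique(fx$regime)), c("A", "B"))
  fd <- make_fixture("deviant_enzyme_pattern")
  expect_lte(nrow(fd), 60)
  expect_true(all(fd$stratum == "excess"))
  expect_error(make_fixture("nope"))
})

test_that("independent cultures are pooled into one table deterministically", {
  m <- reduced_glycolysis()
  spec <- scenario_spec("SBR", "identical", batch_temperatures = 30)
  a <- synthesize_dataset(m, spec, noise = noise_model(seed = 5),
                          independent_runs = 2)
  b <- synthesize_dataset(m, spec, noise = noise_model(seed = 5),
                          independent_runs = 2)
  expect_identical(a, b)
  expect_true(all(a$n == 4)) # 2 replicates x 2 cultures
})
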