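#!/usr/bin/env Rscript
# The measurement-level analysis: synthesize noisy duplicate measurements
# from both simulation rounds (two independent cultures, 10% CV lognormal
# noise), run the collapse statistic and the localization rule, and summarize
# recovery over repeated noise draws.

suppressPackageStartupMessages(library(glycotherm))
dir.create("results", showWarnings = FALSE)

model <- reduced_glycolysis()
seed <- 20260928L

make_cultures <- function(hypothesis, sens = NULL) {
  spec <- if (hypothesis == "identical") scenario_spec("SBR", "identical")
          else scenario_spec("SBR", "single_enzyme_different",
                             sensitivity = sens)
  lapply(c(0.96, 1.04), function(j)
    run_scenario(model, spec, x0_jitter = j))
}

cult_tdhl <- make_cultures("different", sensitivity_spec("TDHL", 2))
cult_ident <- make_cultures("identical")

tab <- synthesize_measurements(cult_tdhl, noise_model(cv = 0.10, seed = seed))
write_gt_csv(tab, "results/synthetic_measurements_tdhl.csv", seed = seed)
report <- analyze_collapse(tab, pathway = model, replicate_cv = 0.10,
                           n_perm = 1000, seed = seed)
write_gt_csv(report$scores, "results/collapse_scores_tdhl.csv", seed = seed)
write_collapse_report(report, "results/collapse_report_tdhl.json")
message("Single noisy dataset (TDHL half-sensitive): localization -> ",
        report$localization$candidate)

recover <- function(cultures, target) {
  mean(vapply(1:50, function(s) {
    t <- synthesize_measurements(cultures, noise_model(cv = 0.10, seed = s))
    r <- analyze_collapse(t, pathway = model, replicate_cv = 0.10, n_perm = 0)
    if (is.null(target)) !any(r$scores$flag_excess)
    else identical(r$localization$candidate, target)
  }, logical(1)))
}
summary <- data.frame(
  case = c("TDHL recovered", "identical: no false flag"),
  rate_over_50_seeds = c(recover(cult_tdhl, "TDHL"),
                         recover(cult_ident, NULL)))
write_gt_csv(summary, "results/recovery_summary.csv", seed = seed)
message("Recovery over 50 noise seeds: ",
        paste(summary$case, "=", summary$rate_over_50_seeds, collapse = "; "))
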