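#' Measurement noise model
#'
#' Multiplicative lognormal noise (the metabolomics convention): each
#' replicate observes `level * L` with `L` lognormal with mean 1 and
#' coefficient of variation `cv`. Reported values are replicate means with
#' the standard error of the mean; glucose readings below the limit of
#' quantification are censored at half the limit.
#'
#' @param cv Coefficient of variation (default 0.10).
#' @param replicates Replicates per sample (default 2).
#' @param glucose_loq Glucose limit of quantification (mM, default 0.01).
#' @param seed Integer seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(cv = 0.10, replicates = 2L, glucose_loq = 0.01,
                        seed = 1L) {
  stopifnot(cv >= 0, replicates >= 1)
  structure(list(cv = cv, replicates = as.integer(replicates),
                 glucose_loq = glucose_loq, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthesize a noisy measurement table from simulated scenarios
#'
#' Emulates the experimental sampling design: duplicate samples at the
#' scheduled times (already encoded in the scenario rows), independently for
#' each culture, with multiplicative lognormal noise. Independent cultures
#' are passed as multiple `scenario_result` objects (typically re-simulated
#' with jittered initial biomass); their replicate draws are pooled per
#' (regime, time, metabolite).
#'
#' @param results A `scenario_result` or list of them (one per culture).
#' @param noise A [noise_model()].
#' @return A `measurement_table` data frame: `regime`, `time_h`,
#'   `temperature_C`, `glucose_mM`, `metabolite`, `level`, `sem`, `n`,
#'   `stratum`. Fully reproducible from `noise$seed`.
#' @export
synthesize_measurements <- function(results, noise = noise_model()) {
  if (inherits(results, "data.frame")) results <- list(results)
  sdlog <- sqrt(log(1 + noise$cv^2))
  meanlog <- -sdlog^2 / 2 # lognormal mean exactly 1
  set.seed(noise$seed)
  per_culture <- lapply(seq_along(results), function(ci) {
    r <- results[[ci]]
    if (is.null(r$sample_id)) r$sample_id <- paste0("t", r$time_h)
    k <- noise$replicates
    draws <- matrix(stats::rlnorm(nrow(r) * k, meanlog, sdlog), ncol = k)
    g_draws <- matrix(stats::rlnorm(nrow(r) * k, meanlog, sdlog), ncol = k)
    lv <- r$level * draws
    gl <- r$glucose_mM * g_draws
    gl[gl < noise$glucose_loq] <- noise$glucose_loq / 2
    data.frame(regime = r$regime, sample_id = r$sample_id, time_h = r$time_h,
               temperature_C = r$temperature_C,
               glucose_raw = rowMeans(gl),
               metabolite = r$metabolite,
               level_mean = rowMeans(lv),
               level_var = if (k > 1) apply(lv, 1, stats::var) else 0,
               n = k, stratum = r$stratum, culture = ci,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_culture)
  key <- interaction(all$regime, all$sample_id, all$metabolite, drop = TRUE)
  agg <- lapply(split(all, key), function(d) {
    n_tot <- sum(d$n)
    m <- sum(d$level_mean * d$n) / n_tot
    # pooled variance across cultures and replicates
    if (n_tot > 1) {
      ss <- sum((d$n - 1) * d$level_var) +
        sum(d$n * (d$level_mean - m)^2)
      sem <- sqrt(ss / (n_tot - 1) / n_tot)
    } else sem <- 0
    data.frame(regime = d$regime[1], time_h = mean(d$time_h),
               temperature_C = mean(d$temperature_C),
               glucose_mM = mean(d$glucose_raw),
               metabolite = d$metabolite[1],
               level = m, sem = sem, n = n_tot, stratum = d$stratum[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$regime, out$time_h, out$metabolite), ]
  rownames(out) <- NULL
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Simulate independent cultures and synthesize their measurements
#'
#' Convenience wrapper: re-simulates the scenario once per culture with the
#' initial batch biomass jittered by up to +/- 5 % (drawn from the seed) and
#' pools the noisy measurements.
#'
#' @param model A `network_model`.
#' @param spec A [scenario_spec()].
#' @param thermo A [thermo_spec()].
#' @param noise A [noise_model()].
#' @param independent_runs Number of cultures (default 2).
#' @return A `measurement_table`.
#' @export
synthesize_dataset <- function(model, spec, thermo = thermo_spec(),
                               noise = noise_model(), independent_runs = 2L) {
  set.seed(noise$seed)
  jit <- 1 + stats::runif(independent_runs, -0.05, 0.05)
  results <- lapply(jit, function(j)
    run_scenario(model, spec, thermo, x0_jitter = j))
  synthesize_measurements(results, noise)
}

#' Deterministic fixtures for the collapse analysis
#'
#' Small tables with known ground truth:
#' * `collapsed`: two regimes whose points lie exactly on one increasing
#'   curve of glucose (all collapse scores 0);
#' * `offset_regime`: regime B is the regime-A curve multiplied by 1.5
#'   (regime B flagged at the default threshold);
#' * `deviant_enzyme_pattern`: a glucose-excess table where all metabolites
#'   upstream of TDHL lose half their level at 12 degC relative to 30 degC
#'   while downstream ones stay flat (localizes to TDHL).
#'
#' @param case Fixture name.
#' @param seed Seed for the mild jitter in glucose placement.
#' @return A `measurement_table`-shaped data frame (noise-free; `sem = 0`).
#' @export
make_fixture <- function(case = c("collapsed", "offset_regime",
                                  "deviant_enzyme_pattern"),
                         seed = 1L) {
  case <- match.arg(case)
  set.seed(seed)
  curve <- function(s) 2 * s / (1 + s) # saturating reference relation
  if (case %in% c("collapsed", "offset_regime")) {
    # regime A contributes two points per glucose level, regime B one, so the
    # pooled isotonic curve sits at (2 g + mult g)/3 per level and only the
    # offset regime exceeds the default threshold
    s_grid <- 10^seq(-1, 1, length.out = 10)
    mult <- c(A = 1, B = if (case == "offset_regime") 1.5 else 1)
    rows <- do.call(rbind, lapply(c("A", "A", "B"), function(q)
      data.frame(regime = q, time_h = seq_along(s_grid),
                 temperature_C = if (q == "A") seq(12, 30, length.out = 10)
                                 else seq(30, 12, length.out = 10),
                 glucose_mM = s_grid,
                 metabolite = "M1", level = mult[[q]] * curve(s_grid),
                 sem = 0, n = 2, stratum = "limited",
                 stringsAsFactors = FALSE)))
    rownames(rows) <- NULL
    class(rows) <- c("measurement_table", "data.frame")
    return(rows)
  }
  mets <- c("G6P", "F6P", "FBP", "TRIO", "PEP", "PYR")
  base <- c(G6P = 4.9, F6P = 0.87, FBP = 2.4, TRIO = 1.1, PEP = 1.6,
            PYR = 2.7)
  upstream <- c("G6P", "F6P", "FBP", "TRIO")
  temps <- c(12, 18, 24, 30)
  rows <- do.call(rbind, lapply(temps, function(T) {
    fac <- ifelse(mets %in% upstream, ((T + 0.42) / 30.42)^0.5, 1)
    data.frame(regime = "SBR", time_h = 1, temperature_C = T,
               glucose_mM = 100, metabolite = mets,
               level = base[mets] * fac, sem = 0, n = 2,
               stratum = "excess", stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("measurement_table", "data.frame")
  rows
}

#' Synthetic null tables for permutation-test calibration
#'
#' Levels depend on glucose through a fixed curve with multiplicative noise;
#' temperature is assigned independently of the residuals, so the
#' residual-temperature association is null by construction.
#'
#' @param seed Integer seed.
#' @param n Number of rows.
#' @param cv Noise coefficient of variation.
#' @return Data frame with `regime`, `temperature_C`, `glucose_mM`, `level`.
#' @export
make_null_table <- function(seed, n = 24L, cv = 0.1) {
  set.seed(seed)
  glc <- 10^stats::runif(n, -1, 1)
  sdlog <- sqrt(log(1 + cv^2))
  lv <- (2 * glc / (1 + glc)) * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  data.frame(regime = rep(c("A", "B"), length.out = n),
             temperature_C = sample(seq(12, 30, length.out = n)),
             glucose_mM = glc, level = lv, stringsAsFactors = FALSE)
}
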