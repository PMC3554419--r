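#' Scenario specification
#'
#' One simulated cultivation regime under one temperature-sensitivity
#' hypothesis. Regimes:
#' * `SBR`: glucose-excess batches at `batch_temperatures`, sampled at three
#'   exponential-phase points (glucose at 80/55/30 % of the initial level);
#' * `LTS30` / `LTS12`: glucose-limited chemostat at steady state (30 or
#'   12 degC), then a 3-h linear down-and-back temperature shift at
#'   0.2 degC/min, sampled at the 30/24/18/12 degC crossings and 1, 2 and 3 h
#'   after the return;
#' * `CTC`: chemostat under the circadian sinoid 21 + 9 sin(pi/12 t + 1.57),
#'   sampled every 3 h during cycles 5 and 6 (after 4 adaptation cycles).
#'
#' @param regime One of `"SBR"`, `"LTS30"`, `"LTS12"`, `"CTC"`.
#' @param hypothesis `"identical"` (all enzymes share the temperature scale)
#'   or `"single_enzyme_different"`.
#' @param sensitivity A [sensitivity_spec()]; required for
#'   `single_enzyme_different` (default: TDHL, factor 2).
#' @param batch_temperatures Batch temperatures (degC) for SBR.
#' @param sample_fractions Glucose fractions of the initial batch level at
#'   which SBR samples are taken.
#' @param ctc_cycles_before_sampling Adaptation cycles before sampling starts.
#' @param ctc_sampling_interval Hours between CTC samples (>= 3).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(regime = c("SBR", "LTS30", "LTS12", "CTC"),
                          hypothesis = c("identical",
                                         "single_enzyme_different"),
                          sensitivity = sensitivity_spec("TDHL", 2),
                          batch_temperatures = c(12, 18, 24, 30),
                          sample_fractions = c(0.8, 0.55, 0.3),
                          ctc_cycles_before_sampling = 4,
                          ctc_sampling_interval = 3) {
  regime <- match.arg(regime)
  hypothesis <- match.arg(hypothesis)
  structure(list(regime = regime, hypothesis = hypothesis,
                 sensitivity = sensitivity,
                 batch_temperatures = batch_temperatures,
                 sample_fractions = sample_fractions,
                 ctc_cycles_before_sampling = ctc_cycles_before_sampling,
                 ctc_sampling_interval = ctc_sampling_interval),
            class = "scenario_spec")
}

scenario_thermo <- function(spec, thermo) {
  if (spec$hypothesis == "single_enzyme_different")
    thermo$sensitivity <- spec$sensitivity
  else
    thermo$sensitivity <- NULL
  thermo
}

#' Glucose-excess reference levels at 30 degC
#'
#' The normalization reference of the scenario tables: the intracellular
#' steady state with extracellular glucose clamped at the feed concentration
#' at the reference temperature.
#'
#' @param model A `network_model`.
#' @param thermo A [thermo_spec()].
#' @param config A [reactor_config()].
#' @param T Reference temperature (degC), default 30.
#' @return Named numeric vector of intracellular levels (mM).
#' @export
reference_levels <- function(model, thermo = thermo_spec(),
                             config = reactor_config("batch"), T = 30) {
  tf <- thermo_functions(model, thermo)
  ext <- species_ids(model, "extracellular")
  clamp <- stats::setNames(rep(0, length(ext)), ext)
  clamp[config$glucose_id] <- config$feed_concentrations[[config$glucose_id]]
  ss <- solve_steady_state(model, clamp, scales = tf$scales(T),
                           keq = tf$keq(T), sink = reactor_sink(config))
  ss$concentrations[species_ids(model, "intracellular")]
}

#' Run one simulation scenario
#'
#' Simulates the regime of `spec` under its hypothesis and samples the
#' trajectory on the regime's schedule, yielding a tidy table of metabolite
#' levels versus extracellular glucose with levels also normalized to the
#' glucose-excess 30 degC reference.
#'
#' @param model A `network_model`.
#' @param spec A [scenario_spec()].
#' @param thermo A [thermo_spec()]; its `sensitivity` is overridden by the
#'   scenario hypothesis.
#' @param config A [reactor_config()]; the mode is set by the regime.
#' @param x0_jitter Multiplicative jitter on the initial batch biomass
#'   (emulates independent cultures; default 1 = none).
#' @return A `scenario_result` data frame: `regime`, `time_h`,
#'   `temperature_C`, `glucose_mM`, `metabolite`, `level`, `level_norm`,
#'   `stratum`. The reference levels are attached as attribute `reference`.
#' @export
run_scenario <- function(model, spec, thermo = thermo_spec(),
                         config = NULL, x0_jitter = 1) {
  thermo <- scenario_thermo(spec, thermo)
  mets <- setdiff(species_ids(model, "intracellular"), "GLCi")
  ref <- reference_levels(model, thermo,
                          config = reactor_config("batch"), T = 30)
  rows <- switch(spec$regime,
    SBR = run_sbr(model, spec, thermo, config, mets, x0_jitter),
    LTS30 = run_lts(model, spec, thermo, config, mets, start_T = 30),
    LTS12 = run_lts(model, spec, thermo, config, mets, start_T = 12),
    CTC = run_ctc(model, spec, thermo, config, mets))
  rows$level_norm <- rows$level / ref[rows$metabolite]
  rownames(rows) <- NULL
  attr(rows, "reference") <- ref
  attr(rows, "hypothesis") <- spec$hypothesis
  class(rows) <- c("scenario_result", "data.frame")
  rows
}

sample_rows <- function(traj, times, regime, mets, stratum, block = "") {
  cols <- c("temperature_C", "GLCo", mets)
  sampled <- lapply(cols, function(cl)
    stats::approx(traj$time_h, traj[[cl]], xout = times, rule = 2)$y)
  names(sampled) <- cols
  # schedule slot id: lets independent cultures (whose fraction crossings fall
  # at slightly different clock times) be pooled per scheduled sample
  sid <- paste0(regime, if (nzchar(block)) paste0("_", block), "_",
                seq_along(times))
  long <- do.call(rbind, lapply(seq_along(mets), function(i)
    data.frame(regime = regime, sample_id = sid, time_h = times,
               temperature_C = sampled$temperature_C,
               glucose_mM = sampled$GLCo,
               metabolite = mets[i],
               level = sampled[[mets[i]]],
               stratum = stratum, stringsAsFactors = FALSE)))
  long
}

run_sbr <- function(model, spec, thermo, config, mets, x0_jitter = 1) {
  if (is.null(config) || config$mode != "batch")
    config <- reactor_config("batch")
  config$x0 <- config$x0 * x0_jitter
  glc0 <- config$feed_concentrations[[config$glucose_id]]
  out <- list()
  for (T in spec$batch_temperatures) {
    # horizon from the exponential-growth time to consume the charge
    tf <- thermo_functions(model, thermo)
    horizon <- batch_horizon(model, config, T, tf)
    traj <- run_reactor(model, config, temperature_profile("constant",
                                                           constant = T),
                        thermo, t_span = c(0, horizon),
                        t_eval = seq(0, horizon, length.out = 600L))
    targets <- glc0 * spec$sample_fractions
    # glucose decreases monotonically in batch; invert the time course
    times <- stats::approx(rev(traj$GLCo), rev(traj$time_h), xout = targets,
                           ties = "ordered")$y
    if (any(is.na(times)))
      stop("SBR sampling: batch at ", T,
           " degC did not reach the scheduled glucose fractions")
    out[[length(out) + 1L]] <- sample_rows(traj, sort(times), "SBR", mets,
                                           "excess", block = paste0("T", T))
  }
  do.call(rbind, out)
}

# conservative horizon for a batch to pass below 30% glucose: exponential
# growth at mu(T) from x0 consuming the charge, plus margin
batch_horizon <- function(model, config, T, tf) {
  # crude specific rate estimate from the excess steady state at T
  ext <- species_ids(model, "extracellular")
  clamp <- stats::setNames(rep(0, length(ext)), ext)
  clamp[config$glucose_id] <- config$feed_concentrations[[config$glucose_id]]
  ss <- solve_steady_state(model, clamp, scales = tf$scales(T),
                           keq = tf$keq(T), sink = reactor_sink(config))
  v <- ss$fluxes[[config$uptake_reaction]]
  qs <- 0.06 * config$cytosol_volume_factor * v # mmol/gDW/h
  mu <- config$yield_x_s * qs * config$glucose_mw / 1000
  glc0 <- config$feed_concentrations[[config$glucose_id]]
  t_deplete <- log(1 + mu * glc0 * 0.75 / (qs * config$x0)) / mu
  1.6 * t_deplete + 2
}

run_lts <- function(model, spec, thermo, config, mets, start_T) {
  if (is.null(config) || config$mode != "chemostat")
    config <- reactor_config("chemostat")
  target_T <- if (start_T == 30) 12 else 30
  profile <- temperature_profile("linear_shift", start_T = start_T,
                                 target_T = target_T, ramp_rate = 0.2)
  dur <- shift_duration(profile) # h
  leg <- dur / 2
  horizon <- dur + 3
  # crossings of 30/24/18/12 degC on both legs, plus 1,2,3 h after return
  marks <- c(30, 24, 18, 12)
  down <- abs(marks - start_T) / (profile$ramp_rate * 60)
  up <- dur - down
  times <- sort(unique(c(down, up, dur + 1:3)))
  traj <- run_reactor(model, config, profile, thermo,
                      t_span = c(0, horizon),
                      t_eval = sort(unique(c(seq(0, horizon, by = 0.02),
                                             times))))
  regime <- paste0("LTS", start_T)
  sample_rows(traj, times, regime, mets, "limited")
}

run_ctc <- function(model, spec, thermo, config, mets) {
  if (is.null(config) || config$mode != "chemostat")
    config <- reactor_config("chemostat")
  profile <- temperature_profile("sinoid")
  period <- 2 * pi / profile$angular_frequency
  t_start <- spec$ctc_cycles_before_sampling * period
  t_end <- t_start + 2 * period
  times <- seq(t_start, t_end, by = spec$ctc_sampling_interval)
  traj <- run_reactor(model, config, profile, thermo,
                      t_span = c(0, t_end),
                      t_eval = sort(unique(c(seq(0, t_end, by = 0.25),
                                             times))))
  sample_rows(traj, times, "CTC", mets, "limited")
}

#' Run both simulation rounds across all regimes
#'
#' Round 1 perturbs one enzyme (`single_enzyme_different`); round 2 uses
#' identical sensitivities. Regimes SBR, LTS30 and CTC mirror the simulated
#' study design (LTS12 can be added).
#'
#' @param model A `network_model`.
#' @param hypothesis `"identical"` or `"single_enzyme_different"`.
#' @param sensitivity A [sensitivity_spec()] for round 1.
#' @param regimes Regimes to include.
#' @param thermo A [thermo_spec()].
#' @return Combined `scenario_result` data frame over all regimes.
#' @export
run_round <- function(model, hypothesis,
                      sensitivity = sensitivity_spec("TDHL", 2),
                      regimes = c("SBR", "LTS30", "CTC"),
                      thermo = thermo_spec()) {
  out <- lapply(regimes, function(rg)
    run_scenario(model, scenario_spec(rg, hypothesis, sensitivity), thermo))
  res <- do.call(rbind, out)
  attr(res, "reference") <- attr(out[[1]], "reference")
  attr(res, "hypothesis") <- hypothesis
  class(res) <- c("scenario_result", "data.frame")
  res
}

#' Relative flux sensitivity to temperature
#'
#' Central-difference sensitivity of the glucose-excess steady-state pathway
#' flux to temperature, `(dJ/dT)/J`, at temperature `T`. When all enzymes
#' share the Ratkowsky scale `R(T)` this equals `d log R / dT =
#' 2 / (T - t_min)` exactly, since the flux is proportional to `R(T)` while
#' metabolite levels stay put.
#'
#' @param model A `network_model`.
#' @param thermo A [thermo_spec()].
#' @param T Temperature (degC).
#' @param dT Half-width of the central difference (degC).
#' @param glucose Clamped glucose (mM); default the standard feed level.
#' @return Relative sensitivity (1/degC).
#' @export
flux_temperature_sensitivity <- function(model, thermo = thermo_spec(),
                                         T, dT = 0.1,
                                         glucose = 25 / 180.16 * 1000) {
  tf <- thermo_functions(model, thermo)
  ext <- species_ids(model, "extracellular")
  clamp <- stats::setNames(rep(0, length(ext)), ext)
  clamp[["GLCo"]] <- glucose
  flux_at <- function(Ti) {
    ss <- solve_steady_state(model, clamp, scales = tf$scales(Ti),
                             keq = tf$keq(Ti))
    ss$fluxes[[1]]
  }
  j0 <- flux_at(T)
  (flux_at(T + dT) - flux_at(T - dT)) / (2 * dT) / j0
}
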