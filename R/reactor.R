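#' Bioreactor configuration
#'
#' Mass balances follow
#' `dN_i/dt = q_i N_X(t) + F_in C_i_in - F_out C_i_out(t)` for every
#' extracellular species, with a first-order evaporation loss for ethanol.
#' Biomass follows `dN_X/dt = (mu - D) N_X` with `mu = yield_x_s * q_s` in
#' gram units. Intracellular rates (mM/min per cytosol volume) convert to
#' biomass-specific rates via the cytosol volume factor:
#' `q_i [mmol/gDW/h] = 0.06 * cytosol_volume_factor * v_i [mM/min]`.
#'
#' A fraction of the glucose uptake is drained at G6P into biomass precursors
#' so that the carbon routed to biomass exactly matches `yield_x_s` with the
#' composition `CH1.8O0.5N0.2` (`biomass_c_mw` g per C-mol); with that drain
#' the carbon balance over a closed batch closes identically.
#'
#' @param mode `"chemostat"` or `"batch"`. Chemostat has `f_in = f_out =
#'   dilution_rate * volume`; batch has no flow.
#' @param volume Working volume (L).
#' @param dilution_rate D (1/h), chemostat only.
#' @param feed_concentrations Named mM vector for extracellular species in the
#'   feed; default glucose 25 g/L = 138.76 mM.
#' @param yield_x_s Biomass yield on glucose (gDW per g glucose).
#' @param cytosol_volume_factor mL cytosol per gDW.
#' @param evaporation_k First-order ethanol evaporation constant (1/h); set 0
#'   to disable (as in carbon-balance audits).
#' @param biomass_c_mw g biomass per C-mol (CH1.8O0.5N0.2).
#' @param glucose_mw Molar mass of glucose (g/mol).
#' @param x0 Initial biomass for batch runs (gDW/L).
#' @param glucose_id,ethanol_id Species ids of glucose and ethanol.
#' @param uptake_reaction Reaction id of the glucose uptake step.
#' @return A `reactor_config` object.
#' @export
reactor_config <- function(mode = c("chemostat", "batch"),
                           volume = 1.0,
                           dilution_rate = 0.03,
                           feed_concentrations = c(GLCo = 25 / 180.16 * 1000),
                           yield_x_s = 0.09,
                           cytosol_volume_factor = 2.0,
                           evaporation_k = 0.008,
                           biomass_c_mw = 24.6,
                           glucose_mw = 180.16,
                           x0 = 0.15,
                           glucose_id = "GLCo",
                           ethanol_id = "ETOH",
                           uptake_reaction = "GLT") {
  mode <- match.arg(mode)
  stopifnot(volume > 0, dilution_rate >= 0, yield_x_s > 0,
            cytosol_volume_factor > 0, evaporation_k >= 0)
  f <- if (mode == "chemostat") dilution_rate * volume else 0
  structure(list(mode = mode, volume = volume,
                 dilution_rate = if (mode == "chemostat") dilution_rate else 0,
                 f_in = f, f_out = f,
                 feed_concentrations = feed_concentrations,
                 yield_x_s = yield_x_s,
                 cytosol_volume_factor = cytosol_volume_factor,
                 evaporation_k = evaporation_k,
                 biomass_c_mw = biomass_c_mw,
                 glucose_mw = glucose_mw,
                 x0 = x0,
                 glucose_id = glucose_id, ethanol_id = ethanol_id,
                 uptake_reaction = uptake_reaction),
            class = "reactor_config")
}

#' Thermal specification for a run
#'
#' Bundles the Ratkowsky parameters, optional per-enzyme sensitivity
#' perturbations and the (off by default) Van't Hoff propagation of
#' equilibrium constants.
#'
#' @param ratkowsky A [ratkowsky_params()] object.
#' @param sensitivity A [sensitivity_spec()], list of them, or `NULL`.
#' @param vant_hoff Logical; when `TRUE`, reversible reactions whose id
#'   appears in [keq_table()] get temperature-corrected Keq.
#' @return A `thermo_spec` object.
#' @export
thermo_spec <- function(ratkowsky = ratkowsky_params(), sensitivity = NULL,
                        vant_hoff = FALSE) {
  structure(list(ratkowsky = ratkowsky, sensitivity = sensitivity,
                 vant_hoff = vant_hoff),
            class = "thermo_spec")
}

# per-reaction scale functions and Keq(T) function for a model
thermo_functions <- function(model, thermo) {
  rx <- names(model$reactions)
  scale_fns <- apply_sensitivity(thermo$ratkowsky, thermo$sensitivity, rx)
  keq_fn <- function(T) NULL
  if (isTRUE(thermo$vant_hoff)) {
    vh <- keq_params_from_table(t_ref = 30)
    rev_ids <- rx[vapply(model$reactions, function(r)
      r$rate_law$kind == "reversible_mm" && r$id %in% names(vh), logical(1))]
    if (length(rev_ids)) {
      base <- vapply(rev_ids, function(id)
        model$reactions[[id]]$rate_law$keq_ref, numeric(1))
      keq_fn <- function(T) {
        Tk <- celsius_to_kelvin(T)
        vapply(rev_ids, function(id)
          base[[id]] * keq_at_temperature(vh[[id]], Tk) / vh[[id]]$keq_ref,
          numeric(1))
      }
    }
  }
  list(scales = function(T) scales_at_temperature(scale_fns, T),
       keq = keq_fn, scale_fns = scale_fns)
}

# fraction of glucose uptake drained to biomass precursors at G6P
anabolic_fraction <- function(config) {
  config$yield_x_s * config$glucose_mw / (6 * config$biomass_c_mw)
}

#' Anabolic drain as a steady-state sink
#'
#' The biomass-precursor drain applied at G6P, proportional to the glucose
#' uptake flux, in the form accepted by [solve_steady_state()]'s `sink`
#' argument. Using it makes algebraic steady states consistent with
#' [run_reactor()] dynamics.
#'
#' @param config A [reactor_config()].
#' @return Function `f(v) -> c(G6P = mM/min)`.
#' @export
reactor_sink <- function(config) {
  f_c <- anabolic_fraction(config)
  uptake <- config$uptake_reaction
  function(v) c(G6P = f_c * v[[uptake]])
}

#' Reactor state time-derivative
#'
#' The right-hand side of the bioreactor ODE system at a given time and
#' temperature. States are a named vector: intracellular concentrations (mM),
#' extracellular amounts `n_<id>` (mmol), biomass `n_X` (gDW), cumulative
#' off-gas `n_CO2cum` (mmol).
#'
#' @param state Named state vector.
#' @param t Time (h).
#' @param model A `network_model`.
#' @param scales Named per-reaction scale vector (already evaluated at the
#'   current temperature).
#' @param config A [reactor_config()].
#' @param keq Optional per-reaction Keq override.
#' @return List: `derivative` (named, same layout as `state`), `rates` (v,
#'   mM/min), `q` (biomass-specific rates, mmol/gDW/h), `mu` (1/h).
#' @export
reactor_derivative <- function(state, t, model, scales, config, keq = NULL) {
  if (any(state < -1e-8))
    stop_domain("reactor_derivative: negative state")
  V <- config$volume
  intr <- species_ids(model, "intracellular")
  ext <- species_ids(model, "extracellular")
  conc <- stats::setNames(numeric(length(model$species)),
                          names(model$species))
  conc[intr] <- pmax(state[intr], 0)
  conc[ext] <- pmax(state[paste0("n_", ext)], 0) / V
  n_x <- max(state[["n_X"]], 0)

  v <- network_rates(model, conc, scales, keq)
  N <- stoichiometric_matrix(model)
  kq <- 0.06 * config$cytosol_volume_factor # mmol/gDW/h per mM/min
  q_ext <- kq * drop(N[ext, , drop = FALSE] %*% v)
  names(q_ext) <- ext

  q_glc <- -q_ext[[config$glucose_id]] # consumption, mmol/gDW/h
  mu <- config$yield_x_s * q_glc * config$glucose_mw / 1000
  v_ana <- anabolic_fraction(config) * v[[config$uptake_reaction]]

  dn_ext <- q_ext * n_x + config$f_in *
    feed_of(config, ext) - config$f_out * conc[ext]
  dn_ext[[config$ethanol_id]] <- dn_ext[[config$ethanol_id]] -
    config$evaporation_k * state[[paste0("n_", config$ethanol_id)]]
  if ("CO2" %in% ext) dn_ext[["CO2"]] <- 0 # vented; tracked in n_CO2cum

  dc_intr <- 60 * drop(N[intr, , drop = FALSE] %*% v)
  names(dc_intr) <- intr
  if ("G6P" %in% intr) dc_intr[["G6P"]] <- dc_intr[["G6P"]] - 60 * v_ana

  D <- config$dilution_rate
  deriv <- c(dc_intr,
             stats::setNames(dn_ext, paste0("n_", ext)),
             n_X = (mu - D) * n_x,
             n_CO2cum = if ("CO2" %in% ext) q_ext[["CO2"]] * n_x else 0)
  list(derivative = deriv[names(state)], rates = v,
       q = c(q_ext, glc_consumed = q_glc), mu = mu)
}

feed_of <- function(config, ext) {
  out <- stats::setNames(numeric(length(ext)), ext)
  common <- intersect(names(config$feed_concentrations), ext)
  out[common] <- config$feed_concentrations[common]
  out
}

#' Chemostat steady state at constant temperature
#'
#' At steady state `mu = D`, which pins the biomass-specific glucose uptake
#' `q_s = D / (Y_xs * Mw)` and hence the intracellular uptake flux. The
#' residual glucose concentration is found by a 1-D root search over the
#' clamped substrate, and biomass follows from the glucose balance.
#'
#' @param model A `network_model`.
#' @param config A [reactor_config()] in chemostat mode.
#' @param T Temperature (degC).
#' @param thermo A [thermo_spec()].
#' @return List: `state` (named reactor state vector), `steady`
#'   (the intracellular `steady_state`), `glucose_mM`, `biomass_gdw_l`,
#'   `mu`, `flux_target`.
#' @export
chemostat_steady_state <- function(model, config, T, thermo = thermo_spec()) {
  stopifnot(config$mode == "chemostat")
  tf <- thermo_functions(model, thermo)
  scales <- tf$scales(T)
  keq <- tf$keq(T)
  D <- config$dilution_rate
  kq <- 0.06 * config$cytosol_volume_factor
  q_target <- D / (config$yield_x_s * config$glucose_mw / 1000) # mmol/gDW/h
  v_target <- q_target / kq                                     # mM/min
  feed <- config$feed_concentrations[[config$glucose_id]]

  ext <- species_ids(model, "extracellular")
  other <- stats::setNames(rep(0, length(ext)), ext)
  ss <- tryCatch(
    steady_state_at_flux(model, v_target,
                         substrate_id = config$glucose_id,
                         flux_reaction = config$uptake_reaction,
                         scales = scales, keq = keq,
                         interval = c(1e-8, feed * 0.999),
                         other_clamped = other[setdiff(ext, config$glucose_id)],
                         sink = reactor_sink(config)),
    error = function(e)
      stop("chemostat infeasible at T = ", T, " degC (washout?): ",
           conditionMessage(e), call. = FALSE))
  glc <- attr(ss, "substrate")
  c_x <- D * (feed - glc) / q_target # gDW/L
  n_x <- c_x * config$volume

  q_ext <- kq * drop(stoichiometric_matrix(model)[ext, , drop = FALSE] %*%
                       ss$fluxes)
  names(q_ext) <- ext
  n_ext <- stats::setNames(numeric(length(ext)), paste0("n_", ext))
  n_ext[paste0("n_", config$glucose_id)] <- glc * config$volume
  eth <- config$ethanol_id
  n_ext[paste0("n_", eth)] <- q_ext[[eth]] * n_x /
    (D + config$evaporation_k) # F C = q Nx - k N
  others <- setdiff(ext, c(config$glucose_id, eth, "CO2"))
  for (s in others)
    n_ext[paste0("n_", s)] <- q_ext[[s]] * n_x / D * ifelse(D > 0, 1, 0)
  if ("CO2" %in% ext) n_ext["n_CO2"] <- 0

  intr <- species_ids(model, "intracellular")
  state <- c(ss$concentrations[intr], n_ext, n_X = n_x, n_CO2cum = 0)
  list(state = state, steady = ss, glucose_mM = glc, biomass_gdw_l = c_x,
       mu = D, flux_target = v_target)
}

#' Run a bioreactor simulation under a temperature profile
#'
#' Integrates the coupled intracellular/extracellular system with a
#' stiff-capable integrator (rtol 1e-8, atol 1e-10). Chemostat runs start
#' from the constant-temperature steady state at the profile's initial
#' temperature; batch runs start at the feed glucose concentration with
#' intracellular pools equilibrated to glucose excess and biomass
#' `config$x0`.
#'
#' @param model A `network_model`.
#' @param config A [reactor_config()].
#' @param profile A [temperature_profile()].
#' @param thermo A [thermo_spec()].
#' @param t_span Length-2 numeric (h).
#' @param t_eval Output grid (h); default 400 points.
#' @param init Optional named initial state (as in [reactor_derivative()]).
#' @return A data frame of class `reactor_trajectory`: `time_h`,
#'   `temperature_C`, extracellular concentrations (mM), intracellular
#'   concentrations (mM), `biomass_gdw_l`, biomass-specific rates
#'   `q_<id>` (mmol/gDW/h, positive = production) and `q_glc` (consumption),
#'   `mu` (1/h), `co2_mmol_per_h`. Attribute `washout` flags persistent
#'   `mu < D`.
#' @export
run_reactor <- function(model, config, profile, thermo = thermo_spec(),
                        t_span, t_eval = NULL, init = NULL) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(t_eval))
    t_eval <- seq(t_span[1], t_span[2], length.out = 400L)
  tf <- thermo_functions(model, thermo)
  T0 <- profile_temperature(profile, t_span[1])

  if (is.null(init)) {
    init <- if (config$mode == "chemostat") {
      chemostat_steady_state(model, config, T0, thermo)$state
    } else {
      batch_initial_state(model, config, T0, tf)
    }
  }

  intr <- species_ids(model, "intracellular")
  ext <- species_ids(model, "extracellular")
  rhs <- function(t, y, parms) {
    T <- profile_temperature(profile, t)
    d <- reactor_derivative(stats::setNames(pmax(y, 0), names(init)), t,
                            model, tf$scales(T), config, tf$keq(T))
    list(d$derivative)
  }
  times <- unique(c(t_span[1], t_eval))
  if (config$mode == "batch") {
    # batch runs end when glucose is depleted (numerically stiff beyond)
    i_glc <- match(paste0("n_", config$glucose_id), names(init))
    rootfun <- function(t, y, parms)
      y[i_glc] / config$volume - glucose_floor
    glucose_floor <- 0.02 # mM
    out <- deSolve::lsoda(init, times, rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000,
                          rootfunc = rootfun,
                          events = list(root = TRUE, terminalroot = 1))
    if (is.null(attr(out, "troot")) || !length(attr(out, "troot")))
      check_integration(out, times)
  } else {
    out <- deSolve::lsoda(init, times, rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
    check_integration(out, times)
  }
  out <- out[out[, 1] %in% t_eval, , drop = FALSE]

  # annotate rows
  n <- nrow(out)
  temp <- profile_temperature(profile, out[, 1])
  q_cols <- NULL
  mu <- numeric(n)
  for (i in seq_len(n)) {
    st <- stats::setNames(pmax(out[i, -1], 0), names(init))
    d <- reactor_derivative(st, out[i, 1], model, tf$scales(temp[i]), config,
                            tf$keq(temp[i]))
    if (is.null(q_cols))
      q_cols <- matrix(0, n, length(d$q), dimnames = list(NULL,
                       paste0("q_", names(d$q))))
    q_cols[i, ] <- d$q
    mu[i] <- d$mu
  }
  ext_conc <- out[, paste0("n_", ext), drop = FALSE] / config$volume
  colnames(ext_conc) <- ext
  biomass <- out[, "n_X"] / config$volume
  traj <- data.frame(time_h = out[, 1], temperature_C = temp,
                     ext_conc, out[, intr, drop = FALSE],
                     biomass_gdw_l = biomass, q_cols, mu = mu,
                     co2_mmol_per_h = q_cols[, "q_CO2"] * out[, "n_X"],
                     co2_cum_mmol = out[, "n_CO2cum"],
                     check.names = FALSE)
  class(traj) <- c("reactor_trajectory", "data.frame")
  D <- config$dilution_rate
  attr(traj, "washout") <- config$mode == "chemostat" &&
    biomass[n] < 0.5 * biomass[1] && mu[n] < D
  attr(traj, "config") <- config
  traj
}

batch_initial_state <- function(model, config, T0, tf) {
  ext <- species_ids(model, "extracellular")
  intr <- species_ids(model, "intracellular")
  glc0 <- config$feed_concentrations[[config$glucose_id]]
  clamp <- stats::setNames(rep(0, length(ext)), ext)
  clamp[config$glucose_id] <- glc0
  ss <- solve_steady_state(model, clamp, scales = tf$scales(T0),
                           keq = tf$keq(T0), sink = reactor_sink(config))
  n_ext <- stats::setNames(rep(0, length(ext)), paste0("n_", ext))
  n_ext[paste0("n_", config$glucose_id)] <- glc0 * config$volume
  c(ss$concentrations[intr], n_ext, n_X = config$x0 * config$volume,
    n_CO2cum = 0)
}

#' CO2 off-gas rate of trajectory points
#'
#' In anaerobic cultures the CO2 production rate tracks the glycolytic flux;
#' it is the decarboxylation flux converted to broth scale:
#' `q_CO2 * N_X` (mmol/h).
#'
#' @param traj A `reactor_trajectory`.
#' @return Numeric vector (mmol/h), one per row.
#' @export
co2_offgas_rate <- function(traj) {
  stopifnot(inherits(traj, "reactor_trajectory"))
  traj$co2_mmol_per_h
}

#' Carbon balance audit of a closed batch run
#'
#' Compares carbon leaving the glucose pool with carbon accumulated in
#' ethanol, glycerol, off-gas CO2 and biomass (at composition CH1.8O0.5N0.2)
#' between the first and last rows of a batch trajectory. Run with
#' `evaporation_k = 0`.
#'
#' @param traj A `reactor_trajectory` from a batch run.
#' @param config The [reactor_config()] used (defaults to the one attached to
#'   the trajectory).
#' @return List with `carbon_in`, `carbon_out` (mC-mol) and `relative_gap`.
#' @export
carbon_balance <- function(traj, config = attr(traj, "config")) {
  V <- config$volume
  first <- traj[1, ]; last <- traj[nrow(traj), ]
  d_glc <- (first[[config$glucose_id]] - last[[config$glucose_id]]) * V # mmol
  carbon_in <- 6 * d_glc
  d_eth <- (last[[config$ethanol_id]] - first[[config$ethanol_id]]) * V
  d_gly <- if ("GLYC" %in% names(traj))
    (last[["GLYC"]] - first[["GLYC"]]) * V else 0
  d_co2 <- last$co2_cum_mmol - first$co2_cum_mmol
  d_x <- (last$biomass_gdw_l - first$biomass_gdw_l) * V # gDW
  carbon_out <- 2 * d_eth + 3 * d_gly + d_co2 +
    d_x / config$biomass_c_mw * 1000
  list(carbon_in = carbon_in, carbon_out = carbon_out,
       relative_gap = abs(carbon_out - carbon_in) / carbon_in)
}
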