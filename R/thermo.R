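#' Ratkowsky temperature-scaling parameters
#'
#' Enzyme capacities follow the square-root-type law
#' `Vmax_j(T) = b_j * (T - t_min)^2` below the optimum. Normalized to the
#' reference temperature this gives the dimensionless scale
#' `R(T) = ((T - t_min)/(t_ref - t_min))^2` shared by all enzymes under the
#' identical-sensitivity hypothesis.
#'
#' The default `t_min = -0.42` degC calibrates the 30-vs-12 degC capacity
#' ratio to 6.0, the batch glycolytic-flux ratio observed between those
#' temperatures.
#'
#' @param b_glc Ratkowsky coefficient of the glucose uptake step
#'   (mM min^-1 degC^-2).
#' @param t_min Notional minimum-growth temperature (degC).
#' @param t_ref Reference temperature T0 (degC), default 30.
#' @return A `ratkowsky_params` object.
#' @export
ratkowsky_params <- function(b_glc = 0.13, t_min = -0.42, t_ref = 30) {
  stopifnot(t_min < 12, 12 <= t_ref, b_glc > 0)
  structure(list(b_glc = b_glc, t_min = t_min, t_ref = t_ref),
            class = "ratkowsky_params")
}

#' Normalized Ratkowsky capacity scale
#'
#' @param params A [ratkowsky_params()] object.
#' @param T Temperature (degC), vectorized; must be `>= t_min`.
#' @param exponent Ratkowsky exponent (2 by default; a "k times less
#'   sensitive" enzyme uses `2/k`).
#' @return `R(T) = ((T - t_min)/(t_ref - t_min))^exponent`; equals 1 at
#'   `t_ref` and 0 at `t_min`, strictly increasing in between.
#' @export
ratkowsky_scale <- function(params, T, exponent = 2) {
  if (any(T < params$t_min))
    stop_domain("ratkowsky_scale: T below t_min")
  ((T - params$t_min) / (params$t_ref - params$t_min))^exponent
}

#' Flux-proportional Ratkowsky coefficient
#'
#' Each reaction's coefficient is the glucose-uptake coefficient weighted by
#' its flux share at the reference condition:
#' `b_j = b_glc * v_j(T0) / v_consumption(T0)`.
#'
#' @param b_glc Coefficient of the uptake reaction (mM min^-1 degC^-2).
#' @param v_j_ref Reference-condition flux of reaction j (mM/min).
#' @param v_consumption_ref Reference-condition glucose uptake flux (mM/min),
#'   must be positive.
#' @return `b_j`, same units as `b_glc`.
#' @export
compute_b <- function(b_glc, v_j_ref, v_consumption_ref) {
  if (v_consumption_ref <= 0)
    stop_domain("compute_b: reference uptake flux must be positive")
  b_glc * v_j_ref / v_consumption_ref
}

#' Standard reaction enthalpy from two equilibrium constants
#'
#' Inverts the Van't Hoff relation
#' `ln(Keq2/Keq1) = dH/R * (1/T1 - 1/T2)`.
#'
#' @param keq_1,keq_2 Equilibrium constants (dimensionless, > 0).
#' @param T1,T2 Absolute temperatures (K), distinct.
#' @return Standard reaction enthalpy dH (J/mol).
#' @export
vant_hoff_delta_h <- function(keq_1, T1, keq_2, T2) {
  if (keq_1 <= 0 || keq_2 <= 0)
    stop_domain("vant_hoff_delta_h: Keq must be positive")
  if (T1 == T2) stop_domain("vant_hoff_delta_h: T1 must differ from T2")
  GAS_CONSTANT * log(keq_2 / keq_1) / (1 / T1 - 1 / T2)
}

GAS_CONSTANT <- 8.314 # J mol^-1 K^-1

#' Van't Hoff parameters
#'
#' @param keq_ref Equilibrium constant at `t_ref`.
#' @param delta_h Standard reaction enthalpy (J/mol).
#' @param t_ref Reference temperature (degC, converted internally to K).
#' @return A `vant_hoff_params` object.
#' @export
vant_hoff_params <- function(keq_ref, delta_h, t_ref = 30) {
  stopifnot(keq_ref > 0)
  structure(list(keq_ref = keq_ref, delta_h = delta_h, t_ref = t_ref,
                 gas_constant = GAS_CONSTANT),
            class = "vant_hoff_params")
}

#' Equilibrium constant at a temperature
#'
#' Forward Van't Hoff propagation from the reference anchor:
#' `Keq(T) = keq_ref * exp(dH/R * (1/T_ref - 1/T))` with temperatures in K.
#'
#' @param params A [vant_hoff_params()] object.
#' @param T Temperature in Kelvin (vectorized), > 0.
#' @return Keq(T); equals `keq_ref` at the reference, monotone in T with the
#'   sign of `delta_h`.
#' @export
keq_at_temperature <- function(params, T) {
  if (any(T <= 0)) stop_domain("keq_at_temperature: T must be > 0 K")
  t_ref_k <- celsius_to_kelvin(params$t_ref)
  params$keq_ref * exp(params$delta_h / params$gas_constant *
                         (1 / t_ref_k - 1 / T))
}

#' @rdname keq_at_temperature
#' @param T_celsius Temperature in degC.
#' @export
celsius_to_kelvin <- function(T_celsius) T_celsius + 273.15

#' Equilibrium constants of glycolytic reactions at 12 and 30 degC
#'
#' The packaged anchor pairs used for Van't Hoff propagation, one row per
#' glycolytic enzyme, with the printed fold change and the direction
#' convention it follows (`"12/30"` means the printed value is
#' `Keq(12)/Keq(30)`, `"30/12"` the inverse). The conventions are mixed in
#' the source table; they are stored explicitly so the consistency checks are
#' direction-aware.
#'
#' @return Data frame: `reaction`, `keq_12`, `keq_30`, `fold_printed`,
#'   `fold_convention`.
#' @export
keq_table <- function() {
  data.frame(
    reaction = c("HXK", "PGI", "PFK", "FBA", "TPI",
                 "TDH", "PGK", "PGM", "ENO", "PYK"),
    keq_12 = c(7.7e3, 0.27, 5.0e3, 9.3e-4, 0.040,
               0.66, 20, 0.074, 5.1, 3.9e4),
    keq_30 = c(3.5e3, 0.29, 2.4e3, 1.4e-3, 0.048,
               0.69, 16, 0.087, 4.5, 1.4e4),
    fold_printed = c(0.45, 0.93, 2.08, 1.51, 1.20,
                     1.05, 1.25, 1.18, 1.13, 2.79),
    fold_convention = c("30/12", "12/30", "12/30", "30/12", "30/12",
                        "30/12", "12/30", "30/12", "12/30", "12/30"),
    stringsAsFactors = FALSE
  )
}

#' Van't Hoff parameters derived from the packaged anchor table
#'
#' @param t_ref Reference temperature (degC) at which `keq_ref` is anchored.
#' @return Named list of [vant_hoff_params()], one per reaction in
#'   [keq_table()].
#' @export
keq_params_from_table <- function(t_ref = 30) {
  tab <- keq_table()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    dh <- vant_hoff_delta_h(tab$keq_12[i], celsius_to_kelvin(12),
                            tab$keq_30[i], celsius_to_kelvin(30))
    keq_ref <- if (t_ref == 30) tab$keq_30[i] else if (t_ref == 12)
      tab$keq_12[i] else stop_config("t_ref must be 12 or 30")
    vant_hoff_params(keq_ref, dh, t_ref = t_ref)
  })
  names(out) <- tab$reaction
  out
}

#' Sensitivity perturbation of one enzyme
#'
#' Declares that one reaction's catalytic capacity is `factor` times less
#' sensitive to temperature than the shared baseline. Implemented as dividing
#' the Ratkowsky exponent by `factor` (2 becomes 1 for `factor = 2`), which
#' halves `d(log R)/dT` at every temperature while keeping `R(t_ref) = 1`.
#'
#' @param reaction_id Target reaction id.
#' @param factor Dimensionless, >= 1.
#' @return A `sensitivity_spec` object.
#' @export
sensitivity_spec <- function(reaction_id, factor = 2) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L, factor >= 1)
  structure(list(reaction_id = reaction_id, factor = factor),
            class = "sensitivity_spec")
}

#' Per-reaction temperature scale functions
#'
#' Builds the map `reaction -> R_j(T)`. All reactions share the baseline
#' Ratkowsky scale except those named in `specs`, whose exponent is divided
#' by their factor. Every returned function equals 1 at `t_ref`.
#'
#' @param params A [ratkowsky_params()] object.
#' @param specs A [sensitivity_spec()], a list of them, or `NULL`.
#' @param reaction_ids Character vector of all reaction ids.
#' @return Named list of functions `f(T_degC) -> scale`.
#' @export
apply_sensitivity <- function(params, specs = NULL, reaction_ids) {
  if (inherits(specs, "sensitivity_spec")) specs <- list(specs)
  exps <- stats::setNames(rep(2, length(reaction_ids)), reaction_ids)
  for (s in specs) {
    if (!s$reaction_id %in% reaction_ids)
      stop_config("apply_sensitivity: unknown reaction `", s$reaction_id, "`")
    exps[s$reaction_id] <- 2 / s$factor
  }
  out <- lapply(exps, function(e) {
    force(e)
    function(T) ratkowsky_scale(params, T, exponent = e)
  })
  names(out) <- reaction_ids
  out
}

#' Evaluate a scale-function map at a temperature
#'
#' @param scale_fns Named list from [apply_sensitivity()].
#' @param T Temperature (degC).
#' @return Named numeric vector of per-reaction scales.
#' @export
scales_at_temperature <- function(scale_fns, T) {
  vapply(scale_fns, function(f) f(T), numeric(1))
}

#' Temperature profiles
#'
#' Three profile variants drive the simulated cultivations:
#' * `constant`: fixed temperature;
#' * `linear_shift`: a continuous down-and-back (or up-and-back) ramp from
#'   `start_T` to `target_T` at `ramp_rate` degC/min, immediately returning,
#'   then holding at `start_T`;
#' * `sinoid`: `mean + amplitude * sin(angular_frequency * t + phase)`,
#'   default `21 + 9 sin(pi/12 t + 1.57)` (a 24-h circadian cycle spanning
#'   12-30 degC).
#'
#' @param variant One of `"constant"`, `"linear_shift"`, `"sinoid"`.
#' @param constant Temperature for the constant variant (degC).
#' @param start_T,target_T,ramp_rate Linear-shift parameters (degC and
#'   degC/min).
#' @param mean,amplitude,angular_frequency,phase Sinoid parameters (degC,
#'   degC, rad/h, rad).
#' @return A `temperature_profile` object.
#' @export
temperature_profile <- function(variant = c("constant", "linear_shift",
                                            "sinoid"),
                                constant = 30,
                                start_T = 30, target_T = 12, ramp_rate = 0.2,
                                mean = 21, amplitude = 9,
                                angular_frequency = pi / 12, phase = 1.57) {
  variant <- match.arg(variant)
  structure(list(variant = variant, constant = constant, start_T = start_T,
                 target_T = target_T, ramp_rate = ramp_rate, mean = mean,
                 amplitude = amplitude, angular_frequency = angular_frequency,
                 phase = phase),
            class = "temperature_profile")
}

#' Temperature at time t
#'
#' @param profile A [temperature_profile()].
#' @param t Time in hours (vectorized), >= 0.
#' @return Temperature (degC).
#' @export
profile_temperature <- function(profile, t) {
  switch(profile$variant,
    constant = rep(profile$constant, length(t)),
    sinoid = profile$mean + profile$amplitude *
      sin(profile$angular_frequency * t + profile$phase),
    linear_shift = {
      rate_h <- profile$ramp_rate * 60
      leg <- abs(profile$target_T - profile$start_T) / rate_h
      dir <- sign(profile$target_T - profile$start_T)
      T1 <- profile$start_T + dir * rate_h * pmin(t, leg)
      down <- t <= leg
      back <- t > leg & t <= 2 * leg
      out <- rep(profile$start_T, length(t))
      out[down] <- T1[down]
      out[back] <- profile$target_T - dir * rate_h * (t[back] - leg)
      out
    })
}

#' Duration of the ramp portion of a linear shift (hours)
#' @param profile A linear-shift [temperature_profile()].
#' @return Hours from start until the temperature is back at `start_T`.
#' @export
shift_duration <- function(profile) {
  stopifnot(profile$variant == "linear_shift")
  2 * abs(profile$target_T - profile$start_T) / (profile$ramp_rate * 60)
}

#' Export a per-reaction scale table for audit
#'
#' @param scale_fns Named list from [apply_sensitivity()].
#' @param temperatures Temperatures (degC) at which to tabulate.
#' @return Data frame with columns `T_C`, `reaction`, `scale`.
#' @export
scale_table <- function(scale_fns, temperatures = seq(12, 30, by = 2)) {
  out <- expand.grid(T_C = temperatures, reaction = names(scale_fns),
                     stringsAsFactors = FALSE)
  out$scale <- mapply(function(T, rx) scale_fns[[rx]](T),
                      out$T_C, out$reaction)
  out[order(out$T_C, out$reaction), ]
}
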