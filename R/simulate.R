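#' Time-course simulation of the intracellular network
#'
#' Integrates the free (non-clamped) species of a network under possibly
#' time-varying clamped concentrations and capacity scales, with a
#' stiff-capable integrator (`deSolve::lsoda`, rtol 1e-8, atol 1e-10).
#' Time is in hours; rates are mM/min internally, converted to mM/h.
#'
#' @param model A `network_model`.
#' @param clamped_profiles Named list: for each clamped species either a
#'   constant (mM) or a function of time `f(t_h) -> mM`.
#' @param scale_profiles Either a constant, a named numeric vector, or a
#'   function `f(t_h)` returning a named per-reaction scale vector.
#' @param t_span Length-2 numeric, hours.
#' @param t_eval Increasing time points (hours) within `t_span` at which the
#'   state is reported; defaults to 200 equispaced points.
#' @param initial Named numeric vector (mM) for free species (default 1 mM).
#' @param keq Optional per-reaction Keq override or function of time.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame of class `gt_trajectory`: `time_h`, one column per
#'   species (mM), and one `flux_<reaction>` column per reaction (mM/min).
#'   On integration failure an error of class `gt_integration_failure` carries
#'   the last successful time in its `last_time` field.
#' @export
simulate_network <- function(model, clamped_profiles, scale_profiles = 1,
                             t_span, t_eval = NULL, initial = NULL,
                             keq = NULL, rtol = 1e-8, atol = 1e-10) {
  refuse_unmapped(model)
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(t_eval))
    t_eval <- seq(t_span[1], t_span[2], length.out = 200L)
  if (is.unsorted(t_eval, strictly = FALSE) ||
      min(t_eval) < t_span[1] || max(t_eval) > t_span[2])
    stop_config("`t_eval` must be increasing and within `t_span`")

  free <- setdiff(names(model$species), model$clamped)
  clamp_at <- make_profile_fn(clamped_profiles, model$clamped)
  scales_at <- make_scales_fn(scale_profiles, names(model$reactions))
  keq_at <- if (is.function(keq)) keq else function(t) keq

  N <- stoichiometric_matrix(model)
  Nf <- N[free, , drop = FALSE]
  y0 <- guess_or_default(initial, free)

  deriv <- function(t, y, parms) {
    conc <- full_conc(model, clamp_at(t), stats::setNames(pmax(y, 0), free))
    v <- network_rates(model, conc, scales_at(t), keq_at(t))
    list(60 * drop(Nf %*% v))
  }

  times <- unique(c(t_span[1], t_eval))
  if (length(times) == 1L) {
    out <- matrix(c(times, y0), nrow = 1,
                  dimnames = list(NULL, c("time", names(y0))))
  } else {
    out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    check_integration(out, times)
  }
  out <- out[out[, 1] %in% t_eval, , drop = FALSE]

  fluxes <- t(vapply(seq_len(nrow(out)), function(i) {
    t <- out[i, 1]
    conc <- full_conc(model, clamp_at(t),
                      stats::setNames(pmax(out[i, -1], 0), free))
    network_rates(model, conc, scales_at(t), keq_at(t))
  }, numeric(length(model$reactions))))
  colnames(fluxes) <- paste0("flux_", names(model$reactions))

  clamped_cols <- t(vapply(out[, 1], function(t) clamp_at(t),
                           numeric(length(model$clamped))))
  colnames(clamped_cols) <- model$clamped

  traj <- data.frame(time_h = out[, 1], out[, free, drop = FALSE],
                     clamped_cols, fluxes, check.names = FALSE)
  class(traj) <- c("gt_trajectory", "data.frame")
  traj
}

make_profile_fn <- function(profiles, ids) {
  if (is.numeric(profiles) && !is.null(names(profiles)))
    profiles <- as.list(profiles)
  missing <- setdiff(ids, names(profiles))
  if (length(missing))
    stop_config("clamped_profiles missing for: ",
                paste(missing, collapse = ", "))
  function(t) {
    vapply(ids, function(id) {
      p <- profiles[[id]]
      if (is.function(p)) p(t) else as.numeric(p)
    }, numeric(1))
  }
}

make_scales_fn <- function(scale_profiles, rx_ids) {
  if (is.function(scale_profiles))
    return(function(t) expand_scales(scale_profiles(t), rx_ids))
  sc <- expand_scales(scale_profiles, rx_ids)
  function(t) sc
}

check_integration <- function(out, times) {
  got <- out[, 1]
  if (length(got) < length(unique(times)) || any(!is.finite(out))) {
    last_time <- if (length(got)) max(got[apply(is.finite(out), 1, all)]) else NA
    stop(errorCondition(
      paste0("integration failed; last successful time = ", last_time, " h"),
      class = c("gt_integration_failure", "error"),
      last_time = last_time))
  }
  invisible(out)
}
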