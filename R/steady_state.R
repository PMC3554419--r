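#' Evaluate all reaction rates of a model
#'
#' @param model A `network_model`.
#' @param concentrations Named numeric vector covering all species (mM).
#' @param scales Named numeric vector of per-reaction capacity scales, or a
#'   single number recycled to all reactions (default 1).
#' @param keq Optional named numeric vector overriding `keq_ref` per reaction
#'   (used for Van't Hoff temperature propagation).
#' @return Named numeric vector of rates (mM/min).
#' @export
network_rates <- function(model, concentrations, scales = 1, keq = NULL) {
  rx <- names(model$reactions)
  scales <- expand_scales(scales, rx)
  v <- numeric(length(rx))
  names(v) <- rx
  for (i in seq_along(rx)) {
    r <- model$reactions[[i]]
    k <- if (!is.null(keq) && r$id %in% names(keq)) keq[[r$id]] else NULL
    v[i] <- scales[[r$id]] * rate_core(r$rate_law, r$stoichiometry,
                                       concentrations, keq = k)
  }
  v
}

expand_scales <- function(scales, rx_ids) {
  if (is.null(scales)) scales <- 1
  if (length(scales) == 1L && is.null(names(scales)))
    return(stats::setNames(rep(as.numeric(scales), length(rx_ids)), rx_ids))
  missing <- setdiff(rx_ids, names(scales))
  if (length(missing))
    stop_config("scales missing for reactions: ",
                paste(missing, collapse = ", "))
  scales[rx_ids]
}

#' Solve for a steady state of the intracellular network
#'
#' Finds concentrations of all non-clamped species such that `N %*% v = 0`
#' for the free species. A damped Newton iteration in log-concentration space
#' is tried first; if it fails, the system is relaxed by stiff ODE integration
#' until the derivatives plateau, followed by a Newton polish. The field
#' `method` reports which path succeeded.
#'
#' @param model A `network_model`.
#' @param clamped_values Named numeric vector (mM) for every clamped species.
#' @param scales Per-reaction capacity scales (single number or named vector).
#' @param initial_guess Named numeric vector (mM) for the free species;
#'   defaults to 1 mM each.
#' @param keq Optional per-reaction Keq override (see [network_rates()]).
#' @param tol Absolute tolerance on `max |N v|` (mM/min), default 1e-9.
#' @param sink Optional function `f(v) -> named numeric` giving extra
#'   consumption rates (mM/min) per species as a function of the flux vector,
#'   e.g. the anabolic precursor drain of [reactor_config()].
#' @return A `steady_state` object: `concentrations` (all species), `fluxes`,
#'   `residual_norm`, `method`.
#' @export
solve_steady_state <- function(model, clamped_values, scales = 1,
                               initial_guess = NULL, keq = NULL, tol = 1e-9,
                               sink = NULL) {
  refuse_unmapped(model)
  sp <- names(model$species)
  clamped <- model$clamped
  missing <- setdiff(clamped, names(clamped_values))
  if (length(missing))
    stop_config("clamped_values missing for: ", paste(missing, collapse = ", "))
  ext <- species_ids(model, "extracellular")
  if (!all(ext %in% clamped))
    stop_config("all extracellular species must be clamped: ",
                paste(setdiff(ext, clamped), collapse = ", "))
  free <- setdiff(sp, clamped)
  scales <- expand_scales(scales, names(model$reactions))

  if (all(vapply(model$reactions, function(r) r$rate_law$vmax_ref, 1) *
          scales == 0)) {
    warning("all capacities are zero; returning the trivial zero-flux state")
    conc <- full_conc(model, clamped_values,
                      guess_or_default(initial_guess, free))
    v <- network_rates(model, conc, scales, keq)
    return(new_steady_state(conc, v, 0, "trivial"))
  }

  N <- stoichiometric_matrix(model)
  Nf <- N[free, , drop = FALSE]
  sink_of <- function(v) {
    out <- stats::setNames(numeric(length(free)), free)
    if (!is.null(sink)) {
      s <- sink(v)
      common <- intersect(names(s), free)
      out[common] <- s[common]
    }
    out
  }
  resid <- function(x) {
    conc <- full_conc(model, clamped_values, stats::setNames(x, free))
    v <- network_rates(model, conc, scales, keq)
    drop(Nf %*% v) - sink_of(v)
  }
  x0 <- guess_or_default(initial_guess, free)

  sol <- newton_log(resid, x0, tol = tol)
  method <- "root"
  if (!sol$converged) {
    relax <- relax_to_steady(model, clamped_values, scales, keq, x0, free,
                             sink = sink)
    sol2 <- newton_log(resid, relax, tol = tol)
    if (sol2$converged) {
      sol <- sol2
      method <- "relaxation"
    } else {
      stop("no steady state found (root + relaxation); last max|N v| = ",
           format(max(abs(sol2$fvec)), digits = 4))
    }
  }
  conc <- full_conc(model, clamped_values, stats::setNames(sol$x, free))
  if (any(conc < 0))
    stop("negative steady-state concentration; refusing to clip")
  v <- network_rates(model, conc, scales, keq)
  res <- if (length(free)) max(abs(drop(Nf %*% v) - sink_of(v))) else 0
  new_steady_state(conc, v, res, method)
}

guess_or_default <- function(initial_guess, free) {
  x0 <- stats::setNames(rep(1, length(free)), free)
  if (!is.null(initial_guess)) {
    common <- intersect(free, names(initial_guess))
    x0[common] <- pmax(initial_guess[common], 1e-9)
  }
  x0
}

full_conc <- function(model, clamped_values, free_values) {
  conc <- stats::setNames(numeric(length(model$species)),
                          names(model$species))
  conc[names(free_values)] <- free_values
  conc[intersect(names(clamped_values), names(conc))] <-
    clamped_values[intersect(names(clamped_values), names(conc))]
  conc
}

new_steady_state <- function(concentrations, fluxes, residual_norm, method) {
  structure(list(concentrations = concentrations, fluxes = fluxes,
                 residual_norm = residual_norm, method = method),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> method =", x$method,
      " max|N v| =", format(x$residual_norm, digits = 3), "\n")
  print(round(x$concentrations, 6))
  invisible(x)
}

# Damped Newton in log-concentration space (keeps iterates positive).
newton_log <- function(resid, x0, tol, max_iter = 200L) {
  u <- log(pmax(x0, 1e-12))
  f <- function(u) resid(exp(u))
  fv <- tryCatch(f(u), error = function(e) NULL)
  if (is.null(fv) || any(!is.finite(fv)))
    return(list(converged = FALSE, x = x0, fvec = rep(Inf, length(x0))))
  for (iter in seq_len(max_iter)) {
    if (max(abs(fv)) <= tol)
      return(list(converged = TRUE, x = exp(u), fvec = fv))
    J <- num_jacobian(f, u, fv)
    step <- tryCatch(solve(J, -fv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(converged = FALSE, x = exp(u), fvec = fv))
    step <- pmin(pmax(step, -5), 5) # trust region in log space
    lambda <- 1
    improved <- FALSE
    for (ls in 1:30) {
      u_new <- u + lambda * step
      fv_new <- tryCatch(f(u_new), error = function(e) NULL)
      if (!is.null(fv_new) && all(is.finite(fv_new)) &&
          max(abs(fv_new)) < max(abs(fv))) {
        u <- u_new; fv <- fv_new; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved)
      return(list(converged = max(abs(fv)) <= tol, x = exp(u), fvec = fv))
  }
  list(converged = max(abs(fv)) <= tol, x = exp(u), fvec = fv)
}

num_jacobian <- function(f, u, fu, h = 1e-6) {
  n <- length(u)
  J <- matrix(0, length(fu), n)
  for (j in seq_len(n)) {
    up <- u; up[j] <- up[j] + h
    J[, j] <- (f(up) - fu) / h
  }
  J
}

# ODE relaxation toward steady state; integrates until derivatives plateau.
relax_to_steady <- function(model, clamped_values, scales, keq, x0, free,
                            t_max = 1e5, sink = NULL) {
  N <- stoichiometric_matrix(model)
  Nf <- N[free, , drop = FALSE]
  deriv <- function(t, y, parms) {
    conc <- full_conc(model, clamped_values,
                      stats::setNames(pmax(y, 0), free))
    v <- network_rates(model, conc, scales, keq)
    d <- drop(Nf %*% v)
    if (!is.null(sink)) {
      s <- sink(v)
      common <- intersect(names(s), free)
      d[match(common, free)] <- d[match(common, free)] - s[common]
    }
    list(d)
  }
  y <- x0
  t_end <- 10
  for (k in 1:12) {
    out <- deSolve::lsoda(y, c(0, t_end), deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    y <- pmax(out[nrow(out), -1], 1e-12)
    names(y) <- free
    d <- deriv(0, y, NULL)[[1]]
    if (max(abs(d)) < 1e-8) break
    t_end <- t_end * 4
    if (t_end > t_max) break
  }
  y
}

#' Steady state at an imposed pathway flux
#'
#' Finds the clamped substrate concentration at which the steady-state flux
#' through a given reaction equals `flux`, as in a glucose-limited chemostat
#' where the flux is set by the feed. Together with [solve_steady_state()]
#' this expresses the manifold equivalence: the state at capacity scale `r`
#' and flux `v` equals the state at scale 1 and flux `v/r`.
#'
#' @param model A `network_model`.
#' @param flux Target flux (mM/min) through `flux_reaction`.
#' @param substrate_id Clamped species to adjust (default: first clamped).
#' @param flux_reaction Reaction whose flux is imposed (default: first).
#' @param scales,keq,initial_guess Passed to [solve_steady_state()].
#' @param interval Search interval for the substrate concentration (mM).
#' @param other_clamped Values for the remaining clamped species (default 0).
#' @return A `steady_state` object with attribute `substrate` (the solved
#'   clamped concentration, mM).
#' @export
steady_state_at_flux <- function(model, flux, substrate_id = NULL,
                                 flux_reaction = NULL, scales = 1, keq = NULL,
                                 initial_guess = NULL,
                                 interval = c(1e-8, 1e4),
                                 other_clamped = NULL, sink = NULL) {
  if (is.null(substrate_id)) substrate_id <- model$clamped[1]
  if (is.null(flux_reaction)) flux_reaction <- names(model$reactions)[1]
  base <- stats::setNames(rep(0, length(model$clamped)), model$clamped)
  if (!is.null(other_clamped))
    base[names(other_clamped)] <- other_clamped
  fun <- function(log_s) {
    cl <- base
    cl[substrate_id] <- exp(log_s)
    ss <- solve_steady_state(model, cl, scales = scales, keq = keq,
                             initial_guess = initial_guess, sink = sink)
    ss$fluxes[[flux_reaction]] - flux
  }
  root <- stats::uniroot(fun, log(interval), tol = 1e-12)
  s_star <- exp(root$root)
  cl <- base
  cl[substrate_id] <- s_star
  ss <- solve_steady_state(model, cl, scales = scales, keq = keq,
                           initial_guess = initial_guess, sink = sink)
  attr(ss, "substrate") <- s_star
  ss
}

# models imported with untranslated kinetic laws cannot be simulated
refuse_unmapped <- function(model) {
  un <- attr(model, "unmapped_laws")
  if (!is.null(un) && length(un))
    stop_config("model has unmapped rate laws (", paste(un, collapse = ", "),
                "); supply rate laws before simulating")
  invisible(model)
}
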