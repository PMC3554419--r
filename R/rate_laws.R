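#' Mass-action ratio of a reaction
#'
#' `Gamma = prod(products^|coef|) / prod(substrates^|coef|)`, using the signed
#' stoichiometry of the reaction. It depends only on stoichiometry, not on the
#' kinetic mechanism.
#'
#' @param reaction A [reaction()] object.
#' @param concentrations Named numeric vector of concentrations (mM).
#' @return Dimensionless ratio.
#' @export
mass_action_ratio <- function(reaction, concentrations) {
  st <- reaction$stoichiometry
  missing <- setdiff(names(st), names(concentrations))
  if (length(missing))
    stop_config("mass_action_ratio: missing species: ",
                paste(missing, collapse = ", "))
  conc <- concentrations[names(st)]
  if (any(conc < 0))
    stop_domain("mass_action_ratio: negative concentration")
  subs <- st < 0
  if (any(conc[subs] == 0))
    stop_gamma_undefined("mass_action_ratio: zero substrate concentration, ",
                         "Gamma undefined for `", reaction$id, "`")
  exp(sum(st * log(conc)))
}

#' Evaluate a reaction rate
#'
#' Computes `v = scale * vmax_ref * f(...) * (1 - Gamma/Keq)` where the
#' saturation function `f` depends on the rate-law kind (see [rate_law()]).
#' `scale` is the dimensionless temperature scale multiplying the capacity;
#' the rate is linear in `scale`.
#'
#' @param x A [reaction()] or a [rate_law()]. When a bare rate law is given,
#'   unit stoichiometry (one substrate, one product as named in the Km maps)
#'   is assumed for the mass-action ratio.
#' @param concentrations Named numeric vector (mM); must contain every species
#'   the law refers to.
#' @param scale Dimensionless nonnegative capacity scale (default 1).
#' @return Rate in mM/min. For reversible kinds the sign equals the sign of
#'   `(1 - Gamma/Keq)`.
#' @export
evaluate_rate <- function(x, concentrations, scale = 1) {
  if (inherits(x, "gt_reaction")) {
    law <- x$rate_law
    st <- x$stoichiometry
  } else if (inherits(x, "rate_law")) {
    law <- x
    st <- c(stats::setNames(rep(-1, length(law$km_substrates)),
                            names(law$km_substrates)),
            stats::setNames(rep(1, length(law$km_products)),
                            names(law$km_products)))
  } else {
    stop_config("evaluate_rate: `x` must be a reaction or rate_law")
  }
  if (length(scale) != 1L || !is.finite(scale) || scale < 0)
    stop_domain("evaluate_rate: `scale` must be a single nonnegative number")
  refs <- unique(c(names(law$km_substrates), names(law$km_products),
                   names(law$effector_constants),
                   names(st)[st != 0]))
  missing <- setdiff(refs, names(concentrations))
  if (length(missing))
    stop_config("evaluate_rate: missing species: ",
                paste(missing, collapse = ", "))
  if (any(concentrations[refs] < 0))
    stop_domain("evaluate_rate: negative concentration")
  scale * rate_core(law, st, concentrations)
}

# saturation-and-thermodynamics core shared with the compiled evaluator
rate_core <- function(law, st, conc, keq = NULL) {
  if (is.null(keq)) keq <- law$keq_ref
  kind <- law$kind
  if (kind == "facilitated_diffusion") {
    s_id <- names(law$km_substrates)[1]
    p_id <- names(st)[st > 0][1]
    K <- law$km_substrates[[1]]
    S <- conc[[s_id]]; P <- conc[[p_id]]
    return(law$vmax_ref * (S - P) / (K * (1 + S / K + P / K)))
  }
  subs <- names(st)[st < 0]
  prods <- names(st)[st > 0]
  if (kind == "mass_action") {
    fwd <- prod(conc[subs]^abs(st[subs]))
    v <- law$vmax_ref * fwd
    if (!is.null(keq)) {
      # fwd*(1 - Gamma/Keq) written as fwd - prod(P)/Keq: finite at zero substrate
      v <- law$vmax_ref * (fwd - prod(conc[prods]^st[prods]) / keq)
    }
    return(v)
  }
  num <- 1
  den <- 1
  for (i in seq_along(law$km_substrates)) {
    term <- conc[[names(law$km_substrates)[i]]] / law$km_substrates[[i]]
    num <- num * term
    den <- den + term
  }
  for (i in seq_along(law$km_products))
    den <- den + conc[[names(law$km_products)[i]]] / law$km_products[[i]]
  for (i in seq_along(law$effector_constants))
    den <- den + conc[[names(law$effector_constants)[i]]] /
      law$effector_constants[[i]]
  if (kind == "reversible_mm") {
    # num*(1 - Gamma/Keq) expanded so zero substrate gives a finite back rate:
    # prod(S^|ns|)/prod(Ks^|ns|) - prod(P^|np|)/(prod(Ks^|ns|)*Keq)
    ks_prod <- prod(vapply(seq_along(law$km_substrates), function(i)
      law$km_substrates[[i]]^abs(st[[names(law$km_substrates)[i]]]),
      numeric(1)))
    fwd <- prod(conc[subs]^abs(st[subs])) / ks_prod
    rev <- prod(conc[prods]^st[prods]) / (ks_prod * keq)
    return(law$vmax_ref * (fwd - rev) / den)
  }
  law$vmax_ref * num / den
}

# Gamma from signed stoichiometry; returns Inf when a substrate is zero and a
# product is positive (drives reversible rates negative), NaN only on 0/0.
gamma_of <- function(st, conc) {
  st <- st[st != 0]
  x <- conc[names(st)]
  if (all(x > 0)) return(exp(sum(st * log(x))))
  subs <- st < 0
  if (any(x[subs] == 0)) {
    if (all(x[!subs] == 0)) return(0) # empty both sides: forward direction
    return(Inf)
  }
  0
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("gt_config_error", "error")))
}
stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("gt_domain_error", "error")))
}
stop_gamma_undefined <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("gt_gamma_undefined", "gt_domain_error",
                                "error")))
}
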