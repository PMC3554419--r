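#' Define a species of a kinetic network
#'
#' @param id Short unique identifier, e.g. `"G6P"`.
#' @param compartment Either `"intracellular"` or `"extracellular"`.
#'   Concentrations are in mM in both compartments (intracellular values are
#'   per cytosol volume).
#' @return A `gt_species` object.
#' @export
species <- function(id, compartment = c("intracellular", "extracellular")) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, compartment = compartment, unit = "mM"),
            class = "gt_species")
}

#' Define a rate law
#'
#' The general form is `v = scale * vmax_ref * f(...) * (1 - Gamma/Keq)`,
#' where `f` is a saturation function built from the Michaelis constants and
#' `Gamma` is the mass-action ratio. The supported kinds are:
#'
#' * `irreversible_mm`: `v = scale * Vmax * prod(S/Ks) / (1 + sum(S/Ks) + sum(E/Ke))`
#' * `reversible_mm`: as above but multiplied by `(1 - Gamma/Keq)` and with
#'   product terms `P/Kp` added to the denominator
#' * `facilitated_diffusion`: symmetric carrier,
#'   `v = scale * Vmax * (S - P) / (K * (1 + S/K + P/K))`
#' * `mass_action`: `v = scale * vmax_ref * prod(S^|n|)`, multiplied by
#'   `(1 - Gamma/Keq)` when `keq_ref` is given
#'
#' `effector_constants` adds competitive (denominator) terms `E/Ke`, used in
#' the packaged model for product inhibition of the irreversible steps.
#'
#' @param kind One of `"irreversible_mm"`, `"reversible_mm"`,
#'   `"facilitated_diffusion"`, `"mass_action"`.
#' @param vmax_ref Capacity at the reference temperature (mM/min); the product
#'   of enzyme level and reference turnover number.
#' @param km_substrates,km_products Named numeric vectors of saturation
#'   constants (mM), keyed by species id.
#' @param keq_ref Equilibrium constant at the reference temperature
#'   (dimensionless in the concentration convention of the reaction).
#' @param effector_constants Named numeric vector of effector constants (mM).
#' @return A `rate_law` object.
#' @export
rate_law <- function(kind = c("irreversible_mm", "reversible_mm",
                              "facilitated_diffusion", "mass_action"),
                     vmax_ref,
                     km_substrates = numeric(),
                     km_products = numeric(),
                     keq_ref = NULL,
                     effector_constants = numeric()) {
  kind <- match.arg(kind)
  if (!is.numeric(vmax_ref) || length(vmax_ref) != 1L || vmax_ref < 0)
    stop("`vmax_ref` must be a single nonnegative number", call. = FALSE)
  for (k in list(km_substrates, km_products, effector_constants)) {
    if (length(k) && (is.null(names(k)) || any(!nzchar(names(k))) || any(k <= 0)))
      stop("saturation/effector constants must be named and strictly positive",
           call. = FALSE)
  }
  if (kind == "reversible_mm") {
    if (is.null(keq_ref) || keq_ref <= 0)
      stop("`reversible_mm` requires `keq_ref` > 0", call. = FALSE)
  }
  structure(list(kind = kind,
                 vmax_ref = vmax_ref,
                 km_substrates = km_substrates,
                 km_products = km_products,
                 keq_ref = keq_ref,
                 effector_constants = effector_constants),
            class = "rate_law")
}

#' Define a reaction
#'
#' @param id Short unique identifier, e.g. `"PFK"`.
#' @param stoichiometry Named numeric vector of signed coefficients (one
#'   column of the stoichiometric matrix); at least one coefficient must be
#'   negative.
#' @param rate_law A [rate_law()] object.
#' @param pathway_index Position in the linear pathway order, used by the
#'   localization rule of [localize_deviant_enzyme()].
#' @param branch Logical; `TRUE` for side branches that are not part of the
#'   main glucose-to-ethanol backbone.
#' @return A `gt_reaction` object.
#' @export
reaction <- function(id, stoichiometry, rate_law, pathway_index = NA_integer_,
                     branch = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("`stoichiometry` must be a named numeric vector", call. = FALSE)
  if (!any(stoichiometry < 0))
    stop("reaction `", id, "` has no substrate (negative coefficient)",
         call. = FALSE)
  if (!inherits(rate_law, "rate_law"))
    stop("`rate_law` must be a rate_law object", call. = FALSE)
  structure(list(id = id,
                 stoichiometry = stoichiometry,
                 rate_law = rate_law,
                 pathway_index = as.integer(pathway_index),
                 branch = isTRUE(branch)),
            class = "gt_reaction")
}

#' Assemble a kinetic network model
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param clamped Character vector of species ids treated as externally fixed
#'   (must cover all extracellular species for steady-state solving).
#' @param name Optional model name.
#' @return A `network_model` object.
#' @export
network_model <- function(species, reactions, clamped = character(),
                          name = "model") {
  sp_ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(sp_ids))
    stop("duplicate species ids: ",
         paste(unique(sp_ids[duplicated(sp_ids)]), collapse = ", "),
         call. = FALSE)
  rx_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rx_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", "),
         call. = FALSE)
  for (r in reactions) {
    unknown <- setdiff(names(r$stoichiometry), sp_ids)
    if (length(unknown))
      stop("reaction `", r$id, "` references undeclared species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(clamped, sp_ids)
  if (length(unknown))
    stop("clamped set references undeclared species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  names(species) <- sp_ids
  names(reactions) <- rx_ids
  structure(list(name = name, species = species, reactions = reactions,
                 clamped = clamped),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$name, "\n", sep = "")
  cat("  species:  ", length(x$species), " (",
      sum(vapply(x$species, function(s) s$compartment == "intracellular",
                 logical(1))), " intracellular)\n", sep = "")
  cat("  reactions:", length(x$reactions), "\n")
  cat("  clamped:  ", paste(x$clamped, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Species ids of a model
#' @param model A `network_model`.
#' @param compartment Optional filter.
#' @return Character vector of ids.
#' @export
species_ids <- function(model, compartment = NULL) {
  ids <- names(model$species)
  if (!is.null(compartment))
    ids <- ids[vapply(model$species, function(s) s$compartment == compartment,
                      logical(1))]
  ids
}

#' Reaction ids of a model
#' @param model A `network_model`.
#' @return Character vector of ids.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Stoichiometric matrix
#'
#' @param model A `network_model`.
#' @return Numeric matrix, species in rows and reactions in columns.
#' @export
stoichiometric_matrix <- function(model) {
  sp <- names(model$species)
  rx <- names(model$reactions)
  N <- matrix(0, length(sp), length(rx), dimnames = list(sp, rx))
  for (r in model$reactions)
    N[names(r$stoichiometry), r$id] <- r$stoichiometry
  N
}

#' Backbone pathway order of metabolites
#'
#' Returns, for every intracellular metabolite consumed by a non-branch
#' reaction, the consuming backbone reaction and its pathway index. This is
#' the ordering used to localize an enzyme with deviating temperature
#' sensitivity from the pattern of deviating metabolites.
#'
#' @param model A `network_model` whose reactions carry `pathway_index`.
#' @return Data frame with columns `metabolite`, `boundary_reaction`,
#'   `position`, sorted by pathway position.
#' @export
metabolite_pathway <- function(model) {
  rows <- list()
  for (r in model$reactions) {
    if (r$branch || is.na(r$pathway_index)) next
    subs <- names(r$stoichiometry)[r$stoichiometry < 0]
    for (s in subs) {
      if (model$species[[s]]$compartment != "intracellular") next
      rows[[length(rows) + 1L]] <-
        data.frame(metabolite = s, boundary_reaction = r$id,
                   position = r$pathway_index, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  # keep the first (most upstream) backbone consumer per metabolite
  out <- out[!duplicated(out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a network model
#'
#' Checks the structural invariants: declared species, unique ids, at least
#' one substrate per reaction, positive constants, clamped coverage of the
#' extracellular compartment, and that every rate-law constant refers to a
#' declared species.
#'
#' @param model A `network_model`.
#' @return Invisibly, a data frame of check results (`check`, `ok`, `detail`).
#'   Fails with an error if any check fails and `error = TRUE`.
#' @param error Whether to raise an error on failure.
#' @export
validate_model <- function(model, error = TRUE) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, ok = ok,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  sp_ids <- names(model$species)
  add("unique species ids", !anyDuplicated(sp_ids))
  add("unique reaction ids", !anyDuplicated(names(model$reactions)))
  ext <- species_ids(model, "extracellular")
  add("extracellular species clamped", all(ext %in% model$clamped),
      paste(setdiff(ext, model$clamped), collapse = ", "))
  for (r in model$reactions) {
    law <- r$rate_law
    refs <- c(names(law$km_substrates), names(law$km_products),
              names(law$effector_constants))
    add(paste0("rate-law species declared [", r$id, "]"),
        all(refs %in% sp_ids), paste(setdiff(refs, sp_ids), collapse = ", "))
    add(paste0("has substrate [", r$id, "]"), any(r$stoichiometry < 0))
    add(paste0("vmax_ref >= 0 [", r$id, "]"), law$vmax_ref >= 0)
    if (law$kind == "reversible_mm")
      add(paste0("keq_ref > 0 [", r$id, "]"),
          !is.null(law$keq_ref) && law$keq_ref > 0)
    if (is.null(law$rate_fn_missing) && law$kind == "unmapped")
      add(paste0("rate law resolved [", r$id, "]"), FALSE, "unmapped rate law")
  }
  out <- do.call(rbind, checks)
  if (error && !all(out$ok)) {
    bad <- out[!out$ok, ]
    stop("model validation failed:\n",
         paste0("  - ", bad$check,
                ifelse(nzchar(bad$detail), paste0(" (", bad$detail, ")"), ""),
                collapse = "\n"),
         call. = FALSE)
  }
  invisible(out)
}
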