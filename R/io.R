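#' Load a kinetic model definition
#'
#' The native format is a YAML document with top-level keys `name`,
#' `species` (list of `{id, compartment}`), `reactions` (list of
#' `{id, pathway_index, branch, stoichiometry, rate_law}`) and `clamped`.
#' The `rate_law` map holds `kind`, `vmax_ref` and the optional
#' `km_substrates`, `km_products`, `keq_ref`, `effector_constants`.
#' SBML files (read-only, structural subset) are detected by extension or can
#' be forced with `format = "sbml"`; see [load_sbml()].
#'
#' @param path File path.
#' @param format `"auto"`, `"yaml"` or `"sbml"`.
#' @return A validated `network_model`.
#' @export
load_model <- function(path, format = c("auto", "yaml", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("model file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "yaml"
  if (format == "sbml") return(load_sbml(path))
  doc <- yaml::read_yaml(path)
  for (key in c("species", "reactions"))
    if (is.null(doc[[key]]))
      stop_config("model file lacks required key `", key, "`")
  sp <- lapply(doc$species, function(s) {
    if (is.null(s$id) || is.null(s$compartment))
      stop_config("species entries need `id` and `compartment`")
    species(s$id, s$compartment)
  })
  rx <- lapply(doc$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry) || is.null(r$rate_law))
      stop_config("reaction entries need `id`, `stoichiometry`, `rate_law`")
    law <- r$rate_law
    reaction(
      id = r$id,
      stoichiometry = unlist(r$stoichiometry),
      rate_law = rate_law(
        kind = law$kind,
        vmax_ref = law$vmax_ref,
        km_substrates = if (length(law$km_substrates))
          unlist(law$km_substrates) else numeric(),
        km_products = if (length(law$km_products))
          unlist(law$km_products) else numeric(),
        keq_ref = law$keq_ref,
        effector_constants = if (length(law$effector_constants))
          unlist(law$effector_constants) else numeric()),
      pathway_index = if (is.null(r$pathway_index)) NA_integer_
                      else r$pathway_index,
      branch = isTRUE(r$branch))
  })
  model <- network_model(sp, rx,
                         clamped = as.character(unlist(doc$clamped)),
                         name = if (is.null(doc$name)) "model" else doc$name)
  validate_model(model)
  model
}

#' Save a kinetic model definition
#'
#' Writes the YAML representation read back identically by [load_model()].
#'
#' @param model A `network_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  doc <- list(
    name = model$name,
    species = lapply(unname(model$species), function(s)
      list(id = s$id, compartment = s$compartment)),
    reactions = lapply(unname(model$reactions), function(r) {
      law <- r$rate_law
      law_doc <- list(kind = law$kind, vmax_ref = law$vmax_ref)
      if (length(law$km_substrates))
        law_doc$km_substrates <- as.list(law$km_substrates)
      if (length(law$km_products))
        law_doc$km_products <- as.list(law$km_products)
      if (!is.null(law$keq_ref)) law_doc$keq_ref <- law$keq_ref
      if (length(law$effector_constants))
        law_doc$effector_constants <- as.list(law$effector_constants)
      out <- list(id = r$id, stoichiometry = as.list(r$stoichiometry),
                  rate_law = law_doc)
      if (!is.na(r$pathway_index)) out$pathway_index <- r$pathway_index
      if (r$branch) out$branch <- TRUE
      out
    }),
    clamped = as.list(model$clamped))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The packaged reduced glycolysis model
#'
#' Loads `models/reduced_glycolysis.yaml` shipped with the package: a
#' nine-reaction anaerobic glycolysis backbone (glucose transport, upper and
#' lower glycolysis lumped where cofactor-independent, an ethanol/CO2 sink and
#' a small glycerol branch) with buffered cofactors omitted. See the methods
#' vignette for the calibration rationale.
#'
#' @return A `network_model`.
#' @export
reduced_glycolysis <- function() {
  path <- system.file("models", "reduced_glycolysis.yaml",
                      package = "glycotherm")
  if (!nzchar(path)) stop_config("packaged model file not found")
  load_model(path)
}

#' Structural SBML import (read-only subset)
#'
#' Reads species, compartments and reaction stoichiometry from an SBML Level
#' 2/3 file with xml2. Kinetic laws are MathML and are NOT translated: every
#' reaction is imported with an `unmapped` placeholder capacity of 0 and
#' listed in the `unmapped_laws` attribute. Such a model passes structural
#' validation but [solve_steady_state()] and [simulate_network()] refuse to
#' run it until rate laws are supplied (all capacities zero triggers the
#' degenerate-input path).
#'
#' @param path SBML file path.
#' @return A `network_model` with attribute `unmapped_laws` (character vector
#'   of reaction ids whose kinetic laws were not representable).
#' @export
load_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  sp_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  if (!length(sp_nodes)) stop_config("no species found in SBML file")
  comp_of <- function(node) {
    cmp <- xml2::xml_attr(node, "compartment")
    bc <- xml2::xml_attr(node, "boundaryCondition")
    if (identical(bc, "true") || grepl("ext", cmp, ignore.case = TRUE))
      "extracellular" else "intracellular"
  }
  sp <- lapply(sp_nodes, function(n)
    species(xml2::xml_attr(n, "id"), comp_of(n)))
  sp_ids <- vapply(sp, function(s) s$id, character(1))
  boundary <- sp_ids[vapply(sp_nodes, function(n)
    identical(xml2::xml_attr(n, "boundaryCondition"), "true"), logical(1))]

  rx_nodes <- xml2::xml_find_all(doc,
                                 ".//sbml:listOfReactions/sbml:reaction", ns)
  unmapped <- character()
  rx <- lapply(seq_along(rx_nodes), function(i) {
    n <- rx_nodes[[i]]
    id <- xml2::xml_attr(n, "id")
    coef <- function(xpath, sign) {
      refs <- xml2::xml_find_all(n, xpath, ns)
      if (!length(refs)) return(numeric())
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    st <- c(coef(".//sbml:listOfReactants/sbml:speciesReference", -1),
            coef(".//sbml:listOfProducts/sbml:speciesReference", 1))
    unmapped <<- c(unmapped, id) # kinetic laws are never translated
    reaction(id, st, rate_law("mass_action", vmax_ref = 0),
             pathway_index = i)
  })
  model <- network_model(sp, rx, clamped = boundary, name = "sbml_import")
  # clamp the boundary species plus anything flagged extracellular
  model$clamped <- union(boundary, species_ids(model, "extracellular"))
  attr(model, "unmapped_laws") <- unmapped
  if (length(unmapped))
    warning("SBML import: kinetic laws not representable for ",
            length(unmapped), " reaction(s); capacities set to 0 and ",
            "simulation will refuse to run until rate laws are supplied")
  model
}

#' Write a table as CSV with a provenance header
#'
#' Comma-separated, '.' decimal, UTF-8, header row; provenance (package
#' version, seed, config hash) is written as leading `#` comment lines that
#' [read_gt_csv()] skips.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Integer seed recorded in the header (or `NA`).
#' @param config Optional list hashed into the header.
#' @return Invisibly, `path`.
#' @export
write_gt_csv <- function(x, path, seed = NA_integer_, config = NULL) {
  hash <- if (is.null(config)) "none" else config_hash(config)
  header <- c(
    paste0("# glycotherm ", as.character(utils::packageVersion("glycotherm"))),
    paste0("# seed: ", seed),
    paste0("# config_hash: ", hash),
    paste0("# written: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gt_csv
#' @export
read_gt_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Deterministic hash of a configuration list
#' @param config A list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE, digits = NA)
  # small polynomial rolling hash over the serialized config; session-stable
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 1e9
  sprintf("%09d", h)
}

#' Write a collapse report as JSON
#'
#' @param report A `collapse_report` from [analyze_collapse()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_collapse_report <- function(report, path) {
  out <- list(
    package = as.character(utils::packageVersion("glycotherm")),
    theta = report$theta,
    n_perm = report$n_perm,
    seed = report$seed,
    scores = report$scores,
    localization = list(
      candidate = if (is.null(report$localization$candidate)) NULL
                  else report$localization$candidate,
      pattern = report$localization$pattern))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
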