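# SBML Level 3 Version 1 export of the assembly network with mass-action
# kinetic laws, written directly with xml2 (core package only; amounts in
# molecules per cell, one unit-volume compartment).

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"

# canonical label -> SBML id: "G.R.E(gr)" -> "G_R_E_gr", "G()" -> "G"
.sbml_id <- function(label) {
  id <- gsub("[().]+", "_", label)
  gsub("_+$", "", id)
}

#' Export a parameterised network as SBML Level 3
#'
#' Writes an SBML L3V1 document: one unit compartment, every species with its
#' initial amount (free monomers and fixed pools at their configured totals,
#' all complexes at zero), `boundaryCondition="true"` on the fixed ribosome
#' pools (S43, S40), the 30 shared rate constants as global parameters, and a
#' mass-action kinetic law (rate constant times reactant amounts) per
#' irreversible reaction.
#'
#' @param network A staged `cap_network`.
#' @param params A [cap_params()] rate-parameter set.
#' @param totals A [cap_totals()] abundance configuration.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, params, totals, path) {
  stopifnot(inherits(network, "cap_network"))
  params <- cap_params_validate(params, network)
  x0 <- initial_amounts(network, totals)
  fixed <- fixed_species_mask(network, totals)

  ids <- vapply(network$labels, .sbml_id, character(1))
  if (anyDuplicated(ids)) stop("non-unique SBML ids", call. = FALSE)

  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "cap_binding_complex_assembly")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      spatialDimensions = "3", constant = "true")

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_along(ids)) {
    xml2::xml_add_child(los, "species", id = ids[[i]], name = network$labels[[i]],
                        compartment = "cell",
                        initialAmount = format(x0[[i]], scientific = FALSE),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = if (fixed[[i]]) "true" else "false",
                        constant = "false")
  }

  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (pn in names(params)) {
    xml2::xml_add_child(lop, "parameter", id = pn,
                        value = format(params[[pn]], digits = 17),
                        constant = "true")
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  rx <- network$reactions
  for (j in seq_len(nrow(rx))) {
    rnode <- xml2::xml_add_child(lor, "reaction", id = sprintf("r%04d", j),
                                 reversible = "false")
    lre <- xml2::xml_add_child(rnode, "listOfReactants")
    for (si in rx$reactants[[j]])
      xml2::xml_add_child(lre, "speciesReference", species = ids[[si]],
                          stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rnode, "listOfProducts")
    for (si in rx$products[[j]])
      xml2::xml_add_child(lpr, "speciesReference", species = ids[[si]],
                          stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .mathml_ns)
    apply_ <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(apply_, "times")
    xml2::xml_add_child(apply_, "ci", rx$rate_param[[j]])
    for (si in rx$reactants[[j]]) xml2::xml_add_child(apply_, "ci", ids[[si]])
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back structural counts from an SBML file
#'
#' Minimal structural reader used for round-trip checks of [export_sbml()]:
#' species/reaction/parameter counts, species ids and boundary flags.
#'
#' @param path SBML file path.
#' @return List with `n_species`, `n_reactions`, `n_parameters`,
#'   `species_ids`, `boundary_ids`.
#' @export
read_sbml_counts <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .sbml_ns)
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  pa <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  list(
    n_species = length(sp),
    n_reactions = length(rx),
    n_parameters = length(pa),
    species_ids = xml2::xml_attr(sp, "id"),
    boundary_ids = xml2::xml_attr(sp, "id")[xml2::xml_attr(sp, "boundaryCondition") == "true"]
  )
}
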