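#' Export a network to SBML
#'
#' Writes an SBML Level 3 Version 1 document (core constructs only: two
#' compartments, species, reactions with stoichiometry and reversibility)
#' for interoperability with constraint-based and kinetic tools.  The
#' tabular TSV dialect remains the source of truth; this export carries the
#' same structural content.
#'
#' @param net A `ccm_network`.
#' @param path Output `.xml` path.
#' @return Invisibly, the path.
#' @export
write_sbml <- function(net, path) {
  stopifnot(inherits(net, "ccm_network"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1"
  )
  model <- xml2::xml_add_child(doc, "model", id = "ll2_ccm")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "blood", constant = "false")
  xml2::xml_add_child(comps, "compartment", id = "cell", constant = "false")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    xml2::xml_add_child(
      sps, "species", id = m$id, name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false",
      boundaryCondition = if (m$compartment == "blood") "true" else "false",
      constant = "false"
    )
  }
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    node <- xml2::xml_add_child(
      rxns, "reaction", id = r$id,
      reversible = tolower(as.character(r$reversible)), fast = "false"
    )
    s <- r$stoichiometry[[1]]
    subs <- s[s < 0]; prods <- s[s > 0]
    if (length(subs)) {
      ls <- xml2::xml_add_child(node, "listOfReactants")
      for (nm in names(subs)) {
        xml2::xml_add_child(ls, "speciesReference", species = nm,
                            stoichiometry = format(-unname(subs[nm])),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (nm in names(prods)) {
        xml2::xml_add_child(lp, "speciesReference", species = nm,
                            stoichiometry = format(unname(prods[nm])),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
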