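# Network serialization: YAML config dialect and SBML Level 3 export.

#' Write a network to a YAML config file
#'
#' The dialect has `parameters:`, `species:` and `reactions:` blocks and
#' round-trips losslessly through [read_network_yaml()].
#'
#' @param network A `reaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_yaml <- function(network, path) {
  sp <- lapply(network$species, function(s) {
    out <- list(name = s$name, compartment = s$compartment,
                initial_amount = s$initial_amount, clamped = s$clamped)
    if (!is.null(s$composition)) out$composition <- as.list(s$composition)
    out
  })
  rx <- lapply(network$reactions, function(r) {
    out <- list(label = r$label,
                reactants = as.list(r$reactants),
                products = as.list(r$products),
                kf = r$kf)
    if (!(length(r$kr) == 1L && is.na(r$kr))) out$kr <- r$kr
    out
  })
  yaml::write_yaml(list(parameters = as.list(network$parameters),
                        species = sp, reactions = rx),
                   path, precision = 15L)
  invisible(path)
}

#' Read a network from a YAML config file
#'
#' @param path File written by [write_network_yaml()] (or hand-authored in the
#'   same dialect).
#' @return A validated `reaction_network`.
#' @export
read_network_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sp <- lapply(cfg$species, function(s) {
    species(name = s$name, compartment = s$compartment,
            initial_amount = s$initial_amount,
            clamped = isTRUE(s$clamped),
            composition = if (!is.null(s$composition)) unlist(s$composition))
  })
  rx <- lapply(cfg$reactions, function(r) {
    reaction(label = r$label,
             reactants = unlist(r$reactants) %||% numeric(0),
             products = unlist(r$products) %||% numeric(0),
             kf = r$kf, kr = if (is.null(r$kr)) NA else r$kr)
  })
  reaction_network(sp, rx, unlist(cfg$parameters) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sbml_mathml_product <- function(doc_ns, k, side) {
  # <apply><times/> k c1 c1 ... </apply> honouring integer exponents
  terms <- c(list(k), unlist(lapply(seq_along(side), function(i) {
    rep(list(names(side)[i]), side[[i]])
  }), recursive = FALSE))
  terms
}

#' Export a network as SBML Level 3
#'
#' Writes species, compartments, parameters and reactions with explicit
#' mass-action kinetic laws (MathML). Reversible reactions carry the net
#' forward-minus-reverse rate. Intended for interoperability; the file is not
#' read back by this package.
#'
#' @param network A `reaction_network`.
#' @param path Output file path.
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path, model_id = "mapkcross_model") {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  ci <- function(x) paste0("<ci> ", esc(x), " </ci>")
  prod_math <- function(kname, side) {
    terms <- c(ci(kname), unlist(lapply(seq_along(side), function(i) {
      rep(ci(names(side)[i]), side[[i]])
    })))
    if (length(terms) == 1L) terms else {
      paste0("<apply><times/>", paste(terms, collapse = ""), "</apply>")
    }
  }
  comps <- unique(vapply(network$species, function(s) s$compartment, character(1)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    sprintf('<model id="%s" timeUnits="time">', model_id),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>', comps),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (s in network$species) {
    lines <- c(lines, sprintf(
      '<species id="%s" compartment="%s" initialAmount="%.15g" hasOnlySubstanceUnits="true" boundaryCondition="%s" constant="false"/>',
      s$name, s$compartment, s$initial_amount,
      if (s$clamped) "true" else "false"))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  for (pn in names(network$parameters)) {
    lines <- c(lines, sprintf('<parameter id="%s" value="%.15g" constant="true"/>',
                              pn, network$parameters[[pn]]))
  }
  lines <- c(lines, "</listOfParameters>", "<listOfReactions>")
  pname <- function(k, fallback) if (is.character(k)) k else fallback
  extra <- character(0)
  for (r in network$reactions) {
    reversible <- !(length(r$kr) == 1L && (is.na(r$kr) ||
                                           identical(r$kr, 0)))
    kf_id <- pname(r$kf, paste0("kf_", r$label))
    if (!is.character(r$kf)) {
      extra <- c(extra, sprintf('<parameter id="%s" value="%.15g" constant="true"/>',
                                kf_id, r$kf))
    }
    math <- prod_math(kf_id, r$reactants)
    if (reversible) {
      kr_id <- pname(r$kr, paste0("kr_", r$label))
      if (!is.character(r$kr)) {
        extra <- c(extra, sprintf('<parameter id="%s" value="%.15g" constant="true"/>',
                                  kr_id, r$kr))
      }
      math <- paste0("<apply><minus/>", math, prod_math(kr_id, r$products),
                     "</apply>")
    }
    side_xml <- function(side, tag) {
      if (!length(side)) return(character(0))
      c(sprintf("<listOf%s>", tag),
        sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                names(side), as.integer(side)),
        sprintf("</listOf%s>", tag))
    }
    lines <- c(lines,
               sprintf('<reaction id="%s" reversible="%s">', r$label,
                       if (reversible) "true" else "false"),
               side_xml(r$reactants, "Reactants"),
               side_xml(r$products, "Products"),
               "<kineticLaw>",
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               math, "</math>", "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  if (length(extra)) {
    ins <- which(lines == "</listOfParameters>")[1]
    lines <- append(lines, extra, after = ins - 1L)
  }
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}
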