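# SBML Level 3 Version 1 + fbc version 2 input/output, built on xml2.
#
# The writer emits one parameter per flux bound, fbc gene products with
# nested and/or geneProductAssociation trees, and one fbc objective per
# biomass variant (the active objective is the model objective). The reader
# accepts any L3+fbc file of that shape and, as a fallback, L2 files with
# bounds in kineticLaw parameters and GPRs in "GENE_ASSOCIATION:" notes.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a model as SBML Level 3 + fbc version 2
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "false")

  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments)))
    xml2::xml_add_child(lc, "compartment",
                        id = model$compartments$id[i],
                        name = model$compartments$name[i],
                        constant = "true")

  if (nrow(model$metabolites)) {
    ls <- xml2::xml_add_child(mod, "listOfSpecies")
    for (i in seq_len(nrow(model$metabolites))) {
      sp <- xml2::xml_add_child(
        ls, "species",
        id = model$metabolites$id[i],
        name = model$metabolites$name[i],
        compartment = model$metabolites$compartment[i],
        hasOnlySubstanceUnits = "false",
        boundaryCondition = "false", constant = "false")
      ch <- model$metabolites$charge[i]
      if (!is.na(ch)) xml2::xml_set_attr(sp, "fbc:charge", as.character(ch))
      f <- model$metabolites$formula[i]
      if (!is.na(f) && nzchar(f)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", f)
    }
  }

  lp <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    xml2::xml_add_child(lp, "parameter", id = paste0(rid, "_lb"),
                        value = format(model$reactions$lower_bound[i], digits = 17),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(rid, "_ub"),
                        value = format(model$reactions$upper_bound[i], digits = 17),
                        constant = "true")
  }

  gpr_to_xml <- function(parent, tree) {
    if (is.character(tree)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = tree)
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
      for (a in tree$args) gpr_to_xml(node, a)
    }
    invisible(NULL)
  }

  if (nrow(model$reactions)) {
    lr <- xml2::xml_add_child(mod, "listOfReactions")
    for (i in seq_len(nrow(model$reactions))) {
      rid <- model$reactions$id[i]
      rx <- xml2::xml_add_child(
        lr, "reaction", id = rid, name = model$reactions$name[i],
        reversible = if (model$reactions$lower_bound[i] < 0) "true" else "false",
        fast = "false",
        "fbc:lowerFluxBound" = paste0(rid, "_lb"),
        "fbc:upperFluxBound" = paste0(rid, "_ub"))
      subsys <- model$reactions$subsystem[i]
      if (!is.na(subsys) && nzchar(subsys)) {
        notes <- xml2::xml_add_child(rx, "notes")
        body <- xml2::xml_add_child(notes, "body",
                                    xmlns = "http://www.w3.org/1999/xhtml")
        xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", subsys))
      }
      coefs <- model$S[, rid]
      part <- names(coefs)[coefs != 0]
      reac <- part[coefs[part] < 0]
      prod <- part[coefs[part] > 0]
      if (length(reac)) {
        n <- xml2::xml_add_child(rx, "listOfReactants")
        for (s in reac)
          xml2::xml_add_child(n, "speciesReference", species = s,
                              stoichiometry = format(-coefs[[s]], digits = 17),
                              constant = "true")
      }
      if (length(prod)) {
        n <- xml2::xml_add_child(rx, "listOfProducts")
        for (s in prod)
          xml2::xml_add_child(n, "speciesReference", species = s,
                              stoichiometry = format(coefs[[s]], digits = 17),
                              constant = "true")
      }
      g <- model$reactions$gpr[i]
      if (!is.na(g) && nzchar(g)) {
        gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
        gpr_to_xml(gpa, gpr_parse(g))
      }
    }
  }

  variants <- model$biomass_variants
  if (is.na(model$objective)) variants <- character()
  else if (!length(variants) || !model$objective %in% variants)
    variants <- c(variants, main = model$objective)
  active <- names(variants)[match(model$objective, variants)]
  if (length(variants)) {
  lo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                            "fbc:activeObjective" = paste0("obj_", active))
  for (nm in names(variants)) {
    ob <- xml2::xml_add_child(lo, "fbc:objective",
                              "fbc:id" = paste0("obj_", nm),
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = variants[[nm]],
                        "fbc:coefficient" = "1")
  }
  }

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = g,
                          "fbc:label" = g)
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

# namespace-agnostic helpers: SBML files differ in the prefixes they use
# for the core and fbc namespaces, so elements are matched by local name
# and attributes by their name after any prefix.
lpath <- function(path, prefix = "./") {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  paste0(prefix, paste0("*[local-name()='", parts, "']", collapse = "/"))
}
find_all_l <- function(node, path) xml2::xml_find_all(node, lpath(path))
find_first_l <- function(node, path, prefix = "./")
  xml2::xml_find_first(node, lpath(path, prefix))

fbc_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == name)
  if (length(hit)) unname(at[[hit[1]]]) else NA_character_
}

xml_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(fbc_attr(node, "geneProduct"))
  if (nm %in% c("and", "or"))
    return(list(op = nm,
                args = lapply(xml2::xml_children(node), xml_gpr)))
  stop("unexpected node in geneProductAssociation: ", nm)
}

#' Read an SBML metabolic model
#'
#' Accepts SBML Level 3 Version 1 with the fbc (version 2) package — flux
#' bounds as parameters, gene products, and objectives — and falls back to
#' Level 2 conventions (bounds in kineticLaw parameters named
#' `LOWER_BOUND`/`UPPER_BOUND`, GPRs in `GENE_ASSOCIATION:` notes).
#' Reactions with no stated bounds default to (-1000, 1000) when marked
#' reversible and (0, 1000) otherwise, with a warning. Reaction kinds
#' (exchange, transport, ...) are re-inferred from structure on load.
#'
#' @param path SBML file path.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  mod <- find_first_l(doc, "model", prefix = ".//")
  if (inherits(mod, "xml_missing")) stop("no <model> element in ", path)
  level <- xml2::xml_attr(doc, "level")

  comp_nodes <- find_all_l(mod, "listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
                  xml2::xml_attr(comp_nodes, "id"),
                  xml2::xml_attr(comp_nodes, "name")))

  sp_nodes <- find_all_l(mod, "listOfSpecies/species")
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = vapply(sp_nodes, function(n) {
      f <- fbc_attr(n, "chemicalFormula"); if (is.na(f)) "" else f
    }, character(1)),
    charge = vapply(sp_nodes, function(n) {
      ch <- fbc_attr(n, "charge")
      if (is.na(ch)) NA_integer_ else as.integer(ch)
    }, integer(1)))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  keep <- !boundary  # boundary species are outside the balanced system
  metabolites <- metabolites[keep, , drop = FALSE]

  par_nodes <- find_all_l(mod, "listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- find_all_l(mod, "listOfReactions/reaction")
  nrx <- length(rx_nodes)
  ids <- xml2::xml_attr(rx_nodes, "id")
  rnames <- ifelse(is.na(xml2::xml_attr(rx_nodes, "name")), ids,
                   xml2::xml_attr(rx_nodes, "name"))
  rev <- xml2::xml_attr(rx_nodes, "reversible") %in% c("true", NA)

  trip <- vector("list", nrx)
  lb <- numeric(nrx); ub <- numeric(nrx)
  gpr <- character(nrx); subsystem <- character(nrx)
  warned_default <- FALSE
  for (i in seq_len(nrx)) {
    node <- rx_nodes[[i]]
    sto <- list()
    for (sr in find_all_l(node, "listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      sto[[s]] <- (if (is.null(sto[[s]])) 0 else sto[[s]]) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in find_all_l(node, "listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      sto[[s]] <- (if (is.null(sto[[s]])) 0 else sto[[s]]) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    trip[[i]] <- sto

    lbp <- fbc_attr(node, "lowerFluxBound")
    ubp <- fbc_attr(node, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(par_val)) {
      lb[i] <- par_val[[lbp]]
      ub[i] <- par_val[[ubp]]
    } else {
      klb <- xml2::xml_find_first(
        node, paste0(lpath("kineticLaw"), "//*[local-name()='parameter'][@id='LOWER_BOUND']"))
      kub <- xml2::xml_find_first(
        node, paste0(lpath("kineticLaw"), "//*[local-name()='parameter'][@id='UPPER_BOUND']"))
      if (!inherits(klb, "xml_missing")) {
        lb[i] <- as.numeric(xml2::xml_attr(klb, "value"))
        ub[i] <- as.numeric(xml2::xml_attr(kub, "value"))
      } else {
        lb[i] <- if (rev[i]) -1000 else 0
        ub[i] <- 1000
        warned_default <- TRUE
      }
    }

    gpa <- find_first_l(node, "geneProductAssociation")
    if (!inherits(gpa, "xml_missing")) {
      gpr[i] <- gpr_serialize(xml_gpr(xml2::xml_child(gpa)))
    } else {
      note <- xml2::xml_text(find_first_l(node, "notes"))
      ga <- regmatches(note, regexpr("GENE_ASSOCIATION:[^\n]*", note))
      gpr[i] <- if (length(ga)) trimws(sub("GENE_ASSOCIATION:", "", ga)) else ""
    }
    note <- xml2::xml_text(find_first_l(node, "notes"))
    ss <- regmatches(note, regexpr("SUBSYSTEM:[^\n]*", note))
    subsystem[i] <- if (length(ss)) trimws(sub("SUBSYSTEM:", "", ss)) else ""
  }
  if (warned_default)
    warning("some reactions had no flux bounds; defaulted to +/-1000")

  S <- Matrix::Matrix(0, nrow(metabolites), nrx, sparse = TRUE,
                      dimnames = list(metabolites$id, ids))
  for (i in seq_len(nrx)) {
    sto <- trip[[i]]
    sto <- sto[names(sto) %in% metabolites$id]  # drop boundary species
    if (length(sto)) S[names(sto), i] <- unlist(sto)
  }

  gp_nodes <- find_all_l(mod, "listOfGeneProducts/geneProduct")
  genes <- vapply(gp_nodes, function(n) fbc_attr(n, "id"), character(1))
  if (!length(genes)) genes <- NULL

  obj_list <- find_first_l(mod, "listOfObjectives")
  objective <- NULL
  variants <- character()
  if (!inherits(obj_list, "xml_missing")) {
    active <- fbc_attr(obj_list, "activeObjective")
    for (ob in find_all_l(obj_list, "objective")) {
      oid <- fbc_attr(ob, "id")
      rxn <- fbc_attr(find_first_l(
        ob, "listOfFluxObjectives/fluxObjective"), "reaction")
      nm <- sub("^obj_", "", oid)
      variants[nm] <- rxn
      if (identical(oid, active)) objective <- rxn
    }
  }
  if (is.null(objective)) {
    cand <- ids[grepl("biomass|^BIO", ids, ignore.case = TRUE)]
    objective <- if (length(cand)) cand[1] else NA_character_
    if (is.na(objective) && length(ids)) stop("no objective found in ", path)
  }
  variants <- variants[names(variants) != "main"]

  metabolic_model(
    id = if (is.na(xml2::xml_attr(mod, "id"))) "model" else xml2::xml_attr(mod, "id"),
    compartments = compartments, metabolites = metabolites,
    reactions = data.frame(id = ids, name = rnames, lower_bound = lb,
                           upper_bound = ub, subsystem = subsystem, gpr = gpr),
    S = S, genes = genes, objective = objective,
    biomass_variants = variants)
}
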