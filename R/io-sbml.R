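# SBML input/output.  Written files are Level 3 Version 1 with the fbc
# version 2 extension (flux bounds as parameters, GPRs as
# geneProductAssociations, an active maximisation objective).  Reading
# supports that dialect plus the older SEED-style Level 2 encoding
# (bounds as kineticLaw parameters LOWER_BOUND/UPPER_BOUND, GPRs in
# GENE_ASSOCIATION notes, objective via OBJECTIVE_COEFFICIENT), which is
# how genome-scale reconstructions of that era were deposited.
# Conventional id prefixes (M_ species, R_ reactions, G_ genes) are added
# on write and stripped on read.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
num17 <- function(x) vapply(x, function(v) format(v, digits = 17, trim = TRUE),
                            character(1))
strip_prefix <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

#' Write a model as SBML Level 3 + fbc
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root("sbml",
                            "xmlns" = SBML_CORE_NS,
                            "xmlns:fbc" = SBML_FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sid(model$id),
                             "fbc:strict" = "false")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in if (length(model$compartments)) model$compartments else "c")
    xml2::xml_add_child(comps, "compartment", id = sid(cmp), constant = "true")
  if (nrow(model$metabolites)) {
    sps <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(model$metabolites))) {
      m <- model$metabolites[i, ]
      node <- xml2::xml_add_child(sps, "species",
                                  id = paste0("M_", sid(m$id)), name = m$name,
                                  compartment = sid(m$compartment),
                                  hasOnlySubstanceUnits = "false",
                                  boundaryCondition = tolower(m$boundary),
                                  constant = "false")
      if (!is.na(m$formula))
        xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
      if (!is.na(m$charge))
        xml2::xml_set_attr(node, "fbc:charge", as.character(m$charge))
    }
  }
  # flux bounds as shared parameters
  bounds <- unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub))))
  if (length(bounds)) {
    pars <- xml2::xml_add_child(mdl, "listOfParameters")
    bound_id <- stats::setNames(sprintf("fb_%d", seq_along(bounds)),
                                num17(bounds))
    for (b in bounds)
      xml2::xml_add_child(pars, "parameter",
                          id = bound_id[[num17(b)]],
                          value = num17(b), constant = "true")
  }
  if (length(model$genes)) {
    gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(gps, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sid(g)), "fbc:label" = g)
  }
  if (length(model$reactions)) {
    rxs <- xml2::xml_add_child(mdl, "listOfReactions")
    for (r in model$reactions) {
      node <- xml2::xml_add_child(rxs, "reaction",
                                  id = paste0("R_", sid(r$id)), name = r$name,
                                  reversible = tolower(r$lb < 0), fast = "false",
                                  "fbc:lowerFluxBound" =
                                    bound_id[[num17(r$lb)]],
                                  "fbc:upperFluxBound" =
                                    bound_id[[num17(r$ub)]])
      reac <- r$stoich[r$stoich < 0]
      prod <- r$stoich[r$stoich > 0]
      if (length(reac)) {
        lst <- xml2::xml_add_child(node, "listOfReactants")
        for (m in names(reac))
          xml2::xml_add_child(lst, "speciesReference",
                              species = paste0("M_", sid(m)),
                              stoichiometry = num17(-reac[[m]]),
                              constant = "true")
      }
      if (length(prod)) {
        lst <- xml2::xml_add_child(node, "listOfProducts")
        for (m in names(prod))
          xml2::xml_add_child(lst, "speciesReference",
                              species = paste0("M_", sid(m)),
                              stoichiometry = num17(prod[[m]]),
                              constant = "true")
      }
      tree <- parse_gpr(r$gpr)
      if (!is.null(tree)) {
        gpa <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
        sbml_write_gpr(gpa, tree)
      }
    }
  }
  if (!is.null(model$objective_id)) {
    objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    fos <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(fos, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sid(model$objective_id)),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpr <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sid(tree)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
    for (a in tree$args) sbml_write_gpr(node, a)
  }
}

#' Read a model from SBML
#'
#' Detects the dialect by namespace: SBML Level 3 with the fbc extension,
#' or SEED-style Level 2 (kinetic-law bound parameters, notes-encoded
#' gene associations).  Missing bounds default to -1000/1000 for
#' reversible and 0/1000 for irreversible reactions.  The objective is
#' taken from the active fbc objective, an OBJECTIVE_COEFFICIENT
#' parameter, or — failing both — the first reaction whose id or name
#' contains "biomass".
#'
#' @param path SBML file path.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  ln <- function(node, name)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  mdl <- ln(doc, "model")
  if (!length(mdl)) stop("no <model> element in '", path, "'", call. = FALSE)
  mdl <- mdl[[1]]
  level <- xml2::xml_attr(xml2::xml_root(doc), "level")

  sp_nodes <- ln(mdl, "species")
  mets <- do.call(rbind, lapply(sp_nodes, function(s) {
    metabolite(strip_prefix(xml2::xml_attr(s, "id"), "M"),
               name = xml2::xml_attr(s, "name") %||% NA_character_,
               compartment = xml2::xml_attr(s, "compartment"),
               formula = xml2::xml_attr(s, "chemicalFormula"),
               charge = suppressWarnings(as.integer(xml2::xml_attr(s, "charge"))),
               boundary = identical(xml2::xml_attr(s, "boundaryCondition"),
                                    "true"))
  }))

  # fbc flux-bound parameters and gene products
  params <- ln(mdl, "parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))
  gene_label <- character()
  for (gp in ln(mdl, "geneProduct")) {
    gid <- xml2::xml_attr(gp, "id")
    lab <- xml2::xml_attr(gp, "label")
    gene_label[gid] <- if (!is.na(lab)) lab else strip_prefix(gid, "G")
  }

  rx_nodes <- xml2::xml_find_all(mdl, sprintf(
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']"))
  rxns <- lapply(rx_nodes, function(rn) {
    rid <- strip_prefix(xml2::xml_attr(rn, "id"), "R")
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, sprintf(
      ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']"))) {
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (is.na(co)) co <- 1
      st[strip_prefix(xml2::xml_attr(sr, "species"), "M")] <- -co
    }
    for (sr in xml2::xml_find_all(rn, sprintf(
      ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']"))) {
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (is.na(co)) co <- 1
      mid <- strip_prefix(xml2::xml_attr(sr, "species"), "M")
      st[mid] <- (if (is.na(st[mid])) 0 else st[mid]) + co
    }
    st <- st[st != 0]
    # bounds: fbc parameters, else kineticLaw LOWER_BOUND/UPPER_BOUND (L2)
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbp)) par_val[[lbp]] else NA_real_
    ub <- if (!is.na(ubp)) par_val[[ubp]] else NA_real_
    obj_coef <- 0
    for (kp in xml2::xml_find_all(rn, sprintf(
      ".//*[local-name()='kineticLaw']//*[local-name()='parameter']"))) {
      pid <- toupper(xml2::xml_attr(kp, "id"))
      pval <- as.numeric(xml2::xml_attr(kp, "value"))
      if (pid == "LOWER_BOUND") lb <- pval
      if (pid == "UPPER_BOUND") ub <- pval
      if (pid == "OBJECTIVE_COEFFICIENT" && !is.na(pval)) obj_coef <- pval
    }
    if (is.na(lb)) lb <- if (rev) -1000 else 0
    if (is.na(ub)) ub <- 1000
    # GPR: fbc geneProductAssociation, else GENE_ASSOCIATION note (L2 SEED)
    gpr <- NA_character_
    gpa <- xml2::xml_find_first(rn, sprintf(
      ".//*[local-name()='geneProductAssociation']"))
    if (!inherits(gpa, "xml_missing")) {
      children <- xml2::xml_children(gpa)
      if (length(children))
        gpr <- sbml_read_gpr(children[[1]], gene_label)
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(rn, sprintf(
        ".//*[local-name()='notes']")))
      if (!is.na(notes)) {
        hit <- regmatches(notes,
                          regexpr("GENE_ASSOCIATION:[^\n<]*", notes))
        if (length(hit)) {
          ga <- trimws(sub("GENE_ASSOCIATION:", "", hit[1]))
          if (nzchar(ga)) gpr <- ga
        }
      }
    }
    list(rxn = reaction(rid, st, lb = lb, ub = ub, gpr = gpr,
                        name = xml2::xml_attr(rn, "name") %||% rid),
         obj_coef = obj_coef)
  })
  obj_id <- NULL
  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing"))
    obj_id <- strip_prefix(xml2::xml_attr(fo, "reaction"), "R")
  rx_list <- lapply(rxns, `[[`, "rxn")
  if (is.null(obj_id)) {
    coefs <- vapply(rxns, `[[`, numeric(1), "obj_coef")
    if (any(coefs != 0)) obj_id <- rx_list[[which(coefs != 0)[1]]]$id
  }
  if (is.null(obj_id)) obj_id <- guess_biomass(rx_list)
  metabolic_model(rx_list, metabolites = mets, objective_id = obj_id,
                  id = xml2::xml_attr(mdl, "id") %||% "sbml_model")
}

sbml_read_gpr <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    return(if (!is.na(gene_label[gid])) unname(gene_label[gid])
           else strip_prefix(gid, "G"))
  }
  parts <- vapply(xml2::xml_children(node), sbml_read_gpr, character(1),
                  gene_label = gene_label)
  parts <- vapply(parts, function(p)
    if (grepl(" ", p)) paste0("(", p, ")") else p, character(1))
  paste(parts, collapse = paste0(" ", nm, " "))
}
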