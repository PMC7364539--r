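# Tab-separated model dialect: a reactions table (id, name, equation,
# lb, ub, gpr, subsystem) and a metabolites table (id, name, compartment,
# formula, charge, boundary).  "#" lines are comments.  A permissive
# header-mapping layer accepts common alternative column names.

tab_header_map <- function(headers, wanted, aliases, path) {
  idx <- integer(0)
  low <- tolower(trimws(headers))
  for (w in wanted) {
    cands <- c(w, aliases[[w]])
    hit <- which(low %in% tolower(cands))
    idx[w] <- if (length(hit)) hit[1] else NA_integer_
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model from tab-separated tables
#'
#' The reactions file must name at least an id and an equation column
#' (aliases such as "reaction"/"abbreviation" and "formula"/"reaction
#' equation" are recognised); optional columns are name, lb, ub, gpr
#' (alias "gene association") and subsystem.  Equations are parsed with
#' [parse_reaction_equation()]; missing bounds default by reversibility
#' (-1000/1000 for `<->`, 0/1000 otherwise).  The metabolites file is
#' optional and contributes names/compartments/formulas.
#'
#' @param reactions_path Path to the reactions table.
#' @param metabolites_path Optional path to the metabolites table.
#' @param objective_id Objective reaction id; if `NULL`, the first
#'   reaction whose id or name contains "biomass" (case insensitive).
#' @return A [metabolic_model()].
#' @export
read_tabular_model <- function(reactions_path, metabolites_path = NULL,
                               objective_id = NULL) {
  rt <- utils::read.delim(reactions_path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  aliases <- list(id = c("reaction", "rxn", "abbreviation", "reaction id"),
                  equation = c("formula", "reaction equation", "eq"),
                  name = c("reaction name", "description"),
                  lb = c("lower_bound", "lower bound", "lowbnd"),
                  ub = c("upper_bound", "upper bound", "uppbnd"),
                  gpr = c("gene association", "gene_association", "genes",
                          "gene_reaction_rule"),
                  subsystem = c("pathway", "subsystem name"))
  idx <- tab_header_map(names(rt), names(aliases), aliases, reactions_path)
  if (is.na(idx["id"]) || is.na(idx["equation"]))
    stop("reactions table must contain id and equation columns; found: ",
         paste(names(rt), collapse = ", "), call. = FALSE)
  get_col <- function(what, default = NA) {
    if (is.na(idx[what])) rep(default, nrow(rt)) else rt[[idx[what]]]
  }
  ids <- as.character(get_col("id"))
  eqs <- as.character(get_col("equation"))
  nms <- as.character(get_col("name", NA_character_))
  lbs <- suppressWarnings(as.numeric(get_col("lb")))
  ubs <- suppressWarnings(as.numeric(get_col("ub")))
  gprs <- as.character(get_col("gpr", NA_character_))
  subs <- as.character(get_col("subsystem", NA_character_))
  rxns <- lapply(seq_len(nrow(rt)), function(i) {
    eq <- parse_reaction_equation(eqs[i])
    reaction(ids[i], eq$stoich,
             lb = if (is.na(lbs[i])) { if (eq$reversible) -1000 else 0 } else lbs[i],
             ub = if (is.na(ubs[i])) 1000 else ubs[i],
             gpr = gprs[i],
             name = if (is.na(nms[i])) ids[i] else nms[i],
             subsystem = subs[i])
  })
  mets <- NULL
  if (!is.null(metabolites_path)) {
    mt <- utils::read.delim(metabolites_path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
    m_alias <- list(id = c("metabolite", "met", "abbreviation"),
                    name = c("metabolite name", "description"),
                    compartment = c("comp", "compartment id"),
                    formula = c("chemical formula", "elemental formula"),
                    charge = c(),
                    boundary = c("boundarycondition", "boundary_condition"))
    midx <- tab_header_map(names(mt), names(m_alias), m_alias, metabolites_path)
    if (is.na(midx["id"]))
      stop("metabolites table must contain an id column; found: ",
           paste(names(mt), collapse = ", "), call. = FALSE)
    gc <- function(w, default = NA) {
      if (is.na(midx[w])) rep(default, nrow(mt)) else mt[[midx[w]]]
    }
    mids <- as.character(gc("id"))
    comp <- as.character(gc("compartment", NA_character_))
    comp[is.na(comp)] <- ifelse(grepl("_[a-z]$", mids[is.na(comp)]),
                                sub("^.*_", "", mids[is.na(comp)]), "c")
    mets <- do.call(rbind, lapply(seq_len(nrow(mt)), function(i) {
      metabolite(mids[i],
                 name = { n <- as.character(gc("name", NA_character_))[i]
                          if (is.na(n)) mids[i] else n },
                 compartment = comp[i],
                 formula = as.character(gc("formula", NA_character_))[i],
                 charge = suppressWarnings(as.integer(gc("charge", NA)))[i],
                 boundary = isTRUE(as.logical(gc("boundary", FALSE)[i])))
    }))
  }
  if (is.null(objective_id)) objective_id <- guess_biomass(rxns)
  metabolic_model(rxns, metabolites = mets, objective_id = objective_id,
                  id = sub("\\.[^.]*$", "", basename(reactions_path)))
}

guess_biomass <- function(rxns) {
  ids <- vapply(rxns, function(r) r$id, character(1))
  nms <- vapply(rxns, function(r) r$name %||% r$id, character(1))
  hit <- which(grepl("biomass", ids, ignore.case = TRUE) |
                 grepl("biomass", nms, ignore.case = TRUE))
  if (!length(hit)) NULL else ids[hit[1]]
}

#' Write a model to tab-separated tables
#'
#' @param model A [metabolic_model()].
#' @param reactions_path,metabolites_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_tabular_model <- function(model, reactions_path, metabolites_path) {
  rt <- data.frame(
    id = names(model$reactions),
    name = vapply(model$reactions, function(r) r$name, character(1)),
    equation = vapply(model$reactions, format_reaction_equation, character(1)),
    lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
    ub = vapply(model$reactions, function(r) r$ub, numeric(1)),
    gpr = vapply(model$reactions, function(r) r$gpr, character(1)),
    subsystem = vapply(model$reactions, function(r)
      as.character(r$subsystem), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(rt, reactions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(model$metabolites, metabolites_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(c(reactions_path, metabolites_path))
}
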