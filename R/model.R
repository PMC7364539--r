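#' Construct a metabolite
#'
#' @param id Unique metabolite id within the model (token, e.g. `"accoa_c"`).
#' @param name Human-readable name.
#' @param compartment Compartment token (e.g. `"c"` cytosol, `"e"`
#'   extracellular).
#' @param formula Optional elemental formula.
#' @param charge Optional integer charge.
#' @param boundary Logical; `TRUE` marks a boundary species that is excluded
#'   from mass-balance rows (the SBML `boundaryCondition` flag).
#' @return A one-row data frame.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_,
                       charge = NA_integer_, boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula), charge = as.integer(charge),
             boundary = isTRUE(boundary), stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative for consumed
#' (substrates), positive for produced (products).  Flux bounds are in
#' mmol h\eqn{^{-1}} g-DW\eqn{^{-1}} (the biomass reaction in h\eqn{^{-1}}).
#'
#' @param id Unique reaction id.
#' @param stoich Named numeric vector mapping metabolite ids to non-zero
#'   coefficients.
#' @param lb,ub Lower and upper flux bounds; defaults 0/1000 (irreversible)
#'   or -1000/1000 when `reversible = TRUE`.
#' @param gpr Optional GPR rule string (see [parse_gpr()]).
#' @param name,subsystem Optional annotation.
#' @param reversible Convenience switch used only when `lb`/`ub` are missing.
#' @return A list of class `"cf_reaction"`.
#' @export
reaction <- function(id, stoich, lb = NULL, ub = NULL, gpr = NA_character_,
                     name = id, subsystem = NA_character_, reversible = FALSE) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (length(stoich) == 0)
    stop("reaction '", id, "': empty stoichiometry", call. = FALSE)
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a named vector", call. = FALSE)
  if (any(stoich == 0))
    stop("reaction '", id, "': zero stoichiometric coefficients not allowed", call. = FALSE)
  if (anyDuplicated(names(stoich)))
    stop("reaction '", id, "': duplicate metabolite in stoichiometry", call. = FALSE)
  if (is.null(lb)) lb <- if (reversible) -1000 else 0
  if (is.null(ub)) ub <- 1000
  if (lb > ub)
    stop("reaction '", id, "': lower bound exceeds upper bound", call. = FALSE)
  parse_gpr(gpr)  # fail early on malformed rules
  structure(list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
                 gpr = if (is.null(gpr)) NA_character_ else gpr,
                 subsystem = subsystem),
            class = "cf_reaction")
}

#' Assemble a constraint-based metabolic model
#'
#' @param reactions List of [reaction()] objects.
#' @param metabolites Data frame of [metabolite()] rows.  Metabolites
#'   referenced by reactions but absent here are added automatically with
#'   compartment guessed from an `_x` id suffix.
#' @param objective_id Id of the objective (biomass) reaction.
#' @param id Model id.
#' @param genes Character vector of gene ids; defaults to the union of all
#'   GPR genes.
#' @return A list of class `"metabolic_model"` with fields `metabolites`
#'   (data frame), `reactions` (named list), `genes`, `objective_id`,
#'   `compartments`.
#' @export
metabolic_model <- function(reactions, metabolites = NULL, objective_id = NULL,
                            id = "model", genes = NULL) {
  stopifnot(is.list(reactions))
  rids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "),
         call. = FALSE)
  names(reactions) <- rids
  if (is.null(metabolites))
    metabolites <- metabolite("..dummy")[0, ]
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids", call. = FALSE)
  referenced <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  missing_m <- setdiff(referenced, metabolites$id)
  if (length(missing_m)) {
    guessed <- do.call(rbind, lapply(missing_m, function(m) {
      comp <- sub("^.*_([a-z])$", "\\1", m)
      if (identical(comp, m)) comp <- "c"
      metabolite(m, compartment = comp)
    }))
    metabolites <- rbind(metabolites, guessed)
  }
  gpr_all <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  if (is.null(genes)) genes <- gpr_all
  model <- structure(list(id = id,
                          metabolites = metabolites,
                          reactions = reactions,
                          genes = sort(unique(genes)),
                          objective_id = objective_id,
                          compartments = sort(unique(metabolites$compartment))),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness, that every metabolite referenced by a reaction
#' exists, that every GPR gene is declared, that bounds are ordered and
#' that the objective reaction exists.
#'
#' @param model A [metabolic_model()].
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mids <- model$metabolites$id
  if (anyDuplicated(mids)) stop("duplicate metabolite ids", call. = FALSE)
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), mids)
    if (length(unknown))
      stop("reaction '", r$id, "' references unknown metabolite '",
           unknown[1], "'", call. = FALSE)
    if (r$lb > r$ub)
      stop("reaction '", r$id, "': lower bound exceeds upper bound", call. = FALSE)
    bad_genes <- setdiff(gpr_genes(r$gpr), model$genes)
    if (length(bad_genes))
      stop("reaction '", r$id, "' GPR uses undeclared gene '", bad_genes[1], "'",
           call. = FALSE)
  }
  if (!is.null(model$objective_id) &&
      !model$objective_id %in% names(model$reactions))
    stop("objective reaction '", model$objective_id, "' not in model", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Constraint-based metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " (", sum(!x$metabolites$boundary), " balanced)\n", sep = "")
  cat("  reactions:   ", length(x$reactions),
      " (", length(find_exchanges(x)), " exchanges)\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  cat("  objective:   ", if (is.null(x$objective_id)) "<none>" else x$objective_id,
      "\n", sep = "")
  invisible(x)
}

#' Number of reactions / metabolites / genes
#' @param model A [metabolic_model()].
#' @return Integer count.
#' @export
n_reactions <- function(model) length(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' @rdname n_reactions
#' @export
n_genes <- function(model) length(model$genes)

#' Assemble the stoichiometric matrix
#'
#' Builds the dense matrix S (balanced metabolites x reactions) with
#' `S[i, j]` the coefficient of metabolite i in reaction j.  Boundary
#' species (`boundary = TRUE`) are excluded from the rows: they are the
#' open ends of the system and carry no mass-balance constraint.
#'
#' @param model A [metabolic_model()].
#' @param drop_boundary Exclude boundary metabolites (default `TRUE`).
#' @return A numeric matrix with metabolite ids as rownames and reaction
#'   ids as colnames.
#' @export
build_stoichiometric_matrix <- function(model, drop_boundary = TRUE) {
  validate_model(model)
  mets <- model$metabolites
  if (drop_boundary) mets <- mets[!mets$boundary, , drop = FALSE]
  S <- matrix(0, nrow(mets), length(model$reactions),
              dimnames = list(mets$id, names(model$reactions)))
  for (r in model$reactions) {
    keep <- names(r$stoich) %in% mets$id
    if (any(keep)) S[names(r$stoich)[keep], r$id] <- r$stoich[keep]
  }
  S
}

#' Identify exchange reactions
#'
#' An exchange reaction moves a single metabolite across the system
#' boundary: after dropping boundary species it touches exactly one
#' metabolite.  The objective (biomass) reaction is never classified as an
#' exchange.  Under the export-positive convention positive flux secretes
#' the metabolite and uptake is a negative flux, so uptake is limited by
#' the exchange's lower bound.
#'
#' @param model A [metabolic_model()].
#' @return Character vector of exchange reaction ids.
#' @export
find_exchanges <- function(model) {
  boundary_ids <- model$metabolites$id[model$metabolites$boundary]
  ids <- vapply(model$reactions, function(r) {
    eff <- setdiff(names(r$stoich), boundary_ids)
    length(eff) == 1 && !identical(r$id, model$objective_id)
  }, logical(1))
  names(model$reactions)[ids]
}

#' Metabolite carried by an exchange reaction
#' @param model A [metabolic_model()].
#' @param rxn_id Exchange reaction id.
#' @return Metabolite id.
#' @export
exchange_metabolite <- function(model, rxn_id) {
  r <- model$reactions[[rxn_id]]
  if (is.null(r)) stop("unknown reaction '", rxn_id, "'", call. = FALSE)
  boundary_ids <- model$metabolites$id[model$metabolites$boundary]
  eff <- setdiff(names(r$stoich), boundary_ids)
  if (length(eff) != 1)
    stop("reaction '", rxn_id, "' is not an exchange", call. = FALSE)
  eff
}

# base metabolite name: strip a trailing _<compartment> token
met_base_name <- function(id) sub("_[a-z][a-z0-9]?$", "", id)

#' Default freely exchanged species
#'
#' Species a minimal mineral-salts medium (the nitrate mineral salts medium
#' used for Methylocella) supplies without limit: oxygen, water, protons,
#' phosphate, ammonium/nitrate, sulfate and trace ions.  Their uptake is
#' left open by [apply_medium()]; everything else is closed and must be
#' granted explicitly.  CO2 needs no special casing: exports are always
#' open (upper bounds are never touched).
#'
#' @return Character vector of metabolite base names.
#' @export
free_species <- function() {
  c("o2", "h2o", "h", "pi", "nh4", "nh3", "no3", "so4",
    "fe2", "fe3", "mg2", "ca2", "k", "na1", "cl", "zn2", "cu2", "mn2",
    "cobalt2", "mobd")
}

#' Exchanges of freely supplied species in a model
#' @param model A [metabolic_model()].
#' @param free Base names of freely supplied species.
#' @return Character vector of exchange reaction ids.
#' @export
free_exchanges <- function(model, free = free_species()) {
  ex <- find_exchanges(model)
  ex[vapply(ex, function(e) met_base_name(exchange_metabolite(model, e)) %in% free,
            logical(1))]
}

#' Define a growth medium
#'
#' @param uptakes Named non-negative numeric vector: exchange reaction id
#'   to maximum uptake rate (mmol h\eqn{^{-1}} g-DW\eqn{^{-1}}).
#' @param supplements Character vector of additional exchange ids to open
#'   at `supplement_rate` (e.g. glyoxylate rescue of a deletion strain).
#' @param supplement_rate Uptake rate granted to supplements.
#' @return A list of class `"cf_medium"`.
#' @export
medium <- function(uptakes = numeric(), supplements = character(),
                   supplement_rate = 10) {
  if (length(uptakes)) {
    stopifnot(!is.null(names(uptakes)), all(nzchar(names(uptakes))))
    if (any(uptakes < 0)) stop("uptake rates must be non-negative", call. = FALSE)
  }
  structure(list(uptakes = uptakes, supplements = supplements,
                 supplement_rate = supplement_rate),
            class = "cf_medium")
}

#' Apply a growth medium to a model
#'
#' First closes the uptake (lower bound) of every exchange reaction except
#' those supplying free mineral-medium species, then opens each medium
#' uptake `u` as a lower bound of `-u` (export-positive convention).
#' Upper bounds are untouched, so secretion stays open.
#'
#' @param model A [metabolic_model()].
#' @param med A [medium()], or a named numeric vector of uptakes.
#' @param free Base names of freely supplied species (see [free_species()]).
#' @return A new model with medium bounds applied; the input is not
#'   modified.
#' @export
apply_medium <- function(model, med, free = free_species()) {
  if (!inherits(med, "cf_medium")) med <- medium(uptakes = med)
  ex <- find_exchanges(model)
  targets <- c(names(med$uptakes), med$supplements)
  bad <- setdiff(targets, ex)
  if (length(bad))
    stop("not an exchange reaction: ", paste(bad, collapse = ", "), call. = FALSE)
  keep_open <- free_exchanges(model, free)
  out <- model
  for (e in setdiff(ex, keep_open))
    out$reactions[[e]]$lb <- max(out$reactions[[e]]$lb, 0)
  for (e in names(med$uptakes))
    out$reactions[[e]]$lb <- -unname(med$uptakes[[e]])
  for (e in med$supplements)
    out$reactions[[e]]$lb <- -med$supplement_rate
  out
}

#' Delete genes from a model
#'
#' Evaluates every reaction's GPR with the deleted genes set to FALSE;
#' reactions losing catalytic support get both bounds set to zero.  The
#' input model is not modified.  Unknown gene ids trigger a warning, not
#' an error, so screens over many strains do not abort.
#'
#' @param model A [metabolic_model()].
#' @param genes Character vector of gene ids to delete.
#' @return A new model with knocked-out reactions constrained to zero flux.
#' @export
apply_gene_deletion <- function(model, genes) {
  genes <- unique(genes)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown))
    warning("gene(s) not in model: ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- model
  for (r in out$reactions) {
    if (!evaluate_gpr(r$gpr, deleted = genes)) {
      out$reactions[[r$id]]$lb <- 0
      out$reactions[[r$id]]$ub <- 0
    }
  }
  attr(out, "deleted_genes") <- union(attr(model, "deleted_genes"), genes)
  out
}

#' Set flux bounds on a reaction
#'
#' @param model A [metabolic_model()].
#' @param rxn_id Reaction id.
#' @param lb,ub New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_flux_bounds <- function(model, rxn_id, lb = NULL, ub = NULL) {
  if (!rxn_id %in% names(model$reactions))
    stop("unknown reaction '", rxn_id, "'", call. = FALSE)
  if (!is.null(lb)) model$reactions[[rxn_id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[rxn_id]]$ub <- ub
  if (model$reactions[[rxn_id]]$lb > model$reactions[[rxn_id]]$ub)
    stop("reaction '", rxn_id, "': lower bound exceeds upper bound", call. = FALSE)
  model
}

#' Flux bound vectors of a model
#' @param model A [metabolic_model()].
#' @return List with numeric vectors `lb` and `ub` named by reaction id.
#' @export
flux_bounds <- function(model) {
  list(lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
       ub = vapply(model$reactions, function(r) r$ub, numeric(1)))
}
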