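#' Flux balance analysis
#'
#' Solves the linear program \eqn{\max / \min\; v_{obj}} subject to the
#' steady-state mass balance \eqn{S v = 0} and flux bounds
#' \eqn{lb \le v \le ub}, optionally with selected fluxes fixed to given
#' rates (e.g. the specific growth rate to its measured value).
#'
#' @param model A [metabolic_model()].
#' @param objective_id Reaction whose flux is optimised; defaults to the
#'   model objective (biomass).
#' @param sense `"max"` or `"min"`.
#' @param fixed Named numeric vector of reaction rates to pin
#'   (`lb = ub = rate`); rates must lie within the reaction's bounds.
#' @param refine Run [parsimonious_refine()] on the optimum so a unique
#'   minimal-total-flux representative is reported.
#' @return A `flux_solution`: list with `status`
#'   (`"optimal"`/`"infeasible"`/`"unbounded"`), `objective_value`,
#'   `fluxes` (named vector), `objective_id` and `constraints_applied`.
#'   Optimal solutions satisfy \eqn{\|S v\|_\infty \le 10^{-6}}.
#' @export
solve_fba <- function(model, objective_id = model$objective_id,
                      sense = c("max", "min"), fixed = NULL, refine = FALSE) {
  sense <- match.arg(sense)
  validate_model(model)
  if (is.null(objective_id) || !objective_id %in% names(model$reactions))
    stop("objective reaction '", objective_id, "' not in model", call. = FALSE)
  model <- fba_fix_rates(model, fixed)
  S <- build_stoichiometric_matrix(model)
  bn <- flux_bounds(model)
  obj <- as.numeric(names(model$reactions) == objective_id)
  res <- solve_lp(obj, S, rep(0, nrow(S)), bn$lb, bn$ub,
                  maximize = (sense == "max"))
  sol <- fba_solution(res, model, objective_id, fixed, sense)
  if (refine && sol$status == "optimal") sol <- parsimonious_refine(model, sol)
  sol
}

fba_fix_rates <- function(model, fixed) {
  if (is.null(fixed) || !length(fixed)) return(model)
  stopifnot(!is.null(names(fixed)))
  for (id in names(fixed)) {
    if (!id %in% names(model$reactions))
      stop("cannot fix unknown reaction '", id, "'", call. = FALSE)
    r <- model$reactions[[id]]
    rate <- unname(fixed[[id]])
    if (rate < r$lb - 1e-9 || rate > r$ub + 1e-9)
      stop("fixed rate ", rate, " for '", id, "' outside bounds [",
           r$lb, ", ", r$ub, "]", call. = FALSE)
    model <- set_flux_bounds(model, id, lb = rate, ub = rate)
  }
  model
}

fba_solution <- function(res, model, objective_id, fixed, sense) {
  fluxes <- NULL
  if (res$status == "optimal") {
    fluxes <- stats::setNames(res$x, names(model$reactions))
    S <- build_stoichiometric_matrix(model)
    imbalance <- max(abs(S %*% fluxes))
    if (imbalance > 1e-6)
      stop("optimal solution violates mass balance (|S v| = ",
           format(imbalance), ")", call. = FALSE)
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 fluxes = fluxes,
                 objective_id = objective_id,
                 sense = sense,
                 constraints_applied = fixed),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution (", x$sense, " ", x$objective_id, "): ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective = ", format(x$objective_value, digits = 6), sep = "")
  cat("\n")
  if (!is.null(x$constraints_applied) && length(x$constraints_applied))
    cat("  fixed:", paste(names(x$constraints_applied),
                          signif(x$constraints_applied, 4),
                          sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Parsimonious refinement of an FBA optimum
#'
#' FBA optima are often degenerate (parallel routes, futile cycles).  To
#' report a unique representative flux distribution the primary objective
#' is fixed at its optimum and the total absolute flux \eqn{\sum_j |v_j|}
#' is minimised (split-variable LP, pFBA-style).  The objective value is
#' preserved to within \eqn{10^{-6}}.
#'
#' @param model The model the solution came from (with any fixed rates
#'   already applied, as [solve_fba()] does internally).
#' @param solution An optimal `flux_solution`.
#' @return A refined `flux_solution` with the same objective value.
#' @export
parsimonious_refine <- function(model, solution) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal")
    stop("parsimonious refinement needs an optimal solution", call. = FALSE)
  model <- fba_fix_rates(model, solution$constraints_applied)
  S <- build_stoichiometric_matrix(model)
  bn <- flux_bounds(model)
  n <- length(bn$lb); m <- nrow(S)
  # v = p - q with p, q >= 0; minimise sum(p + q)
  A <- rbind(cbind(S, -S),
             c(as.numeric(names(model$reactions) == solution$objective_id),
               -as.numeric(names(model$reactions) == solution$objective_id)))
  b <- c(rep(0, m), solution$objective_value)
  lb <- c(pmax(bn$lb, 0), pmax(-bn$ub, 0))
  ub <- c(pmax(bn$ub, 0), pmax(-bn$lb, 0))
  res <- solve_lp(rep(1, 2 * n), A, b, lb, ub, maximize = FALSE)
  if (res$status != "optimal")
    stop("parsimonious refinement infeasible (status ", res$status,
         "); the fixed optimum may be at a numerical tolerance edge", call. = FALSE)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  fluxes <- stats::setNames(v, names(model$reactions))
  obj_new <- unname(fluxes[solution$objective_id])
  if (abs(obj_new - solution$objective_value) > 1e-6)
    stop("refinement changed the objective by more than 1e-6", call. = FALSE)
  out <- solution
  out$fluxes <- fluxes
  out$refined <- TRUE
  out
}

#' Minimal substrate uptake at a fixed growth rate
#'
#' Implements the yield-optimisation protocol: the specific growth rate is
#' fixed to its experimental value, optional secretion/oxidation rates are
#' fixed (e.g. measured 2-propanol, acetone and acetol rates during growth
#' on propane), and the uptake of the named substrate is minimised.  Under
#' the export-positive convention uptake is a negative flux, so the
#' exchange flux is maximised.  The optimum is parsimoniously refined.
#'
#' @param model A [metabolic_model()] with the medium already applied.
#' @param exchange_id Exchange reaction of the substrate.
#' @param mu Specific growth rate (h\eqn{^{-1}}), > 0.
#' @param extra_fixed Named numeric vector of additional rates to fix.
#' @param refine Parsimonious refinement (default `TRUE`).
#' @return A `flux_solution`; element `uptake` holds the minimised uptake
#'   rate (positive, mmol h\eqn{^{-1}} g-DW\eqn{^{-1}}).
#' @export
min_uptake_at_growth <- function(model, exchange_id, mu, extra_fixed = NULL,
                                 refine = TRUE) {
  stopifnot(mu > 0)
  if (!exchange_id %in% find_exchanges(model))
    stop("'", exchange_id, "' is not an exchange reaction", call. = FALSE)
  fixed <- c(stats::setNames(mu, model$objective_id), extra_fixed)
  sol <- solve_fba(model, objective_id = exchange_id, sense = "max",
                   fixed = fixed, refine = refine)
  if (sol$status == "optimal") sol$uptake <- -sol$objective_value
  sol
}

#' Maximal growth and biomass yield at a fixed substrate uptake
#'
#' Opens the substrate exchange to the given uptake rate, sets ATP
#' maintenance to the requested value (default 0, giving the maximal
#' theoretical yield) and maximises biomass production.
#'
#' @param model A [metabolic_model()] with the medium applied.
#' @param exchange_id Substrate exchange reaction.
#' @param uptake Maximal uptake rate (mmol h\eqn{^{-1}} g-DW\eqn{^{-1}}), > 0.
#' @param maintenance Lower bound on the ATP maintenance reaction, if the
#'   model has one (see [find_maintenance()]).
#' @param refine Parsimonious refinement of the reported fluxes.
#' @return A `yield_result`: list with `yield_value` (g-DW per mol
#'   substrate), `uptake` (the realised uptake), `growth` (h\eqn{^{-1}})
#'   and the underlying `solution`.  Yield = growth / uptake x 1000.
#' @export
max_growth_at_uptake <- function(model, exchange_id, uptake, maintenance = 0,
                                 refine = FALSE) {
  stopifnot(uptake > 0)
  if (!exchange_id %in% find_exchanges(model))
    stop("'", exchange_id, "' is not an exchange reaction", call. = FALSE)
  model <- set_flux_bounds(model, exchange_id, lb = -uptake)
  maint <- find_maintenance(model)
  if (!is.null(maint)) model <- set_flux_bounds(model, maint, lb = maintenance)
  else if (maintenance > 0)
    stop("model has no ATP maintenance reaction to bound", call. = FALSE)
  sol <- solve_fba(model, sense = "max", refine = refine)
  if (sol$status != "optimal")
    return(structure(list(status = sol$status, yield_value = NA_real_,
                          uptake = NA_real_, growth = NA_real_, solution = sol),
                     class = "yield_result"))
  realised <- -unname(sol$fluxes[exchange_id])
  growth <- sol$objective_value
  yv <- if (realised > 0) growth / realised * 1000 else 0
  structure(list(status = "optimal", yield_value = yv, uptake = realised,
                 growth = growth, solution = sol),
            class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  if (x$status != "optimal") {
    cat("Yield computation:", x$status, "\n")
  } else {
    cat("Biomass yield: ", format(x$yield_value, digits = 4),
        " g-DW mol-1  (growth ", format(x$growth, digits = 4),
        " h-1 at uptake ", format(x$uptake, digits = 4),
        " mmol h-1 g-DW-1)\n", sep = "")
  }
  invisible(x)
}

#' Locate the ATP maintenance reaction
#'
#' Non-growth-associated maintenance (NGAM) is encoded as a dedicated ATP
#' hydrolysis reaction (ATP + H2O -> ADP + Pi + H) whose lower bound is
#' the maintenance requirement.  Recognised by id (`ATPM`, case
#' insensitive, or ids containing "maintenance").
#'
#' @param model A [metabolic_model()].
#' @return The reaction id, or `NULL` if none is present.
#' @export
find_maintenance <- function(model) {
  ids <- names(model$reactions)
  hit <- ids[toupper(ids) == "ATPM" | grepl("maintenance", ids, ignore.case = TRUE)]
  if (length(hit)) hit[1] else NULL
}

#' Add an ATP maintenance reaction if absent
#'
#' @param model A [metabolic_model()].
#' @param atp,h2o,adp,pi,h Metabolite ids of the hydrolysis participants;
#'   any id absent from the model is created in the cytosol.
#' @return The model, with reaction `ATPM` guaranteed to exist.
#' @export
ensure_maintenance <- function(model, atp = "atp_c", h2o = "h2o_c",
                               adp = "adp_c", pi = "pi_c", h = "h_c") {
  if (!is.null(find_maintenance(model))) return(model)
  st <- c(-1, -1, 1, 1, 1)
  names(st) <- c(atp, h2o, adp, pi, h)
  rxns <- c(model$reactions, list(ATPM = reaction("ATPM", st, lb = 0, ub = 1000,
                                                  name = "ATP maintenance")))
  metabolic_model(rxns, metabolites = model$metabolites,
                  objective_id = model$objective_id, id = model$id,
                  genes = model$genes)
}

#' Fit the ATP maintenance requirement to a measured yield
#'
#' The gap between the maximal theoretical yield (maintenance = 0) and the
#' measured yield is attributed to non-growth-associated ATP maintenance.
#' The maintenance flux lower bound m is found by monotone bisection:
#' predicted yield decreases in m, so the unique m reproducing the
#' measured yield is bracketed by \[0, m_max\] with m_max the maximal
#' feasible ATP hydrolysis flux at the given uptake.
#'
#' @param model A [metabolic_model()] with the medium applied and a
#'   maintenance reaction (see [ensure_maintenance()]).
#' @param exchange_id Substrate exchange reaction.
#' @param uptake Substrate uptake rate (mmol h\eqn{^{-1}} g-DW\eqn{^{-1}}).
#' @param measured_yield Measured biomass yield (g-DW mol\eqn{^{-1}});
#'   must be below the theoretical maximum.
#' @param tol Convergence tolerance on yield (g-DW mol\eqn{^{-1}}).
#' @param max_iter Bisection iteration cap.
#' @return A `maintenance_fit`: list with `m_atp` (mmol h\eqn{^{-1}}
#'   g-DW\eqn{^{-1}}), `residual` (|predicted - measured| yield),
#'   `theoretical_yield` and `iterations`.
#' @export
fit_atp_maintenance <- function(model, exchange_id, uptake, measured_yield,
                                tol = 1e-3, max_iter = 60L) {
  maint <- find_maintenance(model)
  if (is.null(maint))
    stop("model has no ATP maintenance reaction; call ensure_maintenance()",
         call. = FALSE)
  yield_at <- function(m) {
    yr <- max_growth_at_uptake(model, exchange_id, uptake, maintenance = m)
    if (yr$status != "optimal") -Inf else yr$yield_value
  }
  y0 <- yield_at(0)
  if (!is.finite(y0))
    stop("model cannot grow on '", exchange_id, "' at the given uptake",
         call. = FALSE)
  if (measured_yield >= y0 - tol)
    stop("measured yield (", measured_yield, ") is not below the theoretical ",
         "maximum (", signif(y0, 6), "); no maintenance can explain it",
         call. = FALSE)
  # bracket: maximal feasible ATP hydrolysis at this uptake
  m_model <- set_flux_bounds(model, exchange_id, lb = -uptake)
  m_sol <- solve_fba(m_model, objective_id = maint, sense = "max")
  if (m_sol$status != "optimal")
    stop("cannot determine maintenance bracket (status ", m_sol$status, ")",
         call. = FALSE)
  lo <- 0; hi <- m_sol$objective_value
  y_hi <- yield_at(hi)
  if (is.finite(y_hi) && y_hi > measured_yield)
    stop("yield at maximal maintenance (", signif(y_hi, 6),
         ") still exceeds the measured yield; response is not monotone ",
         "towards the target", call. = FALSE)
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    y_mid <- yield_at(mid)
    if (is.finite(y_mid) && abs(y_mid - measured_yield) <= tol) break
    if (!is.finite(y_mid) || y_mid < measured_yield) hi <- mid else lo <- mid
    if (it >= max_iter) { mid <- (lo + hi) / 2; y_mid <- yield_at(mid); break }
  }
  structure(list(m_atp = mid,
                 residual = abs(y_mid - measured_yield),
                 theoretical_yield = y0,
                 measured_yield = measured_yield,
                 iterations = it),
            class = "maintenance_fit")
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat("ATP maintenance fit: m = ", format(x$m_atp, digits = 4),
      " mmol h-1 g-DW-1\n", sep = "")
  cat("  theoretical yield ", format(x$theoretical_yield, digits = 4),
      " -> measured ", format(x$measured_yield, digits = 4),
      " g-DW mol-1 (residual ", format(x$residual, digits = 2), ")\n", sep = "")
  invisible(x)
}

#' Energy-cycle quality control
#'
#' A curated model must not regenerate ATP with every exchange closed:
#' any such flux is a thermodynamically infeasible energy-generating
#' cycle, typically caused by a wrongly reversible reaction.  All exchange
#' bounds are set to zero and the ATP hydrolysis (maintenance) flux is
#' maximised; a maximum above \eqn{10^{-6}} fails the check and the active
#' reactions of a parsimonious optimum are reported.
#'
#' @param model A [metabolic_model()]; a maintenance reaction is added
#'   temporarily if absent.
#' @param flux_tol Activity threshold for listing cycle members.
#' @return List with `max_atp`, `pass`, and `active` (data frame of
#'   reaction id and flux for cycle members, empty on pass).
#' @export
check_energy_cycles <- function(model, flux_tol = 1e-6) {
  model <- ensure_maintenance(model)
  maint <- find_maintenance(model)
  for (e in find_exchanges(model))
    model <- set_flux_bounds(model, e, lb = 0, ub = 0)
  model <- set_flux_bounds(model, maint, lb = 0, ub = 1000)
  sol <- solve_fba(model, objective_id = maint, sense = "max")
  if (sol$status != "optimal")
    stop("energy-cycle QC solve failed (status ", sol$status, ")", call. = FALSE)
  max_atp <- sol$objective_value
  active <- data.frame(reaction = character(), flux = numeric())
  if (max_atp > flux_tol) {
    ref <- parsimonious_refine(model, sol)
    on <- which(abs(ref$fluxes) > flux_tol)
    active <- data.frame(reaction = names(ref$fluxes)[on],
                         flux = unname(ref$fluxes[on]))
  }
  list(max_atp = max_atp, pass = max_atp <= flux_tol, active = active)
}
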