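#' Hand-curated mini-model of Methylocella central carbon metabolism
#'
#' A compact, fully mass-balanced constraint-based model encoding the
#' pathway biology that drives the organism's substrate phenotypes:
#'
#' * soluble methane monooxygenase (sMMO, NADH- and O2-consuming;
#'   genes Msil_1262-1267) and PQQ-linked methanol/methylamine oxidation
#'   to formaldehyde feeding methylene-THF;
#' * the serine cycle (phosphoenolpyruvate carboxylase Msil_1718,
#'   serine-glyoxylate aminotransferase Msil_1714) with glyoxylate
#'   supplied anaplerotically by isocitrate lyase;
#' * the glyoxylate shunt (ICL Msil_3157, MS Msil_1325) and a TCA core;
#' * two parallel propane oxidation pathways: PrMO (genes
#'   Msil_1648-1651) to 1-propanol, then propanal, propionyl-CoA,
#'   methylmalonyl-CoA (mutase Msil_3785) and succinyl-CoA; and sMMO to
#'   2-propanol, then acetone, acetol (oxidation by Msil_1641),
#'   2-oxopropanal, lactate (Msil_2429-2431) and pyruvate, with the
#'   acetone monooxygenation coupled to O2 and ferredoxin
#'   (Msil_0731/Msil_1926);
#' * PQQ alcohol oxidations feeding a lumped cytochrome-c branch of the
#'   respiratory chain, NADH- and FADH2-level oxidative phosphorylation,
#'   an ATP maintenance reaction and a lumped biomass reaction;
#' * exchanges and transporters for the twelve substrates of the growth
#'   panel plus glyoxylate, 1-propanol, 2-propanol, acetone and acetol.
#'
#' The flux partition between the two propane monooxygenations reflects
#' enzyme kinetics, not optimality, so it is encoded as a fixed product
#' ratio (3 parts 2-propanol : 2 parts 1-propanol, the ratio observed in
#' propane-grown cultures) via a balanced coupling pseudo-metabolite.
#' No ethylmalonyl-CoA pathway is present.  Quantitative yields of this
#' fixture are its own; only the boolean growth pattern and the
#' qualitative mutant phenotypes are meant to match the organism.
#'
#' @return A [metabolic_model()] with objective `BIOMASS`.
#' @export
make_minicella_model <- function() {
  rx <- list()
  add <- function(id, stoich, ..., gpr = NA_character_) {
    rx[[id]] <<- reaction(id, stoich, gpr = gpr, ...)
  }

  carbon_ex <- c(ch4 = "methane", meoh = "methanol", ma = "methylamine",
                 ppa = "propane", etoh = "ethanol", ac = "acetate",
                 pyr = "pyruvate", succ = "succinate", glx = "glyoxylate",
                 oxa = "oxalate", gly = "glycine", urea = "urea",
                 ppoh1 = "1-propanol", ppoh2 = "2-propanol",
                 acetone = "acetone", acetol = "acetol")
  for (m in names(carbon_ex)) {
    st <- -1; names(st) <- paste0(m, "_e")
    add(paste0("EX_", m), st, lb = 0, ub = 1000,
        name = paste(carbon_ex[[m]], "exchange"))
  }
  for (m in c("o2", "co2", "h2o", "h", "pi", "nh4")) {
    st <- -1; names(st) <- paste0(m, "_c")
    add(paste0("EX_", m), st, lb = -1000, ub = 1000,
        name = paste(m, "exchange"))
  }
  # transporters: reversible for species that are both substrates and products
  rev_t <- c("ch4", "meoh", "ppa", "etoh", "ac", "ppoh1", "ppoh2",
             "acetone", "acetol")
  for (m in names(carbon_ex)) {
    st <- c(-1, 1)
    names(st) <- paste0(m, c("_e", "_c"))
    add(paste0("T_", m), st, reversible = m %in% rev_t,
        name = paste(carbon_ex[[m]], "transport"))
  }

  smmo_gpr <- paste(paste0("Msil_", 1262:1267), collapse = " and ")
  prmo_gpr <- paste(paste0("Msil_", 1648:1651), collapse = " and ")

  # --- C1 oxidation and the serine cycle ---------------------------------
  add("sMMO", c(ch4_c = -1, o2_c = -1, nadh_c = -1, meoh_c = 1, h2o_c = 1,
                nad_c = 1), gpr = smmo_gpr, name = "soluble methane monooxygenase")
  add("MEDH", c(meoh_c = -1, cytcox_c = -1, fald_c = 1, cytcred_c = 1),
      gpr = "Msil_0471", name = "PQQ methanol dehydrogenase")
  add("MADH", c(ma_c = -1, h2o_c = -1, cytcox_c = -1, fald_c = 1, nh4_c = 1,
                cytcred_c = 1), name = "methylamine dehydrogenase")
  add("FALDH", c(fald_c = -1, nad_c = -1, h2o_c = -1, for_c = 1, nadh_c = 1),
      name = "formaldehyde dehydrogenase")
  add("FDH", c(for_c = -1, nad_c = -1, co2_c = 1, nadh_c = 1),
      name = "formate dehydrogenase")
  add("FTHFL", c(fald_c = -1, thf_c = -1, mlthf_c = 1),
      name = "methylene-THF formation")
  add("SHMT", c(gly_c = -1, mlthf_c = -1, h2o_c = -1, ser_c = 1, thf_c = 1),
      name = "serine hydroxymethyltransferase")
  add("SGAT", c(ser_c = -1, glx_c = -1, hpyr_c = 1, gly_c = 1),
      gpr = "Msil_1714", name = "serine-glyoxylate aminotransferase")
  add("HPR", c(hpyr_c = -1, nadh_c = -1, glyc_c = 1, nad_c = 1),
      name = "hydroxypyruvate reductase")
  add("GLYK", c(glyc_c = -1, atp_c = -1, pg2_c = 1, adp_c = 1),
      name = "glycerate kinase")
  add("ENO", c(pg2_c = -1, pep_c = 1, h2o_c = 1), reversible = TRUE,
      name = "enolase")
  add("PPC", c(pep_c = -1, co2_c = -1, h2o_c = -1, oaa_c = 1, pi_c = 1),
      gpr = "Msil_1718", name = "phosphoenolpyruvate carboxylase")
  add("MTKMCL", c(mal_c = -1, atp_c = -1, coa_c = -1, accoa_c = 1, glx_c = 1,
                  adp_c = 1, pi_c = 1),
      name = "malate thiokinase + malyl-CoA lyase (lumped)")

  # --- lower glycolysis / anaplerosis ------------------------------------
  add("PYK", c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1),
      name = "pyruvate kinase")
  add("PPS", c(pyr_c = -1, atp_c = -1, h2o_c = -1, pep_c = 1, adp_c = 1,
               pi_c = 1), name = "PEP synthase")
  add("PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1,
               nadh_c = 1), name = "pyruvate dehydrogenase")
  add("PCK", c(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1, adp_c = 1),
      name = "PEP carboxykinase")

  # --- TCA core and glyoxylate shunt -------------------------------------
  add("CS", c(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1, coa_c = 1),
      name = "citrate synthase")
  add("ACONT", c(cit_c = -1, icit_c = 1), reversible = TRUE, name = "aconitase")
  add("ICL", c(icit_c = -1, glx_c = 1, succ_c = 1), gpr = "Msil_3157",
      name = "isocitrate lyase")
  add("MS", c(accoa_c = -1, glx_c = -1, h2o_c = -1, mal_c = 1, coa_c = 1),
      gpr = "Msil_1325", name = "malate synthase")
  add("ICDH", c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1, nadph_c = 1),
      name = "isocitrate dehydrogenase (NADP)")
  add("AKGDH", c(akg_c = -1, nad_c = -1, coa_c = -1, succoa_c = 1, co2_c = 1,
                 nadh_c = 1), name = "2-oxoglutarate dehydrogenase")
  add("SUCOAS", c(succoa_c = -1, adp_c = -1, pi_c = -1, succ_c = 1, atp_c = 1,
                  coa_c = 1), name = "succinyl-CoA synthetase")
  add("SDH", c(succ_c = -1, fad_c = -1, fum_c = 1, fadh2_c = 1),
      name = "succinate dehydrogenase")
  add("FUM", c(fum_c = -1, h2o_c = -1, mal_c = 1), reversible = TRUE,
      name = "fumarase")
  add("MDH", c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1),
      reversible = TRUE, name = "malate dehydrogenase")

  # --- ethanol / acetate assimilation ------------------------------------
  add("ADHE", c(etoh_c = -1, nad_c = -1, acald_c = 1, nadh_c = 1),
      name = "ethanol dehydrogenase")
  add("ALDD", c(acald_c = -1, nad_c = -1, h2o_c = -1, ac_c = 1, nadh_c = 1),
      name = "acetaldehyde dehydrogenase")
  add("ACS", c(ac_c = -1, atp_c = -1, coa_c = -1, accoa_c = 1, adp_c = 1,
               pi_c = 1), name = "acetyl-CoA synthetase")

  # --- propane, pathway via 1-propanol (methylmalonyl-CoA branch) --------
  add("PrMO", c(ppa_c = -1, o2_c = -1, nadh_c = -1, prmo_split_c = -3,
                ppoh1_c = 1, h2o_c = 1, nad_c = 1),
      gpr = prmo_gpr, name = "propane monooxygenase (to 1-propanol)")
  add("PrMO2", c(ppa_c = -1, o2_c = -1, nadh_c = -1, prmo_split_c = 2,
                 ppoh2_c = 1, h2o_c = 1, nad_c = 1),
      gpr = smmo_gpr, name = "propane monooxygenation by sMMO (to 2-propanol)")
  add("ADH1P", c(ppoh1_c = -1, cytcox_c = -1, ppal_c = 1, cytcred_c = 1),
      gpr = "Msil_1587", name = "PQQ 1-propanol dehydrogenase")
  add("PALDD", c(ppal_c = -1, coa_c = -1, nad_c = -1, h2o_c = -1, ppcoa_c = 1,
                 nadh_c = 1), name = "propanal dehydrogenase (CoA-acylating)")
  add("PCC", c(ppcoa_c = -1, co2_c = -1, atp_c = -1, mmcoa_c = 1, adp_c = 1,
               pi_c = 1), name = "propionyl-CoA carboxylase")
  add("MMM", c(mmcoa_c = -1, succoa_c = 1), gpr = "Msil_3785",
      name = "methylmalonyl-CoA mutase")

  # --- propane, pathway via 2-propanol (lactate branch) ------------------
  add("ADH2P", c(ppoh2_c = -1, cytcox_c = -1, acetone_c = 1, cytcred_c = 1),
      gpr = "Msil_1587", name = "PQQ 2-propanol dehydrogenase")
  add("ACMO", c(acetone_c = -1, o2_c = -1, fdred_c = -1, acetol_c = 1,
                h2o_c = 1, fdox_c = 1), gpr = "Msil_0731 or Msil_1926",
      name = "acetone monooxygenase (P450, ferredoxin-coupled)")
  add("FDXR", c(fdox_c = -1, nadh_c = -1, fdred_c = 1, nad_c = 1),
      name = "ferredoxin reductase")
  add("ACTD", c(acetol_c = -1, nad_c = -1, mgxal_c = 1, nadh_c = 1),
      gpr = "Msil_1641", name = "acetol dehydrogenase")
  add("GLOX", c(mgxal_c = -1, h2o_c = -1, lac_c = 1),
      gpr = paste("(Msil_3783 or Msil_1643 or Msil_0199) and",
                  "(Msil_1898 or Msil_0771 or Msil_1051)"),
      name = "glyoxalase system (2-oxopropanal to lactate)")
  add("LDH", c(lac_c = -1, nad_c = -1, pyr_c = 1, nadh_c = 1),
      gpr = "Msil_2429 and Msil_2430 and Msil_2431",
      name = "lactate dehydrogenase")

  # --- nitrogen / dead-end substrates ------------------------------------
  add("UREASE", c(urea_c = -1, h2o_c = -1, co2_c = 1, nh4_c = 2),
      name = "urease")
  add("OXADC", c(oxa_c = -1, h_c = -1, for_c = 1, co2_c = 1),
      name = "oxalate decarboxylase")

  # --- respiration and energy --------------------------------------------
  add("NADHOR", c(nadh_c = -1, o2_c = -0.5, adp_c = -2, pi_c = -2, nad_c = 1,
                  atp_c = 2, h2o_c = 3),
      name = "respiratory chain (NADH level, P/O 2)")
  add("CYOR", c(cytcred_c = -1, o2_c = -0.5, adp_c = -1, pi_c = -1,
                cytcox_c = 1, atp_c = 1, h2o_c = 2),
      name = "cytochrome c oxidase (P/O 1)")
  add("FADOR", c(fadh2_c = -1, o2_c = -0.5, adp_c = -1, pi_c = -1, fad_c = 1,
                 atp_c = 1, h2o_c = 2),
      name = "respiratory chain (FADH2 level, P/O 1)")
  add("THD", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
      name = "transhydrogenase")
  add("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      name = "ATP maintenance")
  add("BIOMASS", c(accoa_c = -3, oaa_c = -2, pep_c = -1, nadph_c = -4,
                   atp_c = -30, h2o_c = -30, coa_c = 3, nadp_c = 4,
                   adp_c = 30, pi_c = 30),
      name = "biomass (lumped precursor drain)")

  mets <- do.call(rbind, c(
    lapply(names(carbon_ex),
           function(m) metabolite(paste0(m, "_e"), carbon_ex[[m]],
                                  compartment = "e")),
    list(metabolite("prmo_split_c", "propane monooxygenation product-ratio coupling",
                    compartment = "c"))
  ))
  model <- metabolic_model(rx, metabolites = mets, objective_id = "BIOMASS",
                           id = "miniMethylocella")
  model
}

#' Substrate media for the growth panel
#'
#' One minimal medium per carbon source: the named substrate at
#' `rate` mmol h\eqn{^{-1}} g-DW\eqn{^{-1}} on top of the free mineral
#' set.  The absolute rate does not affect boolean growth calls (LP
#' homogeneity).
#'
#' @param substrates Substrate names (default: the twelve panel
#'   substrates).
#' @param rate Maximal uptake rate granted to the carbon source.
#' @return Named list of [medium()] objects.
#' @export
minicella_media <- function(substrates = minicella_substrates(), rate = 10) {
  ex <- c(methane = "EX_ch4", methanol = "EX_meoh", methylamine = "EX_ma",
          propane = "EX_ppa", ethanol = "EX_etoh", acetate = "EX_ac",
          pyruvate = "EX_pyr", succinate = "EX_succ", glyoxylate = "EX_glx",
          oxalate = "EX_oxa", glycine = "EX_gly", urea = "EX_urea",
          `1-propanol` = "EX_ppoh1", `2-propanol` = "EX_ppoh2",
          acetone = "EX_acetone", acetol = "EX_acetol")
  unknown <- setdiff(substrates, names(ex))
  if (length(unknown))
    stop("no medium defined for: ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- lapply(substrates, function(s) medium(stats::setNames(rate, ex[[s]])))
  stats::setNames(out, substrates)
}

#' @rdname minicella_media
#' @export
minicella_substrates <- function() {
  c("methane", "methanol", "methylamine", "propane", "ethanol", "acetate",
    "pyruvate", "succinate", "glyoxylate", "oxalate", "glycine", "urea")
}

#' Reference growth matrix for the wild type and shunt mutants
#'
#' The published experimental/predicted growth pattern of the wild type,
#' \eqn{\Delta}ICL and \eqn{\Delta}MS strains over the twelve-substrate
#' panel (growth on methane, methanol, methylamine, propane, ethanol,
#' acetate, pyruvate and succinate for the wild type; loss of C1, ethanol
#' and acetate growth in \eqn{\Delta}ICL; loss of ethanol and acetate
#' growth in \eqn{\Delta}MS; no strain grows on glyoxylate, oxalate,
#' glycine or urea).
#'
#' @return Logical matrix, strains x substrates.
#' @export
table1_reference <- function() {
  subs <- minicella_substrates()
  wt <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  icl <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  ms <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m <- rbind(WT = wt, dICL = icl, dMS = ms)
  colnames(m) <- subs
  m
}

#' Mutant strains of the growth panel
#'
#' @return Named list of [strain()] definitions: wild type, the glyoxylate
#'   shunt deletions (\eqn{\Delta}ICL = Msil_3157, \eqn{\Delta}MS =
#'   Msil_1325) and the acetol-oxidation deletion (\eqn{\Delta}1641).
#' @export
minicella_strains <- function() {
  list(WT = strain("WT"),
       dICL = strain("dICL", "Msil_3157"),
       dMS = strain("dMS", "Msil_1325"),
       d1641 = strain("d1641", "Msil_1641"))
}

#' Generate a mass-balanced toy pathway model with a designed yield
#'
#' Builds a linear (optionally branched) assimilation chain
#' substrate -> m1 -> ... -> biomass whose maximal growth at a fixed
#' substrate uptake u is exactly `yield * u`, for oracle tests of the
#' flux-balance protocols.  Options add an alternative dissimilatory
#' route generating ATP (for maintenance-fitting algebra), parallel
#' equivalent routes (for parsimonious-refinement tests) and a
#' deliberately infeasible ATP-generating loop (for energy-cycle QC).
#'
#' @param chain_length Number of internal chain intermediates (>= 1).
#' @param yield Designed biomass units per mmol substrate (> 0).
#' @param n_parallel Number of parallel equivalent routes for the first
#'   chain step.
#' @param atp_per_mmol If > 0, adds a route burning substrate into CO2
#'   yielding this much ATP per mmol, plus an ATP maintenance reaction.
#' @param atp_loop If `TRUE`, adds a thermodynamically infeasible
#'   two-reaction loop that regenerates ATP, which [check_energy_cycles()]
#'   must flag.
#' @param seed Optional seed; draws random per-step stoichiometric
#'   doubling factors while preserving the designed yield exactly.
#'   Deterministic: the same seed yields the identical model.
#' @return A [metabolic_model()] with objective `BIOMASS`.
#' @export
make_toy_pathway_model <- function(chain_length = 3, yield = 1,
                                   n_parallel = 1, atp_per_mmol = 0,
                                   atp_loop = FALSE, seed = NULL) {
  if (yield <= 0) stop("designed yield must be positive", call. = FALSE)
  if (chain_length < 1) stop("chain_length must be >= 1", call. = FALSE)
  mult <- rep(1, chain_length)
  if (!is.null(seed)) {
    rng <- make_rng(seed)
    mult <- 1 + rng$integer(chain_length, 0, 1)  # per-step factor 1 or 2
  }
  rx <- list()
  rx$EX_S <- reaction("EX_S", c(s_e = -1), lb = 0, ub = 1000)
  rx$T_S <- reaction("T_S", c(s_e = -1, m1_c = 1))
  ids <- c("m1_c", paste0("m", seq_len(chain_length) + 1, "_c"))
  for (i in seq_len(chain_length)) {
    st <- stats::setNames(c(-1, mult[i]), c(ids[i], ids[i + 1]))
    if (i == 1 && n_parallel > 1) {
      for (p in seq_len(n_parallel))
        rx[[paste0("STEP1_r", p)]] <- reaction(paste0("STEP1_r", p), st)
    } else {
      rx[[paste0("STEP", i)]] <- reaction(paste0("STEP", i), st)
    }
  }
  last <- ids[chain_length + 1]
  bio <- stats::setNames(-prod(mult) / yield, last)
  if (atp_per_mmol > 0) {
    rx$BURN <- reaction("BURN", c(m1_c = -1, adp_c = -atp_per_mmol,
                                  pi_c = -atp_per_mmol, atp_c = atp_per_mmol,
                                  co2_c = 1))
    rx$EX_co2 <- reaction("EX_co2", c(co2_c = -1), lb = 0, ub = 1000)
    rx$EX_pi <- reaction("EX_pi", c(pi_c = -1), lb = -1000, ub = 1000)
    rx$ATPM <- reaction("ATPM", c(atp_c = -1, adp_c = 1, pi_c = 1),
                        lb = 0, ub = 1000, name = "ATP maintenance")
  }
  if (atp_loop) {
    # x <-> y plus y -> x + ATP: closed loop regenerating ATP from nothing
    rx$LOOPF <- reaction("LOOPF", c(x_c = -1, y_c = 1), reversible = TRUE)
    rx$LOOPG <- reaction("LOOPG", c(y_c = -1, adp_c = -1, pi_c = -1,
                                    x_c = 1, atp_c = 1))
    if (is.null(rx$ATPM)) {
      rx$ATPM <- reaction("ATPM", c(atp_c = -1, adp_c = 1, pi_c = 1),
                          lb = 0, ub = 1000, name = "ATP maintenance")
      rx$EX_pi <- reaction("EX_pi", c(pi_c = -1), lb = -1000, ub = 1000)
    }
  }
  rx$BIOMASS <- reaction("BIOMASS", bio, lb = 0, ub = 1000)
  mets <- metabolite("s_e", "substrate", compartment = "e")
  metabolic_model(rx, metabolites = mets, objective_id = "BIOMASS",
                  id = sprintf("toy_chain%d_y%g", chain_length, yield))
}

# Small deterministic RNG wrapper: every generator routes randomness
# through an isolated stream so no global seed state is touched.
make_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  env <- new.env(parent = emptyenv())
  local_rng <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(env$seed)
    on.exit({
      env$seed <- sample.int(.Machine$integer.max, 1)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  env$seed <- as.integer(seed)
  list(
    normal = function(n, mean = 0, sd = 1) local_rng(function() stats::rnorm(n, mean, sd)),
    uniform = function(n, min = 0, max = 1) local_rng(function() stats::runif(n, min, max)),
    integer = function(n, lo, hi) local_rng(function() lo + (sample.int(hi - lo + 1, n, replace = TRUE) - 1L)),
    permute = function(x) local_rng(function() sample(x))
  )
}

#' Simulate a proteome abundance table with planted flux-correlated enzymes
#'
#' Emulates the structure of a label-free proteomics experiment across
#' growth conditions: a few enzymes whose abundance tracks their predicted
#' metabolic flux (high metabolic control), a background of detected
#' proteins whose abundance is unrelated to flux, and measurement noise.
#' Planted abundances are `a + b * flux_profile + noise` with per-gene
#' positive `a`, `b`; noise is Gaussian with standard deviation
#' `noise_sd` times the gene's dynamic range.  Background entries are
#' drawn first from the model's remaining genes (flux-independent
#' abundances) and then padded with non-metabolic protein ids, mirroring
#' the fact that most detected proteins are not metabolic enzymes.
#'
#' @param model A [metabolic_model()].
#' @param solutions Named list of optimal `flux_solution`s, one per
#'   condition.
#' @param planted_genes Genes to plant as flux-correlated; each must
#'   appear in some GPR.
#' @param noise_sd Noise level as a fraction of each planted gene's
#'   abundance dynamic range (>= 0).
#' @param n_background Number of background proteins.
#' @param seed Seed for reproducibility.
#' @return Numeric matrix (proteins x conditions), non-negative.
#' @export
simulate_proteome <- function(model, solutions, planted_genes, noise_sd = 0.1,
                              n_background = 200, seed = 1) {
  stopifnot(noise_sd >= 0)
  conds <- names(solutions)
  if (is.null(conds) || length(conds) < 2)
    stop("need at least two named conditions", call. = FALSE)
  mappable <- model_gene_map(model)
  bad <- setdiff(planted_genes, names(mappable))
  if (length(bad))
    stop("planted gene(s) not in any GPR: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rng <- make_rng(seed)
  rows <- list()
  for (g in planted_genes) {
    prof <- gene_flux_profile(solutions, model, g)
    a <- rng$uniform(1, 5, 20)
    b <- rng$uniform(1, 50, 150)
    signal <- a + b * prof
    rngspan <- max(signal) - min(signal)
    if (rngspan == 0) rngspan <- max(signal, 1)
    rows[[g]] <- pmax(signal + rng$normal(length(prof), 0, noise_sd * rngspan), 0)
  }
  bg_model <- setdiff(names(mappable), planted_genes)
  bg_model <- bg_model[seq_len(min(length(bg_model), n_background))]
  n_extra <- n_background - length(bg_model)
  bg_ids <- c(bg_model,
              if (n_extra > 0) sprintf("prot_%04d", seq_len(n_extra)))
  for (g in bg_ids) {
    base <- rng$uniform(1, 5, 100)
    rows[[g]] <- pmax(base + rng$normal(length(conds), 0, 0.25 * base), 0)
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- conds
  tab
}

#' Simulate a growth time series with a designed biomass yield
#'
#' Exponential biomass growth at rate `mu`; substrate decreases by the
#' produced biomass divided by the designed yield; optical density
#' carries Gaussian measurement noise.  Emulates the serum-vial yield
#' measurements (biomass via OD with 1 OD ml = 0.25 mg dry weight,
#' substrate via gas chromatography).
#'
#' @param yield_design Designed yield, g-DW per mol substrate.
#' @param mu Specific growth rate (h\eqn{^{-1}}).
#' @param od0 Initial optical density.
#' @param noise_sd Gaussian noise on OD (absolute OD units).
#' @param n_points Number of time points.
#' @param seed Seed for reproducibility.
#' @param volume_ml Culture volume.
#' @param t_max Final time (h).
#' @param plateau_from If in (0, 1), substrate consumption and growth stop
#'   after this fraction of the time course (emulating nutrient
#'   limitation), while OD noise continues.
#' @return Data frame with columns `time_h`, `substrate_mmol`, `od`,
#'   `volume_ml`.
#' @export
simulate_growth_series <- function(yield_design, mu, od0 = 0.05,
                                   noise_sd = 0.002, n_points = 20, seed = 1,
                                   volume_ml = 100, t_max = 100,
                                   plateau_from = NA) {
  stopifnot(yield_design > 0, mu > 0, od0 > 0, n_points >= 3)
  rng <- make_rng(seed)
  t <- seq(0, t_max, length.out = n_points)
  od_true <- od0 * exp(mu * t)
  dw_g <- od_true * volume_ml * 0.25 / 1000          # mg -> g
  consumed_mmol <- (dw_g - dw_g[1]) / yield_design * 1000
  if (!is.na(plateau_from)) {
    # growth stops at the limitation onset; maintenance consumption of the
    # substrate continues at the onset rate, so late points bias the
    # biomass-vs-substrate slope low
    cut <- which(t >= plateau_from * t_max)
    i0 <- cut[1]
    od_true[cut] <- od_true[i0]
    rate <- mu * dw_g[i0] / yield_design * 1000       # mmol h-1
    consumed_mmol[cut] <- consumed_mmol[i0] + rate * (t[cut] - t[i0])
  }
  s0 <- 1.2 * max(consumed_mmol) + 1
  data.frame(time_h = t,
             substrate_mmol = s0 - consumed_mmol,
             od = pmax(od_true + rng$normal(n_points, 0, noise_sd), 0),
             volume_ml = volume_ml)
}

#' Write the packaged fixtures to a directory
#'
#' Writes the mini-model in SBML and tabular form, the reference growth
#' matrix, and example synthetic proteome and growth-curve files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the example synthetic data.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- make_minicella_model()
  paths <- c(sbml = file.path(dir, "minicella.xml"),
             reactions = file.path(dir, "minicella_reactions.tsv"),
             metabolites = file.path(dir, "minicella_metabolites.tsv"),
             table1 = file.path(dir, "growth_reference.tsv"),
             proteome = file.path(dir, "synthetic_proteome.tsv"),
             growth = file.path(dir, "synthetic_growth.csv"))
  write_sbml(model, paths[["sbml"]])
  write_tabular_model(model, paths[["reactions"]], paths[["metabolites"]])
  ref <- table1_reference()
  utils::write.table(data.frame(strain = rownames(ref),
                                ifelse(ref, "+", "-"), check.names = FALSE),
                     paths[["table1"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  media <- minicella_media(c("methane", "succinate", "propane"))
  sols <- lapply(media, function(m)
    solve_fba(apply_medium(model, m), refine = TRUE))
  tab <- simulate_proteome(model, sols,
                           planted_genes = c("Msil_1651", "Msil_1641",
                                             "Msil_3785", "Msil_1718",
                                             "Msil_1714"),
                           noise_sd = 0.1, n_background = 200, seed = seed)
  utils::write.table(data.frame(id = rownames(tab), tab, check.names = FALSE),
                     paths[["proteome"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gs <- simulate_growth_series(5.2, 0.05, seed = seed)
  utils::write.csv(gs, paths[["growth"]], row.names = FALSE)
  invisible(paths)
}
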