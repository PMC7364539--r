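#!/usr/bin/env Rscript
# Optional integration run against the published genome-scale model
# (Methylocella.xml, available from the authors' model repository).  Not
# part of the offline test suite because it needs the downloaded file.
#
# Usage:
#   Rscript scripts/full_model_integration.R path/to/Methylocella.xml
#
# Checks, against the published figures:
#   * parsed model size: 681 genes, 1436 reactions, 1474 metabolites
#   * acetate uptake minimisation at growth 0.05 h-1: ICL ~0.78 and
#     MS ~0.71 mmol h-1 g-DW-1
#   * maximal theoretical yield on methane ~6.64 g-DW mol-1
#   * ATP maintenance explaining a measured methane yield of 5.2
#     g-DW mol-1: ~3.45 mmol h-1 g-DW-1
#   * constrained propane uptake minimisation: ~0.67 mmol h-1 g-DW-1
#     (growth 0.0174 h-1 with measured 2-propanol/acetone secretion and
#     acetol oxidation rates imposed)

suppressPackageStartupMessages(library(cellaflux))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: full_model_integration.R <Methylocella.xml>")
model <- read_sbml(args[1])
print(model)
cat(sprintf("counts: %d genes / %d reactions / %d metabolites (expect 681/1436/1474)\n",
            n_genes(model), n_reactions(model), n_metabolites(model)))

find_ex <- function(pattern) {
  ex <- find_exchanges(model)
  hit <- ex[grepl(pattern, ex, ignore.case = TRUE)]
  if (!length(hit)) stop("no exchange matching '", pattern,
                         "'; inspect find_exchanges() output")
  hit[1]
}

ex_ac <- find_ex("ac(etate)?")
cond <- apply_medium(model, medium(stats::setNames(10, ex_ac)))
sol <- min_uptake_at_growth(cond, ex_ac, 0.05)
icl <- grep("icl|isocitrate.lyase", names(sol$fluxes), ignore.case = TRUE,
            value = TRUE)
ms <- grep("mals|malate.synth", names(sol$fluxes), ignore.case = TRUE,
           value = TRUE)
cat("acetate min uptake:", sol$uptake, "\n")
cat("ICL flux (expect ~0.78):", sol$fluxes[icl], "\n")
cat("MS flux (expect ~0.71):", sol$fluxes[ms], "\n")

ex_ch4 <- find_ex("ch4|methane")
cond <- apply_medium(model, medium(stats::setNames(10, ex_ch4)))
yr <- max_growth_at_uptake(cond, ex_ch4, 10)
cat("methane theoretical yield (expect ~6.64):", yr$yield_value, "\n")

condm <- ensure_maintenance(cond)
fit <- fit_atp_maintenance(condm, ex_ch4, 10, measured_yield = 5.2)
cat("fitted maintenance (expect ~3.45):", fit$m_atp, "\n")

ex_ppa <- find_ex("ppa|propane")
ex_2poh <- find_ex("2.?p(rop)?(an)?ol|ppoh2")
ex_acetone <- find_ex("acetone|act[no]")
acetol_ox <- grep("acetol|1641", names(model$reactions), ignore.case = TRUE,
                  value = TRUE)[1]
cond <- apply_medium(model, medium(stats::setNames(10, ex_ppa)))
sol <- min_uptake_at_growth(cond, ex_ppa, 0.0174,
                            extra_fixed = stats::setNames(
                              c(0.189, 0.073, 0.153),
                              c(ex_2poh, ex_acetone, acetol_ox)))
cat("propane min uptake (expect ~0.67):", sol$uptake, "\n")
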