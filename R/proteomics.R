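# Flux-proteome integration: correlate enzyme abundances across growth
# conditions with the fluxes of the reactions they catalyse, identifying
# enzymes with high metabolic control under FDR control.

# gene -> reaction ids, for all genes appearing in some GPR
model_gene_map <- function(model) {
  out <- list()
  for (r in model$reactions) {
    for (g in gpr_genes(r$gpr)) out[[g]] <- c(out[[g]], r$id)
  }
  out
}

#' Per-condition flux profile of a gene
#'
#' For each condition, the sum of absolute fluxes of all reactions whose
#' GPR contains the gene.  The absolute-sum aggregation is
#' scale-consistent and treats reversible reactions symmetrically; `"max"`
#' takes the largest absolute flux instead.
#'
#' @param solutions Named list of optimal `flux_solution`s, one per
#'   condition.
#' @param model The [metabolic_model()] the solutions came from.
#' @param gene Gene id; must occur in at least one GPR.
#' @param aggregate `"sum"` (default) or `"max"` over the gene's
#'   reactions.
#' @return Named numeric vector over conditions.
#' @export
gene_flux_profile <- function(solutions, model, gene,
                              aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  rxns <- model_gene_map(model)[[gene]]
  if (is.null(rxns))
    stop("gene '", gene, "' does not occur in any GPR (not mappable to flux)",
         call. = FALSE)
  vapply(solutions, function(sol) {
    if (!inherits(sol, "flux_solution") || sol$status != "optimal")
      stop("all solutions must be optimal flux_solution objects", call. = FALSE)
    v <- abs(sol$fluxes[rxns])
    if (aggregate == "sum") sum(v) else max(v)
  }, numeric(1))
}

#' Pearson correlation with a two-sided p-value
#'
#' Pearson's r with the classical t-test p-value
#' (\eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom; with three
#' conditions this is one degree of freedom, a standard Cauchy).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), both with
#'   non-zero variance.
#' @return List with elements `r` and `p`.
#' @export
pearson_r_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values); order-preserving and never below
#' the raw p-value.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Correlate predicted fluxes with enzyme abundances
#'
#' For every protein in the abundance table that maps to model reactions
#' through a GPR, computes its flux profile across conditions
#' ([gene_flux_profile()]), the Pearson correlation with its abundance
#' profile and the t-test p-value, then applies Benjamini-Hochberg FDR
#' over all testable enzymes.  Proteins that are not mappable, have
#' missing values, or have zero variance in either profile are excluded
#' from testing and reported with the reason, never silently assigned a
#' p-value.
#'
#' @param model A [metabolic_model()].
#' @param solutions Named list of optimal `flux_solution`s (one per
#'   condition, e.g. methane/succinate/propane).
#' @param abundance_table Numeric matrix, proteins x conditions, with
#'   rownames; column names must match the solution names.
#' @param alpha FDR cutoff for the significance call.
#' @param aggregate Flux aggregation rule, see [gene_flux_profile()].
#' @param normalize If `TRUE`, divide each column by its total intensity
#'   first.
#' @return An `enzyme_correlation` data frame (`id`, `r`, `p`, `q`,
#'   `significant`) sorted by q, with the excluded proteins in
#'   `attr(, "excluded")` (`id`, `reason`).
#' @export
correlate_proteome <- function(model, solutions, abundance_table, alpha = 0.05,
                               aggregate = c("sum", "max"), normalize = FALSE) {
  aggregate <- match.arg(aggregate)
  conds <- colnames(abundance_table)
  if (is.null(conds) || length(conds) < 3)
    stop("abundance table needs >= 3 named condition columns for ",
         "correlation testing", call. = FALSE)
  missing_conds <- setdiff(conds, names(solutions))
  if (length(missing_conds) == length(conds))
    stop("no overlap between abundance conditions and flux solutions",
         call. = FALSE)
  if (length(missing_conds))
    stop("no flux solution for condition(s): ",
         paste(missing_conds, collapse = ", "), call. = FALSE)
  if (any(abundance_table < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  if (normalize)
    abundance_table <- sweep(abundance_table, 2,
                             colSums(abundance_table, na.rm = TRUE), "/")
  sols <- solutions[conds]
  gmap <- model_gene_map(model)

  ids <- rownames(abundance_table)
  excluded <- data.frame(id = character(), reason = character())
  keep <- character(); rr <- numeric(); pp <- numeric()
  for (id in ids) {
    ab <- abundance_table[id, ]
    if (is.null(gmap[[id]])) {
      excluded <- rbind(excluded, data.frame(id = id, reason = "not_mappable"))
      next
    }
    if (anyNA(ab)) {
      excluded <- rbind(excluded, data.frame(id = id, reason = "missing_values"))
      next
    }
    prof <- gene_flux_profile(sols, model, id, aggregate = aggregate)
    if (stats::sd(prof) == 0 || stats::sd(ab) == 0) {
      excluded <- rbind(excluded, data.frame(id = id, reason = "zero_variance"))
      next
    }
    est <- pearson_r_p(prof, as.numeric(ab))
    keep <- c(keep, id); rr <- c(rr, est$r); pp <- c(pp, est$p)
  }
  qq <- bh_fdr(pp)
  out <- data.frame(id = keep, r = rr, p = pp, q = qq,
                    significant = qq < alpha)
  out <- out[order(out$q, out$p, out$id), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "alpha") <- alpha
  class(out) <- c("enzyme_correlation", "data.frame")
  out
}

#' Volcano-style plot of a flux-proteome correlation screen
#'
#' Pearson r versus \eqn{-\log_{10} p}, significant enzymes highlighted.
#'
#' @param x An `enzyme_correlation` from [correlate_proteome()].
#' @return A ggplot object.
#' @export
plot_correlation_screen <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- as.data.frame(x)
  df$neglog10p <- -log10(pmax(df$p, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$neglog10p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Pearson r (flux vs abundance)",
                  y = expression(-log[10] ~ p),
                  colour = sprintf("q < %.2g", attr(x, "alpha"))) +
    ggplot2::theme_minimal()
}
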