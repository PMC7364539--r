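# Topology of the metabolic network: metabolite connectivity (degree)
# distribution, its log-log slope (scale-free check), and reaction /
# metabolite overlap between reconstructions.

#' Metabolite connectivity distribution
#'
#' The connectivity k of a metabolite is the number of reactions in which
#' it takes part (non-zero stoichiometric coefficient).  Currency
#' metabolites such as ATP are deliberately not excluded: their
#' overrepresentation at high k is part of the expected scale-free
#' picture.  Compartment-duplicated species count separately unless
#' `collapse_compartments` is set.
#'
#' @param model A [metabolic_model()].
#' @param collapse_compartments Merge species differing only by an `_x`
#'   compartment suffix before counting.
#' @param n_top Length of the top-connected list.
#' @return A `connectivity_distribution`: list with `degrees` (named k
#'   per metabolite), `histogram` (data frame `k`, `n`), `top` (data
#'   frame of the most connected metabolites).
#' @export
connectivity_distribution <- function(model, collapse_compartments = FALSE,
                                      n_top = 10) {
  if (!length(model$reactions)) stop("model has no reactions", call. = FALSE)
  participants <- lapply(model$reactions, function(r) names(r$stoich))
  all_ids <- unlist(participants, use.names = FALSE)
  if (collapse_compartments) all_ids <- met_base_name(all_ids)
  k <- table(all_ids)
  degrees <- stats::setNames(as.integer(k), names(k))
  hist <- as.data.frame(table(k = as.integer(degrees)),
                        stringsAsFactors = FALSE)
  hist$k <- as.integer(as.character(hist$k))
  names(hist)[2] <- "n"
  hist$n <- as.integer(hist$n)
  ord <- order(degrees, decreasing = TRUE)
  top <- data.frame(metabolite = names(degrees)[ord], k = degrees[ord],
                    row.names = NULL)[seq_len(min(n_top, length(degrees))), ]
  structure(list(degrees = degrees, histogram = hist, top = top),
            class = "connectivity_distribution")
}

#' @export
print.connectivity_distribution <- function(x, ...) {
  cat("Metabolite connectivity:", length(x$degrees), "metabolites,",
      "k in", min(x$degrees), "..", max(x$degrees), "\n")
  cat("Top connected:", paste(utils::head(x$top$metabolite, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Log-log slope of the connectivity distribution
#'
#' Ordinary least squares of \eqn{\log_{10} n(k)} on \eqn{\log_{10} k}
#' over non-empty degree bins with k >= `k_min` (no logarithmic
#' binning).  A scale-free network shows an approximately linear decay;
#' the fitted slope depends on the fit range, so it is reported together
#' with the range used.
#'
#' @param dist A `connectivity_distribution` from
#'   [connectivity_distribution()].
#' @param k_min Smallest degree included in the fit.
#' @return List with `slope`, `se` (standard error), `n_bins` and
#'   `k_range`.
#' @export
loglog_slope <- function(dist, k_min = 1) {
  h <- dist$histogram
  h <- h[h$k >= k_min & h$n > 0, ]
  if (nrow(h) < 3)
    stop("need at least 3 non-empty degree bins at k >= ", k_min, call. = FALSE)
  fit <- stats::lm(log10(n) ~ log10(k), data = h)
  co <- summary(fit)$coefficients
  list(slope = unname(co[2, 1]), se = unname(co[2, 2]),
       n_bins = nrow(h), k_range = range(h$k))
}

#' Reaction and metabolite overlap between models
#'
#' Venn-region counts of the reaction-id and metabolite-id sets of two or
#' three reconstructions sharing an identifier namespace.
#'
#' @param models Named list of 2 or 3 [metabolic_model()] objects.
#' @return An `overlap_counts`: list with `reactions` and `metabolites`,
#'   each a named vector of region counts (`"A"`, `"B"`, `"A&B"`, ... for
#'   the model names), plus `labels`.
#' @export
model_overlap <- function(models) {
  if (length(models) < 2 || length(models) > 3)
    stop("model_overlap takes 2 or 3 models", call. = FALSE)
  labs <- names(models)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- LETTERS[seq_along(models)]
  sets_of <- function(get_ids) {
    sets <- lapply(models, get_ids)
    for (i in seq_along(sets))
      if (anyDuplicated(sets[[i]]))
        stop("duplicate ids within model '", labs[i], "'", call. = FALSE)
    names(sets) <- labs
    venn_regions(sets)
  }
  structure(list(reactions = sets_of(function(m) names(m$reactions)),
                 metabolites = sets_of(function(m) m$metabolites$id),
                 labels = labs),
            class = "overlap_counts")
}

venn_regions <- function(sets) {
  labs <- names(sets)
  slabs <- sort(labs)                     # canonical region names
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row)
    paste(sort(labs[row]), collapse = "&"))
  counts <- table(pattern)
  # all regions, including empty ones, in canonical order
  combos <- unlist(lapply(seq_along(slabs), function(k)
    utils::combn(slabs, k, paste, collapse = "&", simplify = FALSE)))
  out <- stats::setNames(integer(length(combos)), combos)
  out[names(counts)] <- as.integer(counts)
  out
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("Model overlap (", paste(x$labels, collapse = ", "), ")\n", sep = "")
  cat("  reactions:  "); print(x$reactions)
  cat("  metabolites:"); print(x$metabolites)
  invisible(x)
}

#' Plot the connectivity distribution on log-log axes
#'
#' @param dist A `connectivity_distribution`.
#' @param k_min Fit range passed to [loglog_slope()].
#' @return A ggplot object with the OLS fit line.
#' @export
plot_connectivity <- function(dist, k_min = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  fit <- loglog_slope(dist, k_min = k_min)
  h <- dist$histogram[dist$histogram$n > 0, ]
  ggplot2::ggplot(h, ggplot2::aes(x = log10(.data$k), y = log10(.data$n))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope,
                         intercept = mean(log10(h$n)) -
                           fit$slope * mean(log10(h$k)),
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(x = expression(log[10] ~ k), y = expression(log[10] ~ n),
                  title = sprintf("slope = %.2f (SE %.2f)", fit$slope, fit$se)) +
    ggplot2::theme_minimal()
}
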