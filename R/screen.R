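#' Define a strain by its gene deletions
#'
#' @param name Strain name (unique within a screen).
#' @param deleted_genes Character vector of deleted gene ids; empty for
#'   the wild type.
#' @return A list of class `"cf_strain"`.
#' @export
strain <- function(name, deleted_genes = character()) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  structure(list(name = name, deleted_genes = unique(deleted_genes)),
            class = "cf_strain")
}

#' Strain-by-substrate growth screen
#'
#' For every strain/medium combination: apply the gene deletions, apply
#' the medium, maximise biomass.  Growth is called when the maximal
#' specific growth rate exceeds `epsilon`; an infeasible LP counts as
#' no growth, not an error.
#'
#' @param model A [metabolic_model()].
#' @param strains List of [strain()] definitions.
#' @param substrates Named list of [medium()] objects (names become
#'   columns).
#' @param epsilon Growth threshold (h\eqn{^{-1}}); far below any
#'   biological growth rate, above LP noise.
#' @return A `growth_matrix`: list with logical matrix `grows` and
#'   numeric matrix `mu_max` (strains x substrates).
#' @export
growth_screen <- function(model, strains, substrates, epsilon = 1e-6) {
  stopifnot(length(strains) > 0)
  snames <- vapply(strains, function(s) s$name, character(1))
  if (anyDuplicated(snames)) stop("strain names must be unique", call. = FALSE)
  cnames <- names(substrates)
  if (length(substrates) && (is.null(cnames) || any(!nzchar(cnames))))
    stop("substrate media must be named", call. = FALSE)
  mu <- matrix(0, length(strains), length(substrates),
               dimnames = list(snames, cnames))
  for (s in seq_along(strains)) {
    mut <- apply_gene_deletion(model, strains[[s]]$deleted_genes)
    for (m in seq_along(substrates)) {
      cond <- apply_medium(mut, substrates[[m]])
      sol <- solve_fba(cond, sense = "max")
      mu[s, m] <- if (sol$status == "optimal") sol$objective_value else 0
    }
  }
  structure(list(grows = mu > epsilon, mu_max = mu, epsilon = epsilon),
            class = "growth_matrix")
}

#' @export
print.growth_matrix <- function(x, ...) {
  disp <- ifelse(x$grows, "+", "-")
  cat("Growth screen (", nrow(disp), " strains x ", ncol(disp),
      " substrates, epsilon = ", format(x$epsilon), " h-1)\n", sep = "")
  print(as.data.frame(disp), ...)
  invisible(x)
}

#' Medium supplementation rescue test
#'
#' Evaluates growth of a (mutant) strain on a base medium without and
#' with an additional exchange opened, e.g. the rescue of the
#' glyoxylate-shunt deletion on C1 substrates by supplying glyoxylate.
#'
#' @param model A [metabolic_model()].
#' @param strain_def A [strain()].
#' @param base_medium A [medium()].
#' @param supplement_id Exchange reaction id of the supplement.
#' @param epsilon Growth threshold.
#' @return List with logical elements `before` and `after` and the two
#'   growth rates.
#' @export
rescue_test <- function(model, strain_def, base_medium, supplement_id,
                        epsilon = 1e-6) {
  if (!supplement_id %in% find_exchanges(model))
    stop("'", supplement_id, "' is not an exchange reaction", call. = FALSE)
  mut <- apply_gene_deletion(model, strain_def$deleted_genes)
  grow <- function(med) {
    sol <- solve_fba(apply_medium(mut, med), sense = "max")
    if (sol$status == "optimal") sol$objective_value else 0
  }
  mu0 <- grow(base_medium)
  med2 <- base_medium
  med2$supplements <- unique(c(med2$supplements, supplement_id))
  mu1 <- grow(med2)
  list(before = mu0 > epsilon, after = mu1 > epsilon,
       mu_before = mu0, mu_after = mu1)
}

#' Compare a growth matrix with a reference
#'
#' @param matrix A `growth_matrix` from [growth_screen()] or a logical
#'   matrix.
#' @param reference_matrix Logical matrix with identical row/column
#'   labels (any order).
#' @return Data frame of mismatching cells (`strain`, `substrate`,
#'   `predicted`, `reference`); zero rows means full concordance.
#' @export
compare_to_reference <- function(matrix, reference_matrix) {
  g <- if (inherits(matrix, "growth_matrix")) matrix$grows else matrix
  stopifnot(is.logical(g), is.logical(reference_matrix))
  if (!setequal(rownames(g), rownames(reference_matrix)) ||
      !setequal(colnames(g), colnames(reference_matrix))) {
    bad_r <- c(setdiff(rownames(g), rownames(reference_matrix)),
               setdiff(rownames(reference_matrix), rownames(g)))
    bad_c <- c(setdiff(colnames(g), colnames(reference_matrix)),
               setdiff(colnames(reference_matrix), colnames(g)))
    stop("label mismatch; rows: {", paste(bad_r, collapse = ", "),
         "}, columns: {", paste(bad_c, collapse = ", "), "}", call. = FALSE)
  }
  ref <- reference_matrix[rownames(g), colnames(g), drop = FALSE]
  idx <- which(g != ref, arr.ind = TRUE)
  data.frame(strain = rownames(g)[idx[, 1]],
             substrate = colnames(g)[idx[, 2]],
             predicted = g[idx],
             reference = ref[idx],
             row.names = NULL)
}
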