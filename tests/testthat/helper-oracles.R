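# Independent oracles and shared fixtures for the test suite.

# Brute-force LP oracle: enumerate the vertices of {S v = 0, lb <= v <= ub}
# by fixing (n - rank(S)) variables at bounds and solving for the rest.
# Deliberately independent of the package's simplex implementation.
enum_fba_oracle <- function(model, objective_id, maximize = TRUE) {
  S <- build_stoichiometric_matrix(model)
  bn <- flux_bounds(model)
  lb <- unname(bn$lb); ub <- unname(bn$ub)
  obj <- as.numeric(names(model$reactions) == objective_id)
  n <- length(obj)
  r <- qr(S)$rank
  nfix <- n - r
  best <- NULL
  idxsets <- if (nfix == 0) list(integer(0)) else
    utils::combn(n, nfix, simplify = FALSE)
  for (fix in idxsets) {
    free <- setdiff(seq_len(n), fix)
    grid <- if (nfix == 0) matrix(numeric(0), 1, 0) else
      as.matrix(expand.grid(lapply(fix, function(j) unique(c(lb[j], ub[j])))))
    for (g in seq_len(nrow(grid))) {
      xf <- as.numeric(grid[g, ])
      rhs <- -(if (nfix) S[, fix, drop = FALSE] %*% xf else
        matrix(0, nrow(S), 1))
      Sfree <- S[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(Sfree, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(Sfree %*% sol - rhs)) > 1e-8) next
      x <- numeric(n); x[fix] <- xf; x[free] <- sol
      if (all(x >= lb - 1e-8 & x <= ub + 1e-8)) {
        v <- sum(obj * x)
        if (is.null(best) || (maximize && v > best) || (!maximize && v < best))
          best <- v
      }
    }
  }
  best  # NULL if infeasible
}

# three-reaction chain: uptake bound -10, A -> B, B drained by biomass
chain_model <- function(uptake = 10, double_B = 1) {
  metabolic_model(list(
    reaction("EX_A", c(A = -1), lb = -uptake, ub = 1000),
    reaction("S2", c(A = -1, B = double_B)),
    reaction("BIOMASS", c(B = -1), lb = 0, ub = 1000)
  ), objective_id = "BIOMASS")
}

# cached mini-model and panel shared across tests
minicella <- make_minicella_model()
panel_media <- minicella_media()
panel_strains <- minicella_strains()

# flux solutions for the three proteomics conditions, computed once
proteome_solutions <- local({
  media <- minicella_media(c("methane", "succinate", "propane"))
  lapply(media, function(m) solve_fba(apply_medium(minicella, m), refine = TRUE))
})

planted_panel <- c("Msil_1651", "Msil_1641", "Msil_3785", "Msil_1718",
                   "Msil_1714")
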