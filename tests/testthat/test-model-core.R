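test_that("stoichiometric matrix assembly matches reaction definitions", {
  # single conversion: one column, -1/+1
  m1 <- metabolic_model(list(reaction("R1", c(A = -1, B = 1))))
  S1 <- build_stoichiometric_matrix(m1)
  expect_equal(dim(S1), c(2L, 1L))
  expect_equal(S1["A", "R1"], -1)
  expect_equal(S1["B", "R1"], 1)

  # degenerate: empty model gives a 0 x 0 matrix
  m0 <- metabolic_model(list())
  expect_equal(dim(build_stoichiometric_matrix(m0)), c(0L, 0L))

  # chain EX_A, A -> B, B -> biomass: 2 x 3 with exactly 4 non-zeros
  # (the boundary side of the exchange and the biomass drain are not rows)
  S <- build_stoichiometric_matrix(chain_model())
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(sum(S != 0), 4L)
})

test_that("matrix assembly round-trips all stoichiometries exactly", {
  model <- minicella
  S <- build_stoichiometric_matrix(model)
  for (r in model$reactions) {
    keep <- !model$metabolites$boundary[match(names(r$stoich),
                                              model$metabolites$id)]
    expect_equal(S[names(r$stoich)[keep], r$id],
                 r$stoich[keep], ignore_attr = TRUE)
  }
  # double-counting identity: sum of degrees = sum of support sizes
  expect_equal(sum(S != 0),
               sum(vapply(model$reactions,
                          function(r) sum(names(r$stoich) %in% rownames(S)),
                          integer(1))))
})

test_that("model validation rejects structural errors", {
  expect_error(reaction("bad", numeric(0)), "empty stoichiometry")
  expect_error(reaction("bad", c(A = 0)), "zero stoichiometric")
  expect_error(reaction("bad", c(A = -1), lb = 5, ub = 1), "lower bound")
  expect_error(
    metabolic_model(list(reaction("R1", c(A = -1)),
                         reaction("R1", c(B = -1)))),
    "duplicate reaction")
  expect_error(
    metabolic_model(list(reaction("R1", c(A = -1))), objective_id = "nope"),
    "objective")
  # unknown metabolite named in the error
  m <- metabolic_model(list(reaction("R1", c(A = -1, B = 1))))
  m$reactions$R1$stoich <- c(A = -1, ghost = 1)
  expect_error(build_stoichiometric_matrix(m), "R1.*ghost")
})

test_that("gene deletion zeroes bounds, warns on unknowns, is idempotent and monotone", {
  model <- minicella
  del <- apply_gene_deletion(model, "Msil_3157")
  expect_equal(del$reactions$ICL$lb, 0)
  expect_equal(del$reactions$ICL$ub, 0)
  expect_equal(del$reactions$MS$ub, model$reactions$MS$ub)

  # OR-rescued reaction is retained
  del2 <- apply_gene_deletion(model, "Msil_0731")   # ACMO gpr: 0731 or 1926
  expect_gt(del2$reactions$ACMO$ub, 0)
  del3 <- apply_gene_deletion(model, c("Msil_0731", "Msil_1926"))
  expect_equal(del3$reactions$ACMO$ub, 0)

  # unknown gene: warning, model unchanged
  expect_warning(un <- apply_gene_deletion(model, "Msil_9999"), "not in model")
  expect_equal(flux_bounds(un), flux_bounds(model))

  # idempotence
  once <- apply_gene_deletion(model, c("Msil_3157", "Msil_1325"))
  twice <- apply_gene_deletion(once, c("Msil_3157", "Msil_1325"))
  expect_equal(flux_bounds(once), flux_bounds(twice))

  # monotonicity: enlarging the deletion set never re-activates a reaction
  genes <- model$genes
  small <- apply_gene_deletion(model, genes[1:3])
  big <- apply_gene_deletion(model, genes[1:10])
  closed_small <- names(which(flux_bounds(small)$ub == 0 &
                                flux_bounds(small)$lb == 0))
  closed_big <- names(which(flux_bounds(big)$ub == 0 &
                              flux_bounds(big)$lb == 0))
  expect_true(all(closed_small %in% closed_big))
})

test_that("media close all non-free uptakes and open the requested ones", {
  model <- minicella
  on_ch4 <- apply_medium(model, medium(c(EX_ch4 = 10)))
  expect_equal(on_ch4$reactions$EX_ch4$lb, -10)
  expect_equal(on_ch4$reactions$EX_ac$lb, 0)
  expect_equal(on_ch4$reactions$EX_ppa$lb, 0)
  # free mineral species stay open; CO2 export remains possible
  expect_lt(on_ch4$reactions$EX_o2$lb, 0)
  expect_equal(on_ch4$reactions$EX_co2$ub, 1000)

  # supplements open an extra exchange
  withglx <- apply_medium(model, medium(c(EX_ma = 10), supplements = "EX_glx"))
  expect_equal(withglx$reactions$EX_glx$lb, -10)

  # empty medium: no carbon, no growth
  starved <- apply_medium(model, medium())
  sol <- solve_fba(starved)
  expect_lt(abs(sol$objective_value), 1e-9)

  expect_error(apply_medium(model, medium(c(ICL = 5))), "not an exchange")
  expect_error(medium(c(EX_ch4 = -1)), "non-negative")
})
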