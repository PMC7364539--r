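test_that("toy pathway models realise their designed yield exactly", {
  for (cfg in list(list(len = 1, y = 1), list(len = 3, y = 0.5),
                   list(len = 2, y = 2, seed = 4),
                   list(len = 4, y = 1.5, seed = 9))) {
    toy <- make_toy_pathway_model(chain_length = cfg$len, yield = cfg$y,
                                  seed = cfg$seed)
    toy <- apply_medium(toy, medium(c(EX_S = 10)))
    yr <- max_growth_at_uptake(toy, "EX_S", 10)
    expect_equal(yr$growth, cfg$y * 10, tolerance = 1e-8)
  }
  expect_error(make_toy_pathway_model(yield = -1), "positive")
})

test_that("generators are deterministic given a seed and leave global RNG alone", {
  t1 <- make_toy_pathway_model(chain_length = 3, seed = 42)
  t2 <- make_toy_pathway_model(chain_length = 3, seed = 42)
  expect_identical(t1$reactions, t2$reactions)

  p1 <- simulate_proteome(minicella, proteome_solutions, planted_panel,
                          noise_sd = 0.1, n_background = 20, seed = 99)
  p2 <- simulate_proteome(minicella, proteome_solutions, planted_panel,
                          noise_sd = 0.1, n_background = 20, seed = 99)
  expect_identical(p1, p2)

  g1 <- simulate_growth_series(5.2, 0.05, seed = 13)
  g2 <- simulate_growth_series(5.2, 0.05, seed = 13)
  expect_identical(g1, g2)

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_growth_series(5.2, 0.05, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("generated models pass validation and energy QC unless violation requested", {
  models <- list(make_toy_pathway_model(2, 1),
                 make_toy_pathway_model(3, 2, atp_per_mmol = 2, seed = 5),
                 make_minicella_model())
  for (m in models) {
    expect_true(validate_model(m))
    expect_true(check_energy_cycles(m)$pass)
  }
  expect_false(check_energy_cycles(
    make_toy_pathway_model(1, 1, atp_loop = TRUE))$pass)
})

test_that("the mini-model encodes the mutant biology of the organism", {
  model <- minicella
  # serine-cycle anaplerosis: on methane ICL must carry flux, MS need not
  sol <- solve_fba(apply_medium(model, panel_media$methane), refine = TRUE)
  expect_gt(sol$objective_value, 1e-3)
  expect_gt(abs(sol$fluxes[["ICL"]]), 1e-6)
  expect_lt(abs(sol$fluxes[["MS"]]), 1e-9)

  # acetol-oxidation mutant: keeps (reduced-yield) propane growth, loses
  # 2-propanol and acetone growth
  d1641 <- apply_gene_deletion(model, "Msil_1641")
  extra <- minicella_media(c("propane", "2-propanol", "acetone"))
  y_wt <- max_growth_at_uptake(apply_medium(model, extra$propane), "EX_ppa", 10)
  y_mut <- max_growth_at_uptake(apply_medium(d1641, extra$propane), "EX_ppa", 10)
  expect_gt(y_mut$growth, 1e-6)
  expect_lt(y_mut$yield_value, y_wt$yield_value - 1e-6)
  for (med in extra[c("2-propanol", "acetone")]) {
    mu <- solve_fba(apply_medium(d1641, med))$objective_value
    expect_lt(mu, 1e-6)
  }

  # no ethylmalonyl-CoA pathway: acetate growth requires the shunt genes
  expect_lt(solve_fba(apply_medium(apply_gene_deletion(model, "Msil_3157"),
                                   panel_media$acetate))$objective_value, 1e-6)

  # fixture serialises to both formats
  td <- withr::local_tempdir()
  paths <- write_fixtures(td, seed = 2)
  expect_true(all(file.exists(paths)))
  back <- read_sbml(paths[["sbml"]])
  expect_equal(n_reactions(back), n_reactions(model))
})

test_that("planted proteome entries track flux exactly at zero noise", {
  tab <- simulate_proteome(minicella, proteome_solutions, planted_panel,
                           noise_sd = 0, n_background = 10, seed = 8)
  for (g in planted_panel) {
    prof <- gene_flux_profile(proteome_solutions, minicella, g)
    if (stats::sd(prof) > 0)
      expect_equal(abs(stats::cor(tab[g, ], prof)), 1, tolerance = 1e-9)
  }
  expect_error(simulate_proteome(minicella, proteome_solutions, "nope",
                                 n_background = 5, seed = 1), "not in any GPR")
})

test_that("growth series generator matches its closed form", {
  s <- simulate_growth_series(5.2, 0.05, od0 = 0.05, noise_sd = 0,
                              n_points = 10, seed = 1, volume_ml = 100,
                              t_max = 50)
  dw <- od_to_dry_weight(s$od, s$volume_ml) / 1000
  expect_equal(dw, dw[1] * exp(0.05 * s$time_h), tolerance = 1e-9)
  expect_equal((s$substrate_mmol[1] - s$substrate_mmol) / 1000,
               (dw - dw[1]) / 5.2, tolerance = 1e-12)
  expect_true(all(diff(s$substrate_mmol) <= 0))
})
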