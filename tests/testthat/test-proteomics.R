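fake_solution <- function(fluxes) {
  structure(list(status = "optimal", fluxes = fluxes), class = "flux_solution")
}

test_that("gene flux profiles aggregate absolute fluxes over the gene's reactions", {
  m <- metabolic_model(list(
    reaction("R1", c(A = -1, B = 1), gpr = "g1"),
    reaction("R2", c(B = -1, A = 1), gpr = "g1", reversible = TRUE),
    reaction("R3", c(A = -1, C = 1), gpr = "g2")
  ))
  sols <- list(c1 = fake_solution(c(R1 = 0.5, R2 = 0, R3 = 1)),
               c2 = fake_solution(c(R1 = 0, R2 = 0, R3 = 2)),
               c3 = fake_solution(c(R1 = 0.3, R2 = -0.2, R3 = 0)))
  # single-reaction gene: profile is that reaction's |flux|
  expect_equal(gene_flux_profile(sols, m, "g2"),
               c(c1 = 1, c2 = 2, c3 = 0))
  # two reactions, opposite signs: |0.3| + |-0.2|
  expect_equal(gene_flux_profile(sols, m, "g1")[["c3"]], 0.5)
  expect_equal(gene_flux_profile(sols, m, "g1", aggregate = "max")[["c3"]], 0.3)
  # unmapped gene is a signalled exclusion, not a silent zero
  expect_error(gene_flux_profile(sols, m, "g9"), "not mappable")
})

test_that("Pearson r and the 1-df t-test p-value match closed forms", {
  out <- pearson_r_p(c(1, 2, 3), c(2, 4, 6))
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)
  # r = 0.5 at n = 3: p = 2/3 from the arctan CDF of t with 1 df
  out2 <- pearson_r_p(c(1, 2, 3), c(1, 3, 2))
  expect_equal(out2$r, 0.5, tolerance = 1e-12)
  expect_equal(out2$p, 2 / 3, tolerance = 1e-12)
  # independent check of the t transform on a longer vector
  set.seed(42)
  x <- rnorm(10); y <- x + rnorm(10)
  out3 <- pearson_r_p(x, y)
  t_hand <- out3$r * sqrt((10 - 2) / (1 - out3$r^2))
  expect_equal(out3$p, 2 * stats::pt(-abs(t_hand), df = 8), tolerance = 1e-12)
  expect_error(pearson_r_p(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(pearson_r_p(c(1, 2), c(3, 4)), "at least 3")
})

test_that("with three conditions p depends only on |r| and decreases in it", {
  # sweep the angle between y and x in the 2-d centred space of 3 points
  u <- c(-1, 0, 1) / sqrt(2)
  w <- c(1, -2, 1) / sqrt(6)
  thetas <- seq(0.05, pi / 2 - 0.05, length.out = 20)
  res <- t(vapply(thetas, function(th) {
    y <- cos(th) * u + sin(th) * w + 5
    unlist(pearson_r_p(c(1, 2, 3), y))
  }, c(r = 0, p = 0)))
  expect_equal(res[, "r"], cos(thetas), tolerance = 1e-10)
  expect_true(all(diff(res[, "p"]) > 0))        # |r| down => p up
  # mirrored correlation gives identical p
  y_neg <- -cos(0.3) * u + sin(0.3) * w + 5
  y_pos <- cos(0.3) * u + sin(0.3) * w + 5
  expect_equal(pearson_r_p(c(1, 2, 3), y_neg)$p,
               pearson_r_p(c(1, 2, 3), y_pos)$p, tolerance = 1e-12)
})

test_that("BH adjustment is the step-up minimum, order-equivariant, >= p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- c(0.001, 0.02, 0.5, 0.04, 0.9)
  q <- bh_fdr(p)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(q >= p))
  # hand step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
  ord <- order(p); m <- length(p)
  qs <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q_hand <- numeric(m); q_hand[ord] <- qs
  expect_equal(q, q_hand)
})

test_that("BH keeps the false-discovery proportion at the nominal level", {
  set.seed(7)
  fdp <- replicate(1000, {
    q <- bh_fdr(runif(50))
    mean(q < 0.05) > 0   # all nulls: any discovery is false
  })
  expect_lt(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("the proteome screen recovers noiseless planted enzymes exactly", {
  tab <- simulate_proteome(minicella, proteome_solutions, planted_panel,
                           noise_sd = 0, n_background = 50, seed = 3)
  res <- correlate_proteome(minicella, proteome_solutions, tab)
  hits <- res$id[res$significant]
  planted_res <- res[res$id %in% planted_panel, ]
  expect_equal(planted_res$r, rep(1, length(planted_panel)), tolerance = 1e-9)
  expect_true(all(planted_panel %in% hits))
  # non-metabolic background proteins are excluded with a reason
  excl <- attr(res, "excluded")
  expect_true(any(excl$reason == "not_mappable"))
  expect_false(any(res$id %in% excl$id))
})

test_that("correlation results are invariant to global flux scaling", {
  tab <- simulate_proteome(minicella, proteome_solutions, planted_panel,
                           noise_sd = 0.1, n_background = 30, seed = 5)
  res1 <- correlate_proteome(minicella, proteome_solutions, tab)
  scaled <- lapply(proteome_solutions, function(s) {
    s$fluxes <- s$fluxes * 3.7
    s
  })
  res2 <- correlate_proteome(minicella, scaled, tab)
  expect_equal(res2$r[match(res1$id, res2$id)], res1$r, tolerance = 1e-9)
})

test_that("proteome screen validates its inputs", {
  tab <- simulate_proteome(minicella, proteome_solutions, planted_panel[1],
                           noise_sd = 0, n_background = 5, seed = 1)
  expect_error(correlate_proteome(minicella, proteome_solutions,
                                  tab[, 1, drop = FALSE]), ">= 3")
  bad <- tab; colnames(bad) <- c("x", "y", "z")
  expect_error(correlate_proteome(minicella, proteome_solutions, bad),
               "no flux solution|no overlap")
})
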