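test_that("connectivity counts reactions per metabolite", {
  # linear chain: end metabolites k = 1, interior k = 2
  L <- 6
  rxns <- lapply(seq_len(L), function(i)
    reaction(paste0("R", i), stats::setNames(c(-1, 1),
                                             paste0("m", c(i, i + 1)))))
  chain <- metabolic_model(rxns)
  cd <- connectivity_distribution(chain)
  expect_equal(unname(cd$degrees[c("m1", paste0("m", L + 1))]), c(1L, 1L))
  expect_equal(cd$histogram$n[cd$histogram$k == 1], 2L)
  expect_equal(cd$histogram$n[cd$histogram$k == 2], L - 1L)

  # a metabolite in exactly 3 reactions has k = 3
  m3 <- metabolic_model(list(reaction("a", c(X = -1, P = 1)),
                             reaction("b", c(X = -1, Q = 1)),
                             reaction("c", c(Q = -1, X = 1))))
  expect_equal(unname(connectivity_distribution(m3)$degrees["X"]), 3L)

  # sum rule: total degree equals total reaction support
  cdm <- connectivity_distribution(minicella)
  expect_equal(sum(cdm$degrees),
               sum(vapply(minicella$reactions,
                          function(r) length(r$stoich), integer(1))))
  # currency metabolites top the list
  expect_true("atp_c" %in% cdm$top$metabolite[1:5])
})

test_that("log-log slope fits exact power laws and flags thin data", {
  k <- 1:50
  dist <- list(histogram = data.frame(k = k, n = 100 * k^-2.5))
  fit <- suppressWarnings(loglog_slope(dist))
  expect_equal(fit$slope, -2.5, tolerance = 1e-6)
  expect_lt(fit$se, 1e-6)

  flat <- list(histogram = data.frame(k = 1:10, n = rep(7, 10)))
  expect_equal(suppressWarnings(loglog_slope(flat))$slope, 0, tolerance = 1e-10)

  thin <- list(histogram = data.frame(k = c(1, 2), n = c(5, 3)))
  expect_error(loglog_slope(thin), "3 non-empty")
  # k_min restricts the fit range
  mixed <- list(histogram = data.frame(k = c(1, 2, 4, 8, 16),
                                       n = c(1000, 8 * 2^-2, 8 * 4^-2,
                                             8 * 8^-2, 8 * 16^-2)))
  expect_equal(suppressWarnings(loglog_slope(mixed, k_min = 2))$slope, -2, tolerance = 1e-8)
})

test_that("model overlap computes designed Venn regions and is label-symmetric", {
  mk <- function(ids) metabolic_model(lapply(ids, function(i)
    reaction(i, stats::setNames(-1, paste0("met_", i)))))
  A <- mk(c("r1", "r2", "r3", "r4"))
  B <- mk(c("r3", "r4", "r5"))
  C <- mk(c("r4", "r5", "r6", "r7"))
  ov <- model_overlap(list(A = A, B = B, C = C))
  expect_equal(unname(ov$reactions[c("A", "B", "C")]), c(2L, 0L, 2L))
  expect_equal(unname(ov$reactions["A&B"]), 1L)   # r3
  expect_equal(unname(ov$reactions["B&C"]), 1L)   # r5
  expect_equal(unname(ov$reactions["A&B&C"]), 1L) # r4
  expect_equal(sum(ov$reactions), 7L)             # regions sum to union

  # reordering models permutes labels, not counts
  ov2 <- model_overlap(list(C = C, A = A, B = B))
  expect_equal(sort(unname(ov2$reactions)), sort(unname(ov$reactions)))
  expect_equal(unname(ov2$reactions["A&B&C"]), 1L)

  # self-overlap and disjoint models
  self <- model_overlap(list(X = A, Y = A))
  expect_equal(unname(self$reactions["X&Y"]), 4L)
  expect_equal(unname(self$reactions["X"]) + unname(self$reactions["Y"]), 0L)
  disj <- model_overlap(list(X = mk("p1"), Y = mk("p2")))
  expect_equal(unname(disj$reactions["X&Y"]), 0L)
})
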