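test_that("parameter jitter respects the stated uniform bounds", {
  base <- applyOverrides(defaultParams(), c(V_SLET7 = 6))
  th0 <- samplePopulationParams(base, p = 0, nCells = 5, seed = 1)
  for (i in 1:5) expect_equal(unname(th0[i, ]), unname(base))
  th <- samplePopulationParams(base, p = 0.1, nCells = 200, seed = 2)
  expect_true(all(th[, "V_SLET7"] >= 5.4 & th[, "V_SLET7"] <= 6.6))
  expect_true(all(th >= 0))
  ## Src is jittered like any other parameter
  base2 <- applyOverrides(base, c(Src = 1e-6))
  th2 <- samplePopulationParams(base2, p = 0.5, nCells = 100, seed = 3)
  expect_gt(stats::sd(th2[, "Src"]), 0)
  expect_true(all(th2[, "Src"] >= 5e-7 & th2[, "Src"] <= 1.5e-6))
})

test_that("the sampler is unbiased (uniform-distribution oracle)", {
  th <- samplePopulationParams(defaultParams(), p = 0.25, nCells = 10000,
                               seed = 4)
  expect_equal(mean(th[, "V_SLET7"]), 3, tolerance = 0.01)
  expect_equal(mean(th[, "k_1"]), 10, tolerance = 0.01)
  ## uniform variance (theta * p)^2 / 3
  expect_equal(stats::var(th[, "V_SLET7"]), (3 * 0.25)^2 / 3,
               tolerance = 0.05)
})

test_that("endpoint correlations behave and signal degenerate input", {
  base <- applyOverrides(defaultParams(), c(V_SLET7 = 6, Src = 1e-6))
  pr <- runPopulation(base, p = 0.1, nCells = 12, transientH = 20, seed = 5)
  expect_equal(endpointCorrelation(pr, "Let7", "Let7"), 1)
  r <- endpointCorrelation(pr, "Let7", "IL6")
  expect_true(r >= -1 && r <= 1)
  ## zero jitter -> identical cells -> zero variance -> undefined
  pr0 <- runPopulation(base, p = 0, nCells = 5, transientH = 5, seed = 6)
  expect_error(endpointCorrelation(pr0, "Let7", "IL6"),
               class = "episwitch_undefined_correlation")
})

test_that("a resting population stays mostly non-transformed and shows the
           negative Let-7/IL6 pattern", {
  base <- applyOverrides(defaultParams(), c(V_SLET7 = 6, Src = 1e-6))
  pr <- runPopulation(base, p = 0.1, nCells = 30, seed = 7)
  expect_lt(fractionTransformed(pr), 0.3)
  expect_lt(endpointCorrelation(pr, "Let7", "IL6"), 0)
  ## classification matches the per-cell midpoint rule
  ok <- !is.na(pr@transformed)
  expect_identical(pr@transformed[ok],
                   unname(pr@endpoints[ok, "NFKB"] >
                            pr@cellParams[ok, "NFKB_T"] / 2))
})
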