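test_that("only pure synthesis channels fire from an empty state", {
  p <- applyOverrides(defaultParams(),
                      c(V_SCERNA = 0.2, V_SMPTEN1 = 0.1, V_SMPTEN = 0.3))
  ch <- buildReactions(p, switchVariant(TRUE, TRUE), omega = 100)
  n0 <- setNames(numeric(18), stateNames())
  a <- vapply(ch, function(c) c$propensity(n0), numeric(1))
  pos <- vapply(ch, function(c) c$name, character(1))[a > 0]
  expect_setequal(pos, c("Let7 synthesis", "mIL6 basal synthesis",
                         "mRas synthesis", "mPTEN synthesis",
                         "ceRNA synthesis", "mPTEN1 synthesis"))
})

test_that("bimolecular propensities reproduce the deterministic flux", {
  omega <- 100
  ch <- buildReactions(defaultParams(), omega = omega)
  n <- setNames(numeric(18), stateNames())
  n["Let7"] <- omega; n["mIL6"] <- omega    # 1 uM each
  bind <- Filter(function(c) c$name == "Let7+mIL6 binding", ch)[[1]]
  expect_equal(bind$propensity(n), omega * defaultParams()[["k_1"]])
})

test_that("binding stoichiometries conserve free plus bound counts", {
  ch <- buildReactions(defaultParams(), switchVariant(TRUE, TRUE))
  pairs <- list(c("Let7", "mIL6", "mIL6Let7"),
                c("Let7", "mRas", "mRasLet7"),
                c("miR21", "mPTEN", "miRmpten"),
                c("Let7", "ceRNA", "ceRNAlet7"),
                c("miR21", "mPTEN1", "miRmpten1"))
  for (c in ch) {
    if (!grepl("binding|dissociation", c$name)) next
    pr <- Filter(function(x) c$stoich[[x[3]]] != 0L, pairs)[[1]]
    ## free + bound is conserved for both partners
    expect_identical(c$stoich[[pr[1]]] + c$stoich[[pr[3]]], 0L)
    expect_identical(c$stoich[[pr[2]]] + c$stoich[[pr[3]]], 0L)
  }
})

test_that("reference and compiled propensities agree on random states", {
  set.seed(9)
  p <- applyOverrides(defaultParams(),
                      c(Src = 1e-5, V_SCERNA = 0.2, V_SMPTEN1 = 0.1,
                        V_SMPTEN = 0.2))
  ch <- buildReactions(p, switchVariant(TRUE, TRUE), omega = 100)
  for (rep in 1:10) {
    n <- setNames(sample(0:300, 18, replace = TRUE), stateNames())
    n["NFKB"] <- sample(0:100, 1)
    aR <- vapply(ch, function(c) c$propensity(n), numeric(1))
    aC <- episwitch:::.ssaPropensities(n, p, 100)
    expect_equal(unname(aR), unname(aC), tolerance = 1e-12)
    expect_true(all(aC >= 0))
  }
})

test_that("an absorbing system stays at its initial state", {
  p <- decayOnlyParams()
  init <- setNames(numeric(18), stateNames())
  tr <- ssaRun(p, init = init, omega = 100, tEnd = 5, seed = 1)
  expect_true(all(tr@counts == 0))
  expect_equal(tr@nEvents, 0)
})

test_that("identical seeds give bit-identical event sequences", {
  p <- applyOverrides(defaultParams(), c(Src = 1e-6, V_SLET7 = 3.5))
  t1 <- ssaRun(p, omega = 50, tEnd = 0.5, seed = 11, recordEvents = TRUE)
  t2 <- ssaRun(p, omega = 50, tEnd = 0.5, seed = 11, recordEvents = TRUE)
  t3 <- ssaRun(p, omega = 50, tEnd = 0.5, seed = 12, recordEvents = TRUE)
  expect_identical(t1@events, t2@events)
  expect_identical(t1@counts, t2@counts)
  expect_gt(t1@nEvents, 0)
  expect_false(identical(t1@events, t3@events))
})

test_that("growing system size drives the SSA toward the ODE solution", {
  ## non-switching resting scenario: ensemble-mean Let-7 vs the ODE
  p <- defaultParams()                 # Src = 0
  det <- simulateSwitch(p, icSetA(), tEnd = 4)
  let7d <- trajStates(det)[, "Let7"]
  keep <- trajTimes(det) >= 1          # skip the tiny-count start-up
  maxDev <- function(omega, nRuns = 6) {
    acc <- 0
    for (s in seq_len(nRuns))
      acc <- acc + ssaRun(p, init = icSetA(), omega = omega, tEnd = 4,
                          seed = 40 + s)@counts[, "Let7"] / omega
    m <- acc / nRuns
    max(abs(m[keep] - let7d[keep]) / let7d[keep])
  }
  d1e3 <- maxDev(1000)
  d1e4 <- maxDev(10000)
  expect_lt(d1e4, d1e3)                # fluctuations shrink with omega
  expect_lt(d1e4, 0.05)                # and the mean matches the ODE
})

test_that("single-cell ensembles classify to 0 or 1 and reproduce by seed", {
  p <- applyOverrides(defaultParams(), c(Src = 1e-6, V_SLET7 = 3.5))
  e1 <- ensembleProportion(p, nCells = 1, transientH = 5, seed = 2)
  expect_true(e1@proportion %in% c(0, 1))
  e2 <- ensembleProportion(p, nCells = 4, transientH = 5, seed = 3)
  e3 <- ensembleProportion(p, nCells = 4, transientH = 5, seed = 3)
  expect_identical(e2@transformed, e3@transformed)
})
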