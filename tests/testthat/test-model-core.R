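test_that("an empty system without sources has zero derivatives", {
  p <- decayOnlyParams()
  y <- setNames(numeric(18), stateNames())
  d <- switchRHS(0, y, p, variant = switchVariant(TRUE, TRUE))
  expect_equal(unname(d), rep(0, 18))
})

test_that("synthesis terms at an empty state match the rate constants", {
  y <- setNames(numeric(18), stateNames())
  d <- switchRHS(0, y, defaultParams())
  ## no Lin28 repression, binding or degradation: pure Let-7 synthesis
  expect_equal(d[["Let7"]], 3)
  expect_equal(d[["mRas"]], 0.005)
  expect_equal(d[["mIL6"]], 0.1)          # constitutive term only at NFKB = 0
  expect_equal(d[["NFKB"]], 0)
  expect_equal(d[["STAT3"]], 0)
})

test_that("binding fluxes are antisymmetric between partners and complex", {
  set.seed(42)
  p <- applyOverrides(defaultParams(),
                      c(V_SCERNA = 0.3, V_SMPTEN1 = 0.2, V_SMPTEN = 0.1))
  v <- switchVariant(TRUE, TRUE)
  pairs <- list(
    c("k_1", "Let7",  "mIL6",   "mIL6Let7"),
    c("k_3", "Let7",  "mRas",   "mRasLet7"),
    c("k_5", "miR21", "mPTEN",  "miRmpten"),
    c("k_7", "Let7",  "ceRNA",  "ceRNAlet7"),
    c("k_9", "miR21", "mPTEN1", "miRmpten1"))
  for (rep in 1:5) {
    y <- randomState()
    for (pr in pairs) {
      h <- 1e-6
      pp <- p; pp[pr[1]] <- p[pr[1]] + h
      pm <- p; pm[pr[1]] <- p[pr[1]] - h
      dd <- (switchRHS(0, y, pp, variant = v, check = FALSE) -
               switchRHS(0, y, pm, variant = v, check = FALSE)) / (2 * h)
      expect_lt(abs(dd[[pr[2]]] - dd[[pr[3]]]), 1e-6)
      expect_lt(abs(dd[[pr[2]]] + dd[[pr[4]]]), 1e-6)
    }
  }
})

test_that("the conserved NF-kB pool cannot be left in either direction", {
  set.seed(7)
  p <- defaultParams()
  for (rep in 1:10) {
    y <- randomState()
    y["NFKB"] <- 0
    expect_gte(switchRHS(0, y, p, check = FALSE)[["NFKB"]], 0)
    y["NFKB"] <- p[["NFKB_T"]]
    expect_lte(switchRHS(0, y, p, check = FALSE)[["NFKB"]], 0)
  }
})

test_that("inactive extensions leave the core equations bit-identical", {
  set.seed(11)
  for (rep in 1:10) {
    y <- randomState()
    y[c("ceRNA", "ceRNAlet7", "mPTEN1", "miRmpten1")] <- 0
    dCore <- switchRHS(0, y[stateNames(switchVariant())], defaultParams())
    dFull <- switchRHS(0, y, defaultParams(),
                       variant = switchVariant(TRUE, TRUE))
    expect_identical(unname(dCore),
                     unname(dFull[stateNames(switchVariant())]))
    expect_identical(unname(dFull[c("ceRNA", "ceRNAlet7", "mPTEN1",
                                    "miRmpten1")]), rep(0, 4))
  }
})

test_that("no flux leaves an empty pool", {
  set.seed(5)
  p <- applyOverrides(defaultParams(),
                      c(V_SCERNA = 0.1, V_SMPTEN1 = 0.1, V_SMPTEN = 0.1))
  v <- switchVariant(TRUE, TRUE)
  for (sp in stateNames()) {
    for (rep in 1:3) {
      y <- randomState()
      y[sp] <- 0
      expect_gte(switchRHS(0, y, p, variant = v, check = FALSE)[[sp]], 0)
    }
  }
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- applyOverrides(defaultParams(),
                      c(Src = 1e-4, V_SCERNA = 0.2, V_SMPTEN1 = 0.1))
  v <- switchVariant(TRUE, TRUE)
  y0 <- fullStateForTest <- icSetB(v)
  rFun <- function(t, y, parms)
    list(unname(switchRHS(t, setNames(y, stateNames()), parms,
                          variant = v, check = FALSE)))
  outR <- deSolve::lsoda(unname(y0), c(0, 120), rFun, p,
                         rtol = 1e-10, atol = 1e-12)
  trC <- simulateSwitch(p, y0, srcConstant(1e-4), tEnd = 2, variant = v,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(endState(trC)), unname(outR[nrow(outR), -1]),
               tolerance = 1e-6)
})

test_that("state diagnostics flag each invariant violation without raising", {
  p <- defaultParams()
  expect_length(validateState(icSetA(), p), 0)
  expect_length(validateState(icSetB(), p), 0)
  s <- icSetA(); s["NFKB"] <- 1.5
  expect_match(validateState(s, p), "exceeds total", all = FALSE)
  s2 <- icSetA(); s2["Let7"] <- -1
  expect_match(validateState(s2, p), "negative", all = FALSE)
  s3 <- fullState <- icSetA(switchVariant(cerna = TRUE)); s3["ceRNA"] <- 0.5
  expect_length(validateState(s3, p, switchVariant(cerna = TRUE)), 0)
  expect_match(validateState(s3, p), "variant is off", all = FALSE)
})
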