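test_that("jacobian of a decoupled decay system is diagonal with -k_D", {
  p <- decayOnlyParams()
  y <- setNames(runif(18, 0.5, 2), stateNames())
  y["NFKB"] <- 0.4
  J <- switchJacobian(p, y, switchVariant(TRUE, TRUE), src = 0)
  offDiag <- J; diag(offDiag) <- 0
  expect_lt(max(abs(offDiag)), 1e-8)
  expect_equal(J["Lin28", "Lin28"], -p[["k_DLIN28"]], tolerance = 1e-6)
  expect_equal(J["Let7", "Let7"], -p[["k_DLET7"]], tolerance = 1e-6)
  expect_equal(J["IL6", "IL6"], -p[["k_DIL6"]], tolerance = 1e-6)
  expect_equal(J["miR21", "miR21"], -p[["k_DMIR21"]], tolerance = 1e-6)
})

test_that("finite-difference and analytic jacobians agree", {
  set.seed(3)
  p <- applyOverrides(defaultParams(), c(Src = 1e-5, V_SMPTEN = 0.1))
  for (rep in 1:5) {
    y <- randomState()
    y[c("ceRNA", "ceRNAlet7", "mPTEN1", "miRmpten1")] <- 0
    Jfd <- switchJacobian(p, y[stateNames(switchVariant())])
    Jan <- episwitch:::jacAnalytic(episwitch:::fullState(y), p,
                                   p[["Src"]])[rownames(Jfd), colnames(Jfd)]
    expect_equal(Jfd, Jan, tolerance = 1e-4)
  }
})

test_that("the bistable regime carries two stable states and a saddle", {
  p6 <- applyOverrides(defaultParams(), c(V_SLET7 = 6))
  ss <- findSteadyStates(p6, src = 1e-6)
  stable <- Filter(function(s) s$stable, ss)
  unstable <- Filter(function(s) !s$stable, ss)
  expect_gte(length(stable), 2)
  expect_gte(length(unstable), 1)
  nfkb <- sort(vapply(stable, function(s) s$state[["NFKB"]], numeric(1)))
  expect_lt(nfkb[1], 0.01)              # non-transformed
  expect_gt(nfkb[length(nfkb)], 0.99)   # transformed
  for (s in ss) {
    expect_lte(s$residual, 1e-10)
    expect_identical(s$stable, s$leadingEigenvalue < 0)
  }
  ## polishing an already converged state leaves it unchanged
  pol <- episwitch:::newtonPolish(p6, episwitch:::fullState(stable[[1]]$state),
                                  src = 1e-6)
  expect_true(pol$converged)
  expect_equal(pol$state[names(stable[[1]]$state)], stable[[1]]$state,
               tolerance = 1e-8)
})

test_that("doubling the finite-difference step barely moves the spectrum", {
  p6 <- applyOverrides(defaultParams(), c(V_SLET7 = 6))
  ss <- findSteadyStates(p6, src = 1e-6, nStarts = 6)
  s <- Filter(function(s) s$stable, ss)[[1]]
  e1 <- max(Re(eigen(switchJacobian(p6, s$state, src = 1e-6),
                     only.values = TRUE)$values))
  e2 <- max(Re(eigen(switchJacobian(p6, s$state, src = 1e-6,
                                    relStep = 2e-6, absFloor = 2e-9),
                     only.values = TRUE)$values))
  expect_lt(abs(e1 - e2) / abs(e1), 0.01)
})

test_that("reported stability is consistent with the dynamics", {
  p6 <- applyOverrides(defaultParams(), c(V_SLET7 = 6))
  ss <- findSteadyStates(p6, src = 1e-6)
  stable <- Filter(function(s) s$stable, ss)
  unstable <- Filter(function(s) !s$stable, ss)
  for (s in stable) {
    tr <- simulateSwitch(applyOverrides(p6, c(Src = 1e-6)), s$state,
                         tEnd = 500, sampleEvery = 100)
    dev <- sqrt(sum((endState(tr) - s$state)^2)) /
      max(sqrt(sum(s$state^2)), 1e-8)
    expect_lt(dev, 1e-3)
  }
  ## the saddle departs under a small kick along its unstable eigenvector
  s <- unstable[[1]]
  J <- episwitch:::jacAnalytic(episwitch:::fullState(s$state), p6, 1e-6)
  act <- names(s$state)
  eg <- eigen(J[act, act])
  k <- which.max(Re(eg$values))
  kick <- Re(eg$vectors[, k]); kick <- kick / sqrt(sum(kick^2))
  y <- pmax(s$state + 1e-6 * kick, 0)
  tr <- simulateSwitch(applyOverrides(p6, c(Src = 1e-6)), y, tEnd = 2000,
                       sampleEvery = 400)
  dev <- sqrt(sum((endState(tr) - s$state)^2)) / sqrt(sum(s$state^2))
  expect_gt(dev, 0.5)
})

test_that("thresholds shift with the tumor-suppressor and oncogene rates", {
  thr <- function(ov, variant = NULL)
    switchThreshold(applyOverrides(defaultParams(), ov), variant = variant)
  a <- thr(c(V_SLET7 = 3)); b <- thr(c(V_SLET7 = 6))
  expect_identical(a$status, "bistable")
  expect_identical(b$status, "bistable")
  expect_lt(a$threshold, b$threshold)
  ## too little Let-7: the transformed state is the only attractor
  expect_identical(thr(c(V_SLET7 = 1))$status, "always_transformed")
  ## too much Ras likewise
  expect_identical(thr(c(V_SLET7 = 6, V_SMRAS = 0.03))$status,
                   "always_transformed")
})

test_that("bifurcation scans bracket the bistable window", {
  expect_length(scanBifurcation(defaultParams(), grid = numeric(0))@branches,
                0)
  p6 <- applyOverrides(defaultParams(), c(V_SLET7 = 6))
  grid <- 10^seq(-7, log10(2e-2), length.out = 25)
  bd <- scanBifurcation(p6, grid = grid)
  expect_false(anyNA(bd@bistable))
  nStable <- vapply(bd@branches, function(br)
    sum(vapply(br, function(b) b$stable, logical(1))), integer(1))
  inWin <- grid >= bd@bistable[1] & grid <= bd@bistable[2]
  expect_true(all(nStable[inWin] >= 2))
  expect_true(all(nStable[!inWin] == 1))
  ## the saddle is present inside the window
  nUnst <- vapply(bd@branches, function(br)
    sum(vapply(br, function(b) !b$stable, logical(1))), integer(1))
  expect_true(any(nUnst[inWin] >= 1))
  ## the detected window is consistent with the fold located by bisection
  th <- switchThreshold(p6)
  expect_gte(th$threshold, bd@bistable[2] / 2)
  ## high Ras: single transformed branch everywhere
  bd2 <- scanBifurcation(applyOverrides(p6, c(V_SMRAS = 0.03)),
                         grid = 10^seq(-7, log10(2e-2), length.out = 10))
  n2 <- vapply(bd2@branches, function(br)
    sum(vapply(br, function(b) b$stable, logical(1))), integer(1))
  expect_true(all(n2 == 1))
  expect_true(anyNA(bd2@bistable))
  expect_true(all(vapply(bd2@branches, function(br)
    br[[1]]$state[["NFKB"]] > 0.5, logical(1))))
})
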