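test_that("degenerate horizons and initial conditions are handled", {
  tr0 <- simulateSwitch(defaultParams(), icSetA(), srcConstant(0), tEnd = 0)
  expect_equal(length(trajTimes(tr0)), 1L)
  expect_equal(unname(trajStates(tr0)[1, ]),
               unname(icSetA()[stateNames(switchVariant())]))
  tr <- simulateSwitch(defaultParams(), icSetA(), srcConstant(0), tEnd = 1)
  expect_equal(unname(trajStates(tr)[1, ]),
               unname(icSetA()[stateNames(switchVariant())]))
  expect_true(all(diff(trajTimes(tr)) > 0))
})

test_that("without Src the resting cell stays non-transformed", {
  tr <- runScenario("fig2a")
  expect_true(is.na(detectSwitchTime(tr)))
  e <- endState(tr)
  expect_gt(e[["Let7"]], 10)
  expect_lt(e[["NFKB"]], 0.01)
  expect_lt(e[["Lin28"]], 0.5)
  expect_lt(e[["IL6"]], 0.1)
  expect_lt(e[["STAT3"]], 0.1)
})

test_that("switch times order as high constant < low constant < brief pulse", {
  td <- detectSwitchTime(runScenario("fig2d"))
  tb <- detectSwitchTime(runScenario("fig2b"))
  tc <- detectSwitchTime(runScenario("fig2c"))
  expect_false(anyNA(c(td, tb, tc)))
  expect_lt(td, tb)
  expect_lt(tb, tc)
  ## the 10 h / 36 h / 65 h pattern of the published dose panels
  expect_equal(td, 10, tolerance = 0.2)
  expect_equal(tb, 36, tolerance = 0.05)
  expect_equal(tc, 65, tolerance = 0.05)
})

test_that("switch-time detection handles degenerate trajectories", {
  t <- seq(0, 10, by = 0.1)
  ## constant trajectory already in the transformed state: switch at 0 h
  tr <- syntheticTraj(t, NFKB = rep(1, length(t)), STAT3 = rep(2, length(t)))
  expect_equal(detectSwitchTime(tr), 0)
  ## non-transformed endpoint: no switch
  tr2 <- syntheticTraj(t, NFKB = rep(0.01, length(t)),
                       STAT3 = seq(0, 2, length.out = length(t)))
  expect_true(is.na(detectSwitchTime(tr2)))
  ## truncation re-evaluates the endpoint
  tr3 <- syntheticTraj(t, NFKB = c(rep(0.9, 50), rep(0.01, 51)),
                       STAT3 = c(rep(2, 50), rep(0, 51)))
  expect_true(is.na(detectSwitchTime(tr3)))
  expect_equal(detectSwitchTime(tr3, tMax = 4), 0)
})

test_that("perturbation windows apply exactly inside their boundaries", {
  ## pure exponential decay of Lin28 with degradation switched off during
  ## [10, 20] h gives a closed-form endpoint
  p <- decayOnlyParams()
  init <- setNames(numeric(18), stateNames())
  init["Lin28"] <- 1
  w <- perturbationWindow(10, 20, c(k_DLIN28 = 0))
  tr <- simulateSwitch(p, init, srcConstant(0), tEnd = 30,
                       perturbations = list(w))
  expected <- exp(-p[["k_DLIN28"]] * 20 * 60)   # 30 h minus the 10 h freeze
  expect_equal(endState(tr)[["Lin28"]], expected, tolerance = 1e-6)
  ## without the window the decay runs the full 30 h
  tr2 <- simulateSwitch(p, init, srcConstant(0), tEnd = 30)
  expect_equal(endState(tr2)[["Lin28"]], exp(-p[["k_DLIN28"]] * 30 * 60),
               tolerance = 1e-6)
})

test_that("detected switch times are robust to solver tolerances", {
  t1 <- detectSwitchTime(runScenario("fig2b"))
  t2 <- detectSwitchTime(runScenario("fig2b", rtol = 5e-9, atol = 5e-11))
  expect_lt(abs(t1 - t2), 0.5)
})

test_that("a low PTEN1 mRNA dose delays the switch with biphasic IL6", {
  trB <- runScenario("figS9b")   # V_SMPTEN1 = 0.15
  trA <- runScenario("figS9a")   # V_SMPTEN1 = 0
  tA <- detectSwitchTime(trA); tB <- detectSwitchTime(trB)
  expect_false(anyNA(c(tA, tB)))
  expect_gt(tB, tA)
  ## early local IL6 maximum before the main rise
  il6 <- trajStates(trB)[, "IL6"]
  tt <- trajTimes(trB)
  pre <- which(tt < tB - 1)
  peaks <- which(diff(sign(diff(il6[pre]))) < 0) + 1
  expect_gt(length(peaks), 0)
  expect_lt(il6[pre][peaks[1]], max(il6))
})
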