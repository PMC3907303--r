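test_that("default parameter set carries the published values", {
  p <- defaultParams()
  expect_identical(names(p), paramNames())
  expect_equal(p[["V_SLET7"]], 3)
  expect_equal(p[["k_AA1NFKB"]], 10)
  expect_equal(p[["K_AIL6"]], 40)
  expect_equal(p[["NFKB_T"]], 1)
  expect_equal(p[["k_1"]], 10)
  expect_equal(p[["V_SLIN28"]], 0.012)
  expect_equal(p[["k_DLIN28"]], 0.002)
  ## PTEN transcription and both extension syntheses are off by default, so
  ## the 14-variable core model is recovered
  expect_equal(p[["V_SMPTEN"]], 0)
  expect_equal(p[["V_SCERNA"]], 0)
  expect_equal(p[["V_SMPTEN1"]], 0)
  expect_equal(p[["Src"]], 0)
})

test_that("parameter validation rejects malformed sets", {
  p <- defaultParams()
  expect_invisible(assertParams(p))
  expect_error(assertParams(unname(p)), "named")
  expect_error(assertParams(p[-1]), "missing")
  expect_error(assertParams(c(p, bogus = 1)), "unknown")
  p2 <- p; p2[["k_1"]] <- -1
  expect_error(assertParams(p2), "non-negative")
  p3 <- p; p3[["NFKB_T"]] <- 0
  expect_error(assertParams(p3), "NFKB_T")
  p4 <- p; p4[["K_ILET7"]] <- 0
  expect_error(assertParams(p4), "Michaelis")
})

test_that("overrides apply by name and typos suggest the nearest symbol", {
  p <- applyOverrides(defaultParams(), c(V_SLET7 = 6, Src = 1e-6))
  expect_equal(p[["V_SLET7"]], 6)
  expect_equal(p[["Src"]], 1e-6)
  expect_equal(p[["k_1"]], 10)
  expect_error(applyOverrides(defaultParams(), c(V_SLETT7 = 6)),
               "V_SLET7")
  expect_equal(applyOverrides(defaultParams(), NULL), defaultParams())
})
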