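## shared helpers for the suite

## parameter vector with every synthesis and binding process switched off,
## leaving pure first-order decay of each pool
decayOnlyParams <- function() {
  p <- defaultParams()
  p[grep("^V_S", names(p))] <- 0
  p[c("k_AA1NFKB", "k_AA2NFKB", "k_AA3NFKB")] <- 0
  p[c("k_1", "k_3", "k_5", "k_7", "k_9")] <- 0
  p[c("k_2", "k_4", "k_6", "k_8", "k_10")] <- 0
  p[c("k_SIL6", "k_SRAS", "k_SPTEN")] <- 0
  p
}

## random admissible full state (respects the NF-kB conservation bound)
randomState <- function(scale = 2) {
  y <- setNames(runif(18, 0, scale), stateNames())
  y["NFKB"] <- runif(1, 0, 1)
  y
}

## synthetic trajectory with prescribed NFKB / STAT3 columns
syntheticTraj <- function(times, NFKB, STAT3, params = defaultParams()) {
  states <- matrix(0, length(times), 14,
                   dimnames = list(NULL, stateNames(switchVariant())))
  states[, "NFKB"] <- NFKB
  states[, "STAT3"] <- STAT3
  new("SwitchTrajectory", times = times, states = states, params = params,
      src = srcConstant(0), variant = list(cerna = FALSE, pten1 = FALSE),
      perturbations = list())
}
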