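## Thin wrappers over the compiled stochastic simulator (src/ssa.cpp).

.ssaPropensities <- function(counts, params, omega)
  .Call("episwitch_ssa_propensities", as.numeric(counts), as.numeric(params),
        as.numeric(omega), PACKAGE = "episwitch")

.ssaRunC <- function(initCounts, params, omega, tEndMin, recordDtMin,
                     recordEvents, maxEvents)
  .Call("episwitch_ssa_run", as.numeric(initCounts), as.numeric(params),
        as.numeric(omega), as.numeric(tEndMin), as.numeric(recordDtMin),
        as.logical(recordEvents), as.numeric(maxEvents),
        PACKAGE = "episwitch")
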