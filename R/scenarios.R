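## Scenario library: each entry reproduces one published simulation condition.
## ic is "A" (resting start) or "B" (mid-level start); src is built lazily so
## the registry is a plain data structure.

.scenarioEnv <- new.env(parent = emptyenv())

.scenarioRegistry <- function() {
  if (!is.null(.scenarioEnv$reg)) return(.scenarioEnv$reg)
  win <- function(start, end, ...) perturbationWindow(start, end, c(...))
  reg <- list(
    ## Src dose panels: resting start, increasing stimulus
    fig2a = list(ic = "A", src = 0, tEnd = 100,
                 note = "no Src; stays non-transformed"),
    fig2b = list(ic = "A", src = 5e-5, tEnd = 100,
                 note = "constant low Src; switch near 36 h"),
    fig2c = list(ic = "A", srcPulse = TRUE, tEnd = 100,
                 note = "Src = 0.015 for 5 min; delayed switch near 65 h"),
    fig2d = list(ic = "A", src = 0.015, tEnd = 100,
                 note = "constant high Src; switch near 10 h"),
    ## transient-inhibition resets of the transformed state
    figS1a = list(ic = "A", srcPulse = TRUE, tEnd = 200,
                  perturbations = list(win(100, 130, k_AA1NFKB = 0,
                                           k_AA2NFKB = 0, k_AA3NFKB = 0)),
                  note = "NF-kB activation zeroed on 100-130 h"),
    figS1b = list(ic = "A", srcPulse = TRUE, tEnd = 200,
                  perturbations = list(win(100, 130, V_SLIN28 = 0)),
                  note = "Lin28 synthesis zeroed on 100-130 h"),
    figS1c = list(ic = "A", srcPulse = TRUE, tEnd = 200,
                  perturbations = list(win(100, 130, V_S1MIL6 = 0,
                                           V_S2MIL6 = 0)),
                  note = "IL6 mRNA synthesis zeroed on 100-130 h"),
    ## deterministic baselines of the stochastic comparison
    fig5a = list(ic = "B", src = 1e-6, overrides = c(V_SLET7 = 3.5),
                 tEnd = 100, note = "mid-level start; switch near 20 h"),
    fig5b = list(ic = "B", src = 1e-5, overrides = c(V_SLET7 = 4),
                 tEnd = 100, note = "mid-level start; stays non-transformed"),
    ## miR-21 overexpression with and without Lin28 inhibition
    fig9a = list(ic = "A", src = 1e-5,
                 overrides = c(V_SLET7 = 3, V_SMPTEN = 0.1), tEnd = 400,
                 perturbations = list(win(100, Inf, V_SMIR21 = 4000)),
                 note = "miR-21 overexpression from 100 h triggers the switch"),
    fig9b = list(ic = "A", src = 1e-5,
                 overrides = c(V_SLET7 = 3, V_SMPTEN = 0.1), tEnd = 400,
                 perturbations = list(win(100, Inf, V_SMIR21 = 4000,
                                          V_SLIN28 = 0.008)),
                 note = "same overexpression with Lin28 inhibited; no switch"))
  ## PTEN1 mRNA dose series (miR-21 sponge active)
  s9base <- c(V_SLET7 = 1.15, V_SMIR21 = 10, K_IPTEN = 0.1, V_SMPTEN = 3,
              k_SPTEN = 0.3)
  s9 <- c(figS9a = 0, figS9b = 0.15, figS9c = 0.2, figS9d = 0.5)
  for (nm in names(s9))
    reg[[nm]] <- list(ic = "B", src = 0,
                      overrides = c(s9base, V_SMPTEN1 = s9[[nm]]),
                      variant = list(pten1 = TRUE), tEnd = 100,
                      note = sprintf("PTEN1 mRNA synthesis %g", s9[[nm]]))
  .scenarioEnv$reg <- reg
  reg
}

#' Names of the registered scenarios
#'
#' @return Character vector of scenario identifiers understood by
#'   [runScenario()].
#' @export
scenarioNames <- function() names(.scenarioRegistry())

#' Run a registered scenario
#'
#' Executes one of the library conditions (see [scenarioNames()]): the Src
#' dose panels from the resting start, the transient-inhibition resets of the
#' transformed state, the mid-level-start baselines, the miR-21
#' overexpression experiments, and the PTEN1 mRNA dose series.
#'
#' @param name Scenario identifier.
#' @param overrides Optional extra parameter overrides applied on top of the
#'   scenario's own.
#' @param tEnd Optional replacement horizon, hours.
#' @param ... Passed to [simulateSwitch()] (e.g. solver tolerances).
#' @return A [SwitchTrajectory-class].
#' @examples
#' \donttest{
#' traj <- runScenario("fig2b")
#' detectSwitchTime(traj)
#' }
#' @export
runScenario <- function(name, overrides = NULL, tEnd = NULL, ...) {
  if (!name %in% names(.scenarioRegistry()))
    stop("unknown scenario '", name, "'; see scenarioNames()")
  sc <- .scenarioRegistry()[[name]]
  variant <- asVariant(sc$variant)
  params <- applyOverrides(defaultParams(), sc$overrides)
  params <- applyOverrides(params, overrides)
  src <- if (isTRUE(sc$srcPulse)) srcPulse() else srcConstant(sc$src)
  init <- if (sc$ic == "A") icSetA(variant) else icSetB(variant)
  simulateSwitch(params, init, src, tEnd = if (is.null(tEnd)) sc$tEnd else tEnd,
                 perturbations = if (is.null(sc$perturbations)) list()
                                 else sc$perturbations,
                 variant = variant, ...)
}
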