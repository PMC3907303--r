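## Configuration loading and the figure-reproduction runner.  A run
## configuration is a flat key = value mapping: model parameters under their
## canonical symbols plus a small set of reserved run settings.

.reservedKeys <- c(ic = "B", t_end_h = 100, seed = 1, omega = 100,
                   cerna = 0, pten1 = 0, n_cells = 100, variation = 0.1,
                   transient_h = 50)

#' Load a run configuration
#'
#' Builds a fully resolved run configuration from (in increasing precedence)
#' the package defaults, a flat JSON/YAML config file, and direct overrides.
#' Keys are either model-parameter symbols (see [paramNames()]) or the
#' reserved run settings `ic` (`"A"`/`"B"`), `t_end_h`, `seed`, `omega`,
#' `cerna`, `pten1`, `n_cells`, `variation`, `transient_h`.  Unknown keys are
#' rejected with the nearest valid symbol suggested, so typos against the
#' published parameter table cannot silently fall back to defaults.
#'
#' @param path Optional path to a flat JSON or YAML file.
#' @param overrides Optional named list/vector applied after the file.
#' @return A list with elements `params` (full parameter vector), `variant`,
#'   `ic`, `tEnd`, `seed`, `omega`, `nCells`, `variation`, `transientH`.
#' @examples
#' cfg <- loadConfig(overrides = c(V_SLET7 = 6, Src = 1e-6))
#' cfg$params[["V_SLET7"]]
#' @export
loadConfig <- function(path = NULL, overrides = NULL) {
  vals <- list()
  if (!is.null(path)) {
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(names(raw)) || any(!nzchar(names(raw))))
      stop("config file must be a flat key = value mapping")
    vals <- as.list(raw)
  }
  if (!is.null(overrides) && length(overrides)) {
    overrides <- as.list(overrides)
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("'overrides' must be named")
    vals[names(overrides)] <- overrides
  }

  valid <- c(paramNames(), names(.reservedKeys))
  bad <- setdiff(names(vals), valid)
  if (length(bad)) {
    near <- vapply(bad, function(x)
      valid[which.min(adist(x, valid, ignore.case = TRUE))], character(1))
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", bad, near),
               collapse = ", "))
  }

  settings <- as.list(.reservedKeys)
  settings$ic <- "B"
  for (k in names(.reservedKeys))
    if (k %in% names(vals)) settings[[k]] <- vals[[k]]
  pk <- intersect(names(vals), paramNames())
  numPar <- vapply(vals[pk], function(v) {
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v)) stop("non-numeric parameter value in config")
    v
  }, numeric(1))
  params <- applyOverrides(defaultParams(), numPar)
  if (!settings$ic %in% c("A", "B"))
    stop("'ic' must be \"A\" or \"B\"")

  list(params = params,
       variant = switchVariant(cerna = as.logical(as.numeric(settings$cerna)),
                               pten1 = as.logical(as.numeric(settings$pten1))),
       ic = settings$ic,
       tEnd = as.numeric(settings$t_end_h),
       seed = as.integer(settings$seed),
       omega = as.numeric(settings$omega),
       nCells = as.integer(settings$n_cells),
       variation = as.numeric(settings$variation),
       transientH = as.numeric(settings$transient_h))
}

#' Serialize a run configuration
#'
#' Writes the non-default entries of a resolved configuration back to a flat
#' JSON mapping; `loadConfig(path)` on the result reproduces the
#' configuration (round trip).
#'
#' @param config A configuration as returned by [loadConfig()].
#' @param path Output path (`.json`).
#' @return Invisibly, the flat list written.
#' @export
writeConfig <- function(config, path) {
  flat <- as.list(config$params)
  flat$ic <- config$ic
  flat$t_end_h <- config$tEnd
  flat$seed <- config$seed
  flat$omega <- config$omega
  flat$cerna <- as.numeric(config$variant$cerna)
  flat$pten1 <- as.numeric(config$variant$pten1)
  flat$n_cells <- config$nCells
  flat$variation <- config$variation
  flat$transient_h <- config$transientH
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(flat)
}

#' Reproduce a published in-silico experiment
#'
#' Executes the registered pipeline behind one figure of the study the model
#' comes from and returns a run record with the headline numbers.
#' Deterministic panels run [runScenario()]; bifurcation figures sweep
#' [switchThreshold()] across the stated synthesis rates; stochastic figures
#' run [ensembleProportion()] ensembles; population figures run
#' [runPopulation()].
#'
#' @param id Figure identifier; see `names(reproduceRegistry())`.
#' @param seed Seed for the stochastic/population pipelines.
#' @param nCells Cells per ensemble or population.
#' @return A list (run record) with `id`, `kind`, headline numbers, and the
#'   underlying result objects.
#' @export
reproduce <- function(id, seed = 1, nCells = NULL) {
  reg <- reproduceRegistry()
  if (!id %in% names(reg))
    stop("unknown figure id '", id, "'; see names(reproduceRegistry())")
  reg[[id]](seed = seed, nCells = nCells)
}

#' Registry of figure-reproduction pipelines
#'
#' @return Named list of pipeline functions taking `(seed, nCells)`.
#' @export
reproduceRegistry <- function() {
  det <- function(scen) {
    force(scen)
    function(seed = 1, nCells = NULL) {
    traj <- runScenario(scen)
    list(id = scen, kind = "deterministic",
         switchTime = detectSwitchTime(traj),
         transformed = isTransformed(traj, traj@params), trajectory = traj)
    }
  }
  thresholds <- function(id, symbol, values, base = c()) {
    function(seed = 1, nCells = NULL) {
      variant <- switchVariant(cerna = symbol == "V_SCERNA" ||
                                 "V_SCERNA" %in% names(base))
      th <- vapply(values, function(v) {
        pp <- applyOverrides(defaultParams(), c(base, setNames(v, symbol)))
        switchThreshold(pp, variant)$threshold
      }, numeric(1))
      list(id = id, kind = "thresholds", parameter = symbol, values = values,
           thresholds = th)
    }
  }
  ensembles <- function(id, symbol, values, base = c(), cerna = FALSE) {
    function(seed = 1, nCells = NULL) {
      if (is.null(nCells)) nCells <- 50
      variant <- switchVariant(cerna = cerna)
      fr <- vapply(values, function(v) {
        pp <- applyOverrides(defaultParams(), c(base, setNames(v, symbol)))
        ensembleProportion(pp, omega = 100, nCells = nCells, transientH = 50,
                           variant = variant, seed = seed)@proportion
      }, numeric(1))
      list(id = id, kind = "ensembles", parameter = symbol, values = values,
           proportionTransformed = fr)
    }
  }
  popn <- function(id, over, p = 0.1, corVars = c("Let7", "IL6")) {
    function(seed = 1, nCells = NULL) {
      if (is.null(nCells)) nCells <- 100
      pp <- applyOverrides(defaultParams(), over)
      pr <- runPopulation(pp, p = p, nCells = nCells, seed = seed)
      list(id = id, kind = "population",
           fractionTransformed = fractionTransformed(pr),
           correlation = endpointCorrelation(pr, corVars[1], corVars[2]),
           result = pr)
    }
  }

  reg <- list()
  for (s in scenarioNames()) reg[[s]] <- det(s)
  reg$fig3 <- thresholds("fig3", "V_SLET7", c(3, 4, 6))
  reg$fig4 <- thresholds("fig4", "V_SMRAS", c(0, 0.005, 0.02, 0.027),
                         base = c(V_SLET7 = 6))
  reg$figS2 <- thresholds("figS2", "V_SMPTEN", c(0.01, 0.1, 0.5),
                          base = c(V_SLET7 = 6, V_SMRAS = 0.03))
  reg$figS7 <- thresholds("figS7", "V_SCERNA", c(0, 0.5, 1),
                          base = c(V_SLET7 = 6))
  reg$fig6 <- ensembles("fig6", "V_SLET7", c(3, 3.5, 4), base = c(Src = 1e-6))
  reg$fig7 <- ensembles("fig7", "V_SMRAS", c(0.005, 0.02, 0.027),
                        base = c(V_SLET7 = 6, Src = 1e-6))
  reg$figS3 <- ensembles("figS3", "V_SMPTEN", c(0.01, 0.05),
                         base = c(V_SLET7 = 3.5, Src = 1e-6))
  reg$figS8 <- ensembles("figS8", "V_SCERNA", c(0, 0.1, 0.15),
                         base = c(V_SLET7 = 6, Src = 1e-6), cerna = TRUE)
  fig8base <- c(V_SLET7 = 6, Src = 1e-6)
  reg$fig8a <- popn("fig8a", fig8base)
  reg$fig8b <- popn("fig8b", c(fig8base, V_SMRAS = 0.02))
  reg$fig8c <- popn("fig8c", c(fig8base, V_SMRAS = 0.05))
  reg$fig8d <- popn("fig8d", c(V_SLET7 = 3, Src = 1e-6))
  reg$fig8e <- popn("fig8e", c(fig8base, V_SLIN28 = 0.024))
  reg$fig8f <- popn("fig8f", c(fig8base, V_SMRAS = 0.05, V_SMPTEN = 0.5))
  s6base <- c(V_SLET7 = 3, V_SMPTEN = 0.1, Src = 1e-5)
  reg$figS6ab <- popn("figS6ab", c(s6base, V_SMIR21 = 4),
                      corVars = c("miR21", "STAT3"))
  reg$figS6cd <- popn("figS6cd", c(s6base, V_SMIR21 = 4000),
                      corVars = c("miR21", "STAT3"))
  reg$figS6ef <- popn("figS6ef", c(s6base, V_SMIR21 = 4000, V_SLIN28 = 0.008),
                      corVars = c("miR21", "PTEN"))
  cez <- function(v) function(seed = 1, nCells = NULL) {
    if (is.null(nCells)) nCells <- 100
    pp <- applyOverrides(defaultParams(),
                         c(V_SLET7 = 6, Src = 1e-6, V_SCERNA = v))
    pr <- runPopulation(pp, p = 0.1, nCells = nCells,
                        variant = switchVariant(cerna = TRUE), seed = seed)
    list(id = sprintf("fig11 V_SCERNA=%g", v), kind = "population",
         fractionTransformed = fractionTransformed(pr),
         correlation = endpointCorrelation(pr, "Let7", "IL6"), result = pr)
  }
  reg$fig11a <- cez(0); reg$fig11b <- cez(0.1); reg$fig11c <- cez(0.2)
  figS4 <- function(seed = 1, nCells = NULL) {
    if (is.null(nCells)) nCells <- 100
    ps <- c(0.05, 0.1, 0.25, 0.5)
    fr <- sapply(ps, function(pv) {
      c(normal = fractionTransformed(runPopulation(
          applyOverrides(defaultParams(), c(V_SLET7 = 6, Src = 1e-6)),
          p = pv, nCells = nCells, seed = seed)),
        ras = fractionTransformed(runPopulation(
          applyOverrides(defaultParams(),
                         c(V_SLET7 = 6, Src = 1e-6, V_SMRAS = 0.05)),
          p = pv, nCells = nCells, seed = seed)))
    })
    colnames(fr) <- paste0("p", ps)
    list(id = "figS4", kind = "population", fractions = fr)
  }
  reg$figS4 <- figS4
  figS5 <- function(seed = 1, nCells = NULL) {
    if (is.null(nCells)) nCells <- 100
    srcs <- c(1e-5, 1e-4, 1e-3)
    fr <- vapply(srcs, function(sv) fractionTransformed(runPopulation(
      applyOverrides(defaultParams(), c(V_SLET7 = 6, Src = sv)),
      p = 0.25, nCells = nCells, seed = seed)), numeric(1))
    list(id = "figS5", kind = "population", src = srcs,
         fractionResponding = fr)
  }
  reg$figS5 <- figS5
  reg
}
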