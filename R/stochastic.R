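#' Stochastic (Gillespie) trajectory
#'
#' S4 container for one exact stochastic realization: integer copy-number
#' snapshots on a regular grid, the system size, and optionally the full
#' event sequence.
#'
#' @slot times Snapshot times, hours.
#' @slot counts Copy-number matrix (rows = times, columns = species).
#' @slot omega System size (molecules per micromolar).
#' @slot params Parameter vector used.
#' @slot nEvents Number of reaction events fired.
#' @slot events `data.frame` with `time_h` and `channel` when event recording
#'   was requested, otherwise empty.
#' @name StochasticTrajectory-class
#' @aliases StochasticTrajectory
#' @exportClass StochasticTrajectory
setClass("StochasticTrajectory",
  representation(times = "numeric", counts = "matrix", omega = "numeric",
                 params = "numeric", nEvents = "numeric",
                 events = "data.frame"))

setMethod("show", "StochasticTrajectory", function(object) {
  n <- length(object@times)
  cat(sprintf(
    "<StochasticTrajectory> omega = %g, %d snapshots over [%g, %g] h, %.0f events\n",
    object@omega, n, object@times[1], object@times[n], object@nEvents))
})

#' @export
as.data.frame.StochasticTrajectory <- function(x, ...) {
  data.frame(time_h = x@times, x@counts, check.names = FALSE)
}

#' Reaction channels of the stochastic model
#'
#' Reference description of the stochastic version of the model: one channel
#' per elementary process, each with a name, an integer stoichiometry vector
#' and a propensity function of the copy-number state.  Unimolecular rate
#' constants carry over unchanged, bimolecular constants are scaled by
#' `1/omega`, zero-order syntheses by `omega`, and the saturating
#' (Michaelian and Goldbeter-Koshland) processes are lumped channels whose
#' propensity is `omega` times the deterministic rate law evaluated at
#' `count/omega`.  This R version documents and cross-checks the compiled
#' simulator used by [ssaRun()].
#'
#' @param params Parameter vector.
#' @param variant [switchVariant()] flags; extension channels are included
#'   only when the corresponding species are active.
#' @param omega System size (molecules per micromolar).
#' @return List of channels, each a list with `name`, `stoich` (named
#'   integer vector over the full species order) and `propensity`
#'   (a function of the named counts vector).
#' @examples
#' ch <- buildReactions(defaultParams(), omega = 100)
#' length(ch)
#' @export
buildReactions <- function(params, variant = NULL, omega = 100) {
  p <- assertParams(params)
  variant <- asVariant(variant)
  W <- omega
  sv <- function(...) {
    v <- setNames(integer(18), .stateOrder)
    ch <- c(...)
    v[names(ch)] <- ch
    v
  }
  mm <- function(x, K) x / (K + x)
  chan <- list(
    list(name = "NFKB activation", stoich = sv(NFKB = 1L),
         propensity = function(n) {
           pool <- p[["NFKB_T"]] - n[["NFKB"]] / W
           if (pool <= 0) return(0)
           drive <- (p[["k_AA1NFKB"]] * p[["Src"]] +
                       p[["k_AA2NFKB"]] * n[["IL6"]] / W +
                       p[["k_AA3NFKB"]] * n[["Ras"]] / W) *
             p[["K_IPTEN"]] / (p[["K_IPTEN"]] + n[["PTEN"]] / W)
           W * drive * mm(pool, p[["K_ANFKB"]])
         }),
    list(name = "NFKB inactivation", stoich = sv(NFKB = -1L),
         propensity = function(n)
           W * p[["V_DNFKB"]] * mm(n[["NFKB"]] / W, p[["K_INFKB"]])),
    list(name = "Lin28 synthesis", stoich = sv(Lin28 = 1L),
         propensity = function(n)
           W * p[["V_SLIN28"]] * mm(n[["NFKB"]] / W, p[["K_A1NF"]])),
    list(name = "Lin28 degradation", stoich = sv(Lin28 = -1L),
         propensity = function(n) p[["k_DLIN28"]] * n[["Lin28"]]),
    list(name = "Let7 synthesis", stoich = sv(Let7 = 1L),
         propensity = function(n)
           W * p[["V_SLET7"]] * p[["K_ILET7"]] /
             (p[["K_ILET7"]] + n[["Lin28"]] / W)),
    list(name = "Let7 degradation", stoich = sv(Let7 = -1L),
         propensity = function(n) p[["k_DLET7"]] * n[["Let7"]]),
    list(name = "Let7+mIL6 binding",
         stoich = sv(Let7 = -1L, mIL6 = -1L, mIL6Let7 = 1L),
         propensity = function(n)
           p[["k_1"]] / W * n[["Let7"]] * n[["mIL6"]]),
    list(name = "mIL6Let7 dissociation",
         stoich = sv(Let7 = 1L, mIL6 = 1L, mIL6Let7 = -1L),
         propensity = function(n) p[["k_2"]] * n[["mIL6Let7"]]),
    list(name = "mIL6 basal synthesis", stoich = sv(mIL6 = 1L),
         propensity = function(n) W * p[["V_S1MIL6"]]),
    list(name = "mIL6 NFKB-dependent synthesis", stoich = sv(mIL6 = 1L),
         propensity = function(n)
           W * p[["V_S2MIL6"]] * mm(n[["NFKB"]] / W, p[["K_A2NF"]])),
    list(name = "mIL6 degradation", stoich = sv(mIL6 = -1L),
         propensity = function(n) p[["k_DMIL6"]] * n[["mIL6"]]),
    list(name = "mIL6Let7 degradation", stoich = sv(mIL6Let7 = -1L),
         propensity = function(n) p[["k_DILLET"]] * n[["mIL6Let7"]]),
    list(name = "IL6 synthesis", stoich = sv(IL6 = 1L),
         propensity = function(n) p[["k_SIL6"]] * n[["mIL6"]]),
    list(name = "IL6 degradation", stoich = sv(IL6 = -1L),
         propensity = function(n) p[["k_DIL6"]] * n[["IL6"]]),
    list(name = "mRas synthesis", stoich = sv(mRas = 1L),
         propensity = function(n) W * p[["V_SMRAS"]]),
    list(name = "Let7+mRas binding",
         stoich = sv(Let7 = -1L, mRas = -1L, mRasLet7 = 1L),
         propensity = function(n)
           p[["k_3"]] / W * n[["Let7"]] * n[["mRas"]]),
    list(name = "mRasLet7 dissociation",
         stoich = sv(Let7 = 1L, mRas = 1L, mRasLet7 = -1L),
         propensity = function(n) p[["k_4"]] * n[["mRasLet7"]]),
    list(name = "mRas degradation", stoich = sv(mRas = -1L),
         propensity = function(n) p[["k_DMRAS"]] * n[["mRas"]]),
    list(name = "mRasLet7 degradation", stoich = sv(mRasLet7 = -1L),
         propensity = function(n) p[["k_DRASLET"]] * n[["mRasLet7"]]),
    list(name = "Ras synthesis", stoich = sv(Ras = 1L),
         propensity = function(n) p[["k_SRAS"]] * n[["mRas"]]),
    list(name = "Ras degradation", stoich = sv(Ras = -1L),
         propensity = function(n) p[["k_DRAS"]] * n[["Ras"]]),
    list(name = "STAT3 synthesis", stoich = sv(STAT3 = 1L),
         propensity = function(n)
           W * p[["V_SSTAT"]] * mm(n[["IL6"]] / W, p[["K_AIL6"]])),
    list(name = "STAT3 degradation", stoich = sv(STAT3 = -1L),
         propensity = function(n) p[["k_DSTAT"]] * n[["STAT3"]]),
    list(name = "miR21 synthesis", stoich = sv(miR21 = 1L),
         propensity = function(n)
           W * p[["V_SMIR21"]] * mm(n[["STAT3"]] / W, p[["K_ASTAT"]])),
    list(name = "miR21 degradation", stoich = sv(miR21 = -1L),
         propensity = function(n) p[["k_DMIR21"]] * n[["miR21"]]),
    list(name = "miR21+mPTEN binding",
         stoich = sv(miR21 = -1L, mPTEN = -1L, miRmpten = 1L),
         propensity = function(n)
           p[["k_5"]] / W * n[["miR21"]] * n[["mPTEN"]]),
    list(name = "miRmpten dissociation",
         stoich = sv(miR21 = 1L, mPTEN = 1L, miRmpten = -1L),
         propensity = function(n) p[["k_6"]] * n[["miRmpten"]]),
    list(name = "mPTEN synthesis", stoich = sv(mPTEN = 1L),
         propensity = function(n) W * p[["V_SMPTEN"]]),
    list(name = "mPTEN degradation", stoich = sv(mPTEN = -1L),
         propensity = function(n) p[["k_DMPTEN"]] * n[["mPTEN"]]),
    list(name = "miRmpten degradation", stoich = sv(miRmpten = -1L),
         propensity = function(n) p[["k_DMIRMP"]] * n[["miRmpten"]]),
    list(name = "PTEN synthesis", stoich = sv(PTEN = 1L),
         propensity = function(n) p[["k_SPTEN"]] * n[["mPTEN"]]),
    list(name = "PTEN degradation", stoich = sv(PTEN = -1L),
         propensity = function(n) p[["k_DPTEN"]] * n[["PTEN"]]))
  if (variant$cerna) chan <- c(chan, list(
    list(name = "ceRNA synthesis", stoich = sv(ceRNA = 1L),
         propensity = function(n) W * p[["V_SCERNA"]]),
    list(name = "Let7+ceRNA binding",
         stoich = sv(Let7 = -1L, ceRNA = -1L, ceRNAlet7 = 1L),
         propensity = function(n)
           p[["k_7"]] / W * n[["Let7"]] * n[["ceRNA"]]),
    list(name = "ceRNAlet7 dissociation",
         stoich = sv(Let7 = 1L, ceRNA = 1L, ceRNAlet7 = -1L),
         propensity = function(n) p[["k_8"]] * n[["ceRNAlet7"]]),
    list(name = "ceRNA degradation", stoich = sv(ceRNA = -1L),
         propensity = function(n) p[["k_DCERNA"]] * n[["ceRNA"]]),
    list(name = "ceRNAlet7 degradation", stoich = sv(ceRNAlet7 = -1L),
         propensity = function(n) p[["k_DCELET7"]] * n[["ceRNAlet7"]])))
  if (variant$pten1) chan <- c(chan, list(
    list(name = "mPTEN1 synthesis", stoich = sv(mPTEN1 = 1L),
         propensity = function(n) W * p[["V_SMPTEN1"]]),
    list(name = "miR21+mPTEN1 binding",
         stoich = sv(miR21 = -1L, mPTEN1 = -1L, miRmpten1 = 1L),
         propensity = function(n)
           p[["k_9"]] / W * n[["miR21"]] * n[["mPTEN1"]]),
    list(name = "miRmpten1 dissociation",
         stoich = sv(miR21 = 1L, mPTEN1 = 1L, miRmpten1 = -1L),
         propensity = function(n) p[["k_10"]] * n[["miRmpten1"]]),
    list(name = "mPTEN1 degradation", stoich = sv(mPTEN1 = -1L),
         propensity = function(n) p[["k_DMPTEN1"]] * n[["mPTEN1"]]),
    list(name = "miRmpten1 degradation", stoich = sv(miRmpten1 = -1L),
         propensity = function(n) p[["k_DMIRMP1"]] * n[["miRmpten1"]])))
  chan
}

#' Run one exact stochastic realization
#'
#' Direct-method Gillespie simulation of the model at system size `omega`.
#' Default initial counts are `round(omega * icSetB())`, the like-for-like
#' counterpart of the deterministic mid-level start.  Randomness comes from
#' R's RNG, so `set.seed()` (or the `seed` argument) makes the event sequence
#' bit-reproducible.
#'
#' @param params Parameter vector; its `Src` entry is the (constant)
#'   inflammatory input.
#' @param init Named initial concentration vector (micromolar), converted to
#'   counts by rounding `init * omega`; `NULL` uses [icSetB()].
#' @param omega System size, molecules per micromolar.
#' @param tEnd Horizon, hours.
#' @param seed Optional integer seed applied before the run.
#' @param variant [switchVariant()] flags.
#' @param recordEvery Snapshot interval, hours.
#' @param recordEvents Also keep the full event list (time + channel index,
#'   1-based in the [buildReactions()] order over all 42 channels).
#' @param maxEvents Safety cap on the number of reaction events.
#' @return A [StochasticTrajectory-class].
#' @examples
#' \donttest{
#' tr <- ssaRun(applyOverrides(defaultParams(),
#'                             c(Src = 1e-6, V_SLET7 = 3.5)),
#'              omega = 100, tEnd = 10, seed = 1)
#' }
#' @export
ssaRun <- function(params, init = NULL, omega = 100, tEnd = 100, seed = NULL,
                   variant = NULL, recordEvery = 0.1, recordEvents = FALSE,
                   maxEvents = 5e8) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  if (is.null(init)) init <- icSetB(variant)
  bad <- validateState(init, params, variant)
  if (length(bad)) stop("invalid initial condition: ",
                        paste(bad, collapse = "; "))
  if (!is.null(seed)) set.seed(seed)
  counts0 <- round(fullState(init) * omega)
  res <- .ssaRunC(unname(counts0), unname(params), omega, tEnd * 60,
                  recordEvery * 60, recordEvents, maxEvents)
  cm <- res$counts
  colnames(cm) <- .stateOrder
  ev <- if (recordEvents)
    data.frame(time_h = res$eventTimesMin / 60, channel = res$eventChannel)
  else data.frame(time_h = numeric(0), channel = integer(0))
  new("StochasticTrajectory", times = res$timesMin / 60, counts = cm,
      omega = omega, params = params, nEvents = res$nEvents, events = ev)
}

#' Ensemble summary of stochastic cells
#'
#' @slot nCells Number of realizations.
#' @slot transformed Logical vector of per-cell endpoint classifications.
#' @slot proportion Fraction of transformed cells.
#' @slot omega System size.
#' @slot seed Master seed.
#' @name EnsembleSummary-class
#' @aliases EnsembleSummary
#' @exportClass EnsembleSummary
setClass("EnsembleSummary",
  representation(nCells = "numeric", transformed = "logical",
                 proportion = "numeric", omega = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@proportion < 0 || object@proportion > 1)
      return("proportion must lie in [0, 1]")
    TRUE
  })

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf(
    "<EnsembleSummary> %d cells at omega = %g: %.0f%% transformed\n",
    object@nCells, object@omega, 100 * object@proportion))
})

#' Fraction of stochastically transformed cells
#'
#' Runs `nCells` independent stochastic realizations from the mid-level
#' start (each on its own seed derived from `seed` by a fixed offset),
#' classifies every endpoint after `transientH` hours by the NF-kB midpoint
#' rule in copy numbers (`count > omega * NFKB_T / 2`), and returns the
#' transformed fraction.
#'
#' @param params Parameter vector (its `Src` entry is the input level).
#' @param omega System size.
#' @param nCells Number of cells.
#' @param transientH Transient time before classification, hours.
#' @param variant [switchVariant()] flags.
#' @param seed Master seed; cell `i` runs on `seed + i`.
#' @param init Optional initial concentration vector (default [icSetB()]).
#' @return An [EnsembleSummary-class].
#' @export
ensembleProportion <- function(params, omega = 100, nCells = 50,
                               transientH = 50, variant = NULL, seed = 1,
                               init = NULL) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  stopifnot(nCells >= 1)
  if (is.null(init)) init <- icSetB(variant)
  half <- omega * params[["NFKB_T"]] / 2
  transformed <- logical(nCells)
  for (i in seq_len(nCells)) {
    tr <- ssaRun(params, init = init, omega = omega, tEnd = transientH,
                 seed = seed + i, variant = variant,
                 recordEvery = transientH)
    transformed[i] <- tr@counts[nrow(tr@counts), "NFKB"] > half
  }
  new("EnsembleSummary", nCells = nCells, transformed = transformed,
      proportion = mean(transformed), omega = omega, seed = seed)
}
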