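#' Heterogeneous cell-population result
#'
#' S4 container for a deterministic population run: the per-cell sampled
#' parameters, the per-cell endpoint states after the transient, and the
#' endpoint classification.
#'
#' @slot cellParams Matrix (cells x parameters) of sampled parameter sets.
#' @slot endpoints Matrix (cells x species) of endpoint concentrations; rows
#'   of failed integrations are `NA` and excluded from summaries.
#' @slot transformed Logical per-cell classification (NF-kB midpoint rule).
#' @slot variation Variation fraction used for the jitter.
#' @slot transientH Transient time, hours.
#' @slot seed Seed of the sampler.
#' @name PopulationResult-class
#' @aliases PopulationResult
#' @exportClass PopulationResult
setClass("PopulationResult",
  representation(cellParams = "matrix", endpoints = "matrix",
                 transformed = "logical", variation = "numeric",
                 transientH = "numeric", seed = "numeric"))

setMethod("show", "PopulationResult", function(object) {
  ok <- !is.na(object@transformed)
  cat(sprintf(
    "<PopulationResult> %d cells (%.0f%% parameter variation): %.0f%% transformed after %g h\n",
    nrow(object@endpoints), 100 * object@variation,
    100 * mean(object@transformed[ok]), object@transientH))
  if (any(!ok)) cat(sprintf("  %d cells failed to integrate and were excluded\n",
                            sum(!ok)))
})

#' @describeIn PopulationResult-class Fraction of transformed cells (failed
#'   cells excluded).
#' @param result A `PopulationResult`.
#' @export
fractionTransformed <- function(result) {
  mean(result@transformed[!is.na(result@transformed)])
}

#' Sample cell-to-cell parameter variability
#'
#' Draws one parameter set per cell with each entry independently uniform on
#' `[theta * (1 - p), theta * (1 + p)]` around its base value `theta`.  The
#' inflammatory input `Src` is a parameter like any other and is jittered
#' too.  A uniform (not Gaussian) law respects the stated percentage bound
#' exactly and cannot produce negative rates for `p < 1`.
#'
#' @param params Base parameter vector.
#' @param p Variation fraction (e.g. `0.1` for 10 percent).
#' @param nCells Number of cells.
#' @param seed Integer seed.
#' @return Matrix with one row per cell and one column per parameter.
#' @examples
#' th <- samplePopulationParams(defaultParams(), p = 0.1, nCells = 5, seed = 1)
#' range(th[, "V_SLET7"]) # within [2.7, 3.3]
#' @export
samplePopulationParams <- function(params, p = 0.1, nCells = 100, seed = 1) {
  params <- assertParams(params)
  stopifnot(p >= 0, p < 1, nCells >= 1)
  set.seed(seed)
  u <- matrix(runif(nCells * length(params), 1 - p, 1 + p), nrow = nCells)
  m <- sweep(u, 2, params, `*`)
  colnames(m) <- names(params)
  m
}

#' Simulate a heterogeneous cell population
#'
#' Integrates `nCells` deterministic cells, each with its own jittered
#' parameter set (see [samplePopulationParams()]), from a common initial
#' condition to the end of the transient, then classifies every endpoint by
#' the NF-kB midpoint rule.  Cells whose integration fails are recorded as
#' `NA` and excluded from summaries.
#'
#' @param params Base parameter vector (set its `Src` entry to the input
#'   level of the experiment).
#' @param p Variation fraction.
#' @param nCells Number of cells.
#' @param ic `"A"`, `"B"`, or a named initial concentration vector.
#' @param transientH Transient time before the endpoint is read, hours.
#' @param variant [switchVariant()] flags.
#' @param seed Integer seed for the parameter sampler.
#' @return A [PopulationResult-class].
#' @examples
#' \donttest{
#' pr <- runPopulation(applyOverrides(defaultParams(),
#'                                    c(V_SLET7 = 6, Src = 1e-6)),
#'                     nCells = 20, seed = 1)
#' fractionTransformed(pr)
#' endpointCorrelation(pr, "Let7", "IL6")
#' }
#' @export
runPopulation <- function(params = defaultParams(), p = 0.1, nCells = 100,
                          ic = "B", transientH = 50, variant = NULL,
                          seed = 1) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  active <- stateNames(variant)
  init <- if (is.character(ic)) {
    if (ic == "A") icSetA(variant) else icSetB(variant)
  } else ic
  theta <- samplePopulationParams(params, p, nCells, seed)
  endpoints <- matrix(NA_real_, nCells, length(active),
                      dimnames = list(NULL, active))
  transformed <- rep(NA, nCells)
  for (i in seq_len(nCells)) {
    res <- tryCatch({
      traj <- simulateSwitch(setNames(theta[i, ], colnames(theta)), init,
                             tEnd = transientH, variant = variant,
                             sampleEvery = transientH)
      endState(traj)
    }, error = function(e) {
      message(sprintf("cell %d excluded: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      endpoints[i, ] <- res
      transformed[i] <- res[["NFKB"]] > theta[i, "NFKB_T"] / 2
    }
  }
  new("PopulationResult", cellParams = theta, endpoints = endpoints,
      transformed = transformed, variation = p, transientH = transientH,
      seed = seed)
}

#' Pearson correlation between endpoint variables
#'
#' Sample Pearson correlation of two species across the cell endpoints of a
#' population run (failed cells excluded).  With fewer than 3 usable cells
#' or zero variance in either variable the correlation is undefined and an
#' error of class `"episwitch_undefined_correlation"` is raised.
#'
#' @param result A [PopulationResult-class].
#' @param varX,varY Species names, e.g. `"Let7"`, `"IL6"`.
#' @return Pearson correlation coefficient.
#' @export
endpointCorrelation <- function(result, varX, varY) {
  stopifnot(is(result, "PopulationResult"))
  ok <- !is.na(result@transformed)
  x <- result@endpoints[ok, varX]
  y <- result@endpoints[ok, varY]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(structure(class = c("episwitch_undefined_correlation", "error",
                             "condition"),
                   list(message = sprintf(
                     "correlation of %s and %s is undefined (fewer than 3 cells or zero variance)",
                     varX, varY), call = sys.call(-1))))
  cor(x, y)
}
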