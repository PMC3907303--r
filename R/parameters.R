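## Parameter bookkeeping.  Parameters travel as a flat named numeric vector in
## a fixed order; the same order is hard-wired in src/model_rhs.c and
## src/ssa.cpp, so .paramOrder must never be reordered.

.paramOrder <- c(
  ## NF-kB activation / inactivation (Goldbeter-Koshland cycle on a conserved pool)
  "k_AA1NFKB", "k_AA2NFKB", "k_AA3NFKB", "K_IPTEN", "V_DNFKB",
  "K_ANFKB", "K_INFKB", "NFKB_T",
  ## Lin28
  "V_SLIN28", "K_A1NF", "k_DLIN28",
  ## Let-7 and its mRNA partners
  "V_SLET7", "K_ILET7", "k_1", "k_2", "k_3", "k_4", "k_5", "k_6", "k_DLET7",
  ## IL6 mRNA / protein
  "V_S1MIL6", "V_S2MIL6", "K_A2NF", "k_DMIL6", "k_DILLET", "k_SIL6", "k_DIL6",
  ## Ras mRNA / protein
  "V_SMRAS", "k_DMRAS", "k_DRASLET", "k_SRAS", "k_DRAS",
  ## STAT3, miR-21, PTEN
  "V_SSTAT", "K_AIL6", "k_DSTAT", "V_SMIR21", "K_ASTAT", "k_DMIR21",
  "V_SMPTEN", "k_DMPTEN", "k_DMIRMP", "k_SPTEN", "k_DPTEN",
  ## ceRNA extension (generic Let-7 sponge)
  "V_SCERNA", "k_7", "k_8", "k_DCERNA", "k_DCELET7",
  ## PTEN1 mRNA extension (miR-21 sponge)
  "V_SMPTEN1", "k_9", "k_10", "k_DMPTEN1", "k_DMIRMP1",
  ## inflammatory input level (treated as a parameter; protocols override it)
  "Src")

.michaelisConstants <- c("K_IPTEN", "K_ANFKB", "K_INFKB", "K_A1NF", "K_ILET7",
                         "K_A2NF", "K_AIL6", "K_ASTAT")

#' Default parameter set of the inflammation-transformation switch
#'
#' Returns the published reference parameterization of the model as a flat
#' named numeric vector.  Rate constants are per minute, concentrations and
#' Michaelis constants in micromolar.  The synthesis rates of the two
#' competing-endogenous-RNA extensions (`V_SCERNA`, `V_SMPTEN1`) and the PTEN
#' transcription rate `V_SMPTEN` default to 0, so the 14-variable core model
#' is recovered exactly.  The inflammatory input `Src` defaults to 0 (no
#' signal); time-dependent inputs are described by [srcConstant()] /
#' [srcPulse()] rather than by editing this entry.
#'
#' @return Named numeric vector with one entry per model parameter, in the
#'   canonical order used throughout the package.
#' @seealso [paramNames()], [applyOverrides()], [switchRHS()]
#' @examples
#' p <- defaultParams()
#' p[c("V_SLET7", "NFKB_T", "k_1", "K_AIL6")]
#' @export
defaultParams <- function() {
  c(k_AA1NFKB = 10, k_AA2NFKB = 0.09, k_AA3NFKB = 1, K_IPTEN = 5,
    V_DNFKB = 0.01, K_ANFKB = 0.01, K_INFKB = 0.02, NFKB_T = 1,
    V_SLIN28 = 0.012, K_A1NF = 0.01, k_DLIN28 = 0.002,
    V_SLET7 = 3, K_ILET7 = 0.1, k_1 = 10, k_2 = 0.01, k_3 = 10, k_4 = 0.01,
    k_5 = 10, k_6 = 0.01, k_DLET7 = 0.01,
    V_S1MIL6 = 0.1, V_S2MIL6 = 0.01, K_A2NF = 5, k_DMIL6 = 0.01,
    k_DILLET = 0.5, k_SIL6 = 1.2, k_DIL6 = 0.1,
    V_SMRAS = 0.005, k_DMRAS = 0.01, k_DRASLET = 0.5, k_SRAS = 1, k_DRAS = 0.1,
    V_SSTAT = 0.5, K_AIL6 = 40, k_DSTAT = 0.1,
    V_SMIR21 = 4, K_ASTAT = 5, k_DMIR21 = 0.2,
    V_SMPTEN = 0, k_DMPTEN = 0.01, k_DMIRMP = 0.01, k_SPTEN = 0.05,
    k_DPTEN = 0.1,
    V_SCERNA = 0, k_7 = 10, k_8 = 0.01, k_DCERNA = 0.01, k_DCELET7 = 0.01,
    V_SMPTEN1 = 0, k_9 = 10, k_10 = 0.01, k_DMPTEN1 = 0.01, k_DMIRMP1 = 0.01,
    Src = 0)[.paramOrder]
}

#' Canonical parameter names
#'
#' @return Character vector of all valid parameter symbols, in canonical
#'   order (`Src` last).
#' @export
paramNames <- function() .paramOrder

#' Validate a parameter vector
#'
#' Checks that `params` is a complete, canonically named, non-negative
#' parameter vector with strictly positive Michaelis constants and total
#' NF-kB pool.
#'
#' @param params Named numeric vector as returned by [defaultParams()].
#' @return Invisibly, `params` reordered canonically.  Errors on violation.
#' @export
assertParams <- function(params) {
  if (!is.numeric(params) || is.null(names(params)))
    stop("'params' must be a named numeric vector")
  unknown <- setdiff(names(params), .paramOrder)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.paramOrder, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  params <- params[.paramOrder]
  if (anyNA(params) || any(params < 0))
    stop("parameters must be non-negative and non-missing")
  if (params[["NFKB_T"]] <= 0)
    stop("NFKB_T must be strictly positive")
  km <- params[.michaelisConstants]
  if (any(km <= 0))
    stop("Michaelis constants must be strictly positive: ",
         paste(names(km)[km <= 0], collapse = ", "))
  invisible(params)
}

#' Override entries of a parameter vector by name
#'
#' Applies `overrides` on top of `params`, rejecting any symbol that is not a
#' model parameter; the error message suggests the nearest valid symbol, so a
#' typo against the published parameter table is caught immediately.
#'
#' @param params Base parameter vector.
#' @param overrides Named numeric vector or list of replacement values (may be
#'   empty).
#' @return The merged, validated parameter vector.
#' @examples
#' p <- applyOverrides(defaultParams(), c(V_SLET7 = 6, Src = 1e-6))
#' @export
applyOverrides <- function(params, overrides = NULL) {
  if (is.null(overrides) || length(overrides) == 0L)
    return(assertParams(params))
  overrides <- unlist(overrides)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("'overrides' must be named")
  bad <- setdiff(names(overrides), .paramOrder)
  if (length(bad)) {
    near <- vapply(bad, function(x) {
      d <- adist(x, .paramOrder, ignore.case = TRUE)
      .paramOrder[which.min(d)]
    }, character(1))
    stop("unknown parameter(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", bad, near), collapse = ", "))
  }
  params[names(overrides)] <- as.numeric(overrides)
  assertParams(params)
}
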