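## Model state: a named concentration vector in fixed (column-stable) order.
## The first 14 species are the core model; the last 4 belong to the two
## ceRNA extensions and stay identically zero when the extensions are off.

.stateOrder <- c("NFKB", "Lin28", "Let7", "mIL6", "mIL6Let7", "IL6",
                 "mRas", "mRasLet7", "Ras", "STAT3", "miR21", "mPTEN",
                 "miRmpten", "PTEN",
                 "ceRNA", "ceRNAlet7", "mPTEN1", "miRmpten1")
.coreSpecies  <- .stateOrder[1:14]
.cernaSpecies <- c("ceRNA", "ceRNAlet7")
.pten1Species <- c("mPTEN1", "miRmpten1")

#' Species names of the model state
#'
#' @param variant Optional [switchVariant()]; if supplied, only the species
#'   active under that variant are returned (core 14 plus the extension
#'   species that are switched on).
#' @return Character vector of species names in the fixed state order.
#' @export
stateNames <- function(variant = NULL) {
  if (is.null(variant)) return(.stateOrder)
  variant <- asVariant(variant)
  keep <- .coreSpecies
  if (variant$cerna) keep <- c(keep, .cernaSpecies)
  if (variant$pten1) keep <- c(keep, .pten1Species)
  .stateOrder[.stateOrder %in% keep]
}

#' Model variant flags
#'
#' The core model has 14 species.  Two optional competing-endogenous-RNA
#' extensions add two species each: a generic ceRNA that sponges Let-7, and
#' PTEN1 mRNA that sponges miR-21.  The core equations are identical across
#' variants except that the Let-7 balance gains the ceRNA binding fluxes and
#' the miR-21 balance gains the PTEN1 binding fluxes.
#'
#' @param cerna Logical; include the Let-7-sponging ceRNA species.
#' @param pten1 Logical; include the miR-21-sponging PTEN1 mRNA species.
#' @return A `SwitchVariant` list with elements `cerna` and `pten1`.
#' @export
switchVariant <- function(cerna = FALSE, pten1 = FALSE) {
  stopifnot(is.logical(cerna), length(cerna) == 1L, !is.na(cerna),
            is.logical(pten1), length(pten1) == 1L, !is.na(pten1))
  structure(list(cerna = cerna, pten1 = pten1), class = "SwitchVariant")
}

asVariant <- function(variant) {
  if (is.null(variant)) return(switchVariant())
  if (inherits(variant, "SwitchVariant")) return(variant)
  if (is.list(variant))
    return(switchVariant(isTRUE(variant$cerna), isTRUE(variant$pten1)))
  stop("'variant' must be created with switchVariant()")
}

## Expand a possibly partial state vector to the full 18-species order,
## zero-filling species that are not supplied.
fullState <- function(state) {
  if (is.null(names(state)))
    stop("'state' must be a named numeric vector")
  unknown <- setdiff(names(state), .stateOrder)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  full <- setNames(numeric(length(.stateOrder)), .stateOrder)
  full[names(state)] <- state
  full
}

#' Initial conditions: non-transformed start (set A)
#'
#' The resting initial-condition set: trace levels of every activator and a
#' unit level of Let-7.  Without an Src signal the system relaxes from here
#' to the non-transformed state (high Let-7, low NF-kB/Lin28/IL6/STAT3).
#'
#' @param variant Optional [switchVariant()]; extension species are included
#'   (at zero) when active.
#' @return Named concentration vector (micromolar).
#' @export
icSetA <- function(variant = NULL) {
  ic <- setNames(numeric(18), .stateOrder)
  ic[c("NFKB", "Lin28", "mIL6", "IL6", "mRas", "Ras", "STAT3", "mPTEN")] <- 0.01
  ic["Let7"] <- 1
  ic[stateNames(variant)]
}

#' Initial conditions: mid-level start (set B)
#'
#' The mid-level initial-condition set with every protein and mRNA pool at
#' 0.5 micromolar; from here the default model ignites the switch on its own
#' within a day.  Used by the stochastic and population layers as the
#' like-for-like deterministic reference start.
#'
#' @inheritParams icSetA
#' @return Named concentration vector (micromolar).
#' @export
icSetB <- function(variant = NULL) {
  ic <- setNames(numeric(18), .stateOrder)
  ic[c("NFKB", "Lin28", "mIL6", "IL6", "mRas", "Ras", "STAT3")] <- 0.5
  ic["Let7"] <- 1
  ic["mPTEN"] <- 0.01
  ic[stateNames(variant)]
}

#' Diagnose state-vector invariant violations
#'
#' Reports (without raising) violations of the model-state invariants:
#' negative concentrations, active NF-kB exceeding the conserved total
#' `NFKB_T`, and non-zero extension species while the corresponding variant
#' flag is off.
#'
#' @param state Named concentration vector (full or variant-subset order).
#' @param params Parameter vector (used for `NFKB_T`).
#' @param variant Optional [switchVariant()].
#' @return Character vector of violation messages; empty if the state is
#'   admissible.
#' @examples
#' validateState(icSetA(), defaultParams())
#' @export
validateState <- function(state, params = defaultParams(), variant = NULL) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  full <- fullState(state)
  out <- character(0)
  neg <- names(full)[full < 0]
  if (length(neg))
    out <- c(out, paste0("negative concentration: ", paste(neg, collapse = ", ")))
  if (full[["NFKB"]] > params[["NFKB_T"]])
    out <- c(out, sprintf("NFKB exceeds total (%g > NFKB_T = %g)",
                          full[["NFKB"]], params[["NFKB_T"]]))
  if (!variant$cerna && any(full[.cernaSpecies] != 0))
    out <- c(out, "ceRNA species non-zero but the ceRNA variant is off")
  if (!variant$pten1 && any(full[.pten1Species] != 0))
    out <- c(out, "PTEN1 species non-zero but the PTEN1 variant is off")
  out
}
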