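#' Right-hand side of the kinetic equations
#'
#' Reference implementation of the model's kinetic equations, one derivative
#' per active species in micromolar per minute.  NF-kB activation and
#' inactivation form a Goldbeter-Koshland (zero-order ultrasensitive) cycle on
#' the conserved pool `NFKB_T`: the activation drive `k_AA1NFKB*Src +
#' k_AA2NFKB*IL6 + k_AA3NFKB*Ras`, attenuated by PTEN through the Michaelian
#' factor `K_IPTEN/(K_IPTEN + PTEN)`, acts on the inactive fraction with
#' Michaelis constant `K_ANFKB`, while inactivation proceeds at maximal rate
#' `V_DNFKB` with Michaelis constant `K_INFKB`.  Every other process is
#' mass-action: Michaelian synthesis terms (Lin28 activated by NF-kB, Let-7
#' repressed by Lin28, IL6 mRNA with a constitutive and an NF-kB-dependent
#' term, STAT3 activated by IL6, miR-21 activated by STAT3), reversible
#' miRNA-mRNA binding for the Let7/mIL6, Let7/mRas and miR21/mPTEN pairs (and
#' Let7/ceRNA, miR21/mPTEN1 when the extensions are active), first-order
#' degradation of every pool, and degradation of each inhibitory complex that
#' destroys both partners.
#'
#' The same equations are compiled in C for the integrator; this R version is
#' the readable source of truth, used for Jacobians and tested against the
#' compiled one.
#'
#' @param t Time, minutes (only used to evaluate the Src protocol).
#' @param state Named concentration vector (full 18-species order or the
#'   active subset for `variant`).
#' @param params Parameter vector, see [defaultParams()].
#' @param src [SrcProtocol-class] input, or a single number meaning a
#'   constant level; if `NULL`, the `Src` entry of `params` is used.
#' @param variant [switchVariant()] flags.
#' @param check Validate the state first (negative concentrations or inactive
#'   extension species raise an error).  Disable in inner loops.
#' @return Named derivative vector over the active species, micromolar/min.
#' @examples
#' # at an empty state only the synthesis terms survive:
#' switchRHS(0, icSetA() * 0, defaultParams())[c("Let7", "mRas")]
#' @export
switchRHS <- function(t, state, params, src = NULL, variant = NULL,
                      check = TRUE) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  active <- stateNames(variant)
  if (check) {
    ## non-zero extension species under an inactive variant are flagged here
    bad <- validateState(state, params, variant)
    if (length(bad)) stop("inadmissible state: ", paste(bad, collapse = "; "))
  }
  y <- fullState(state)
  srcNow <- if (is.null(src)) params[["Src"]]
            else if (is.numeric(src)) src[1]
            else srcLevel(src, t)
  d <- rhsFull(y, params, srcNow)
  d[active]
}

## Core derivative computation on the full 18-species vector; src is a plain
## number.  Kept separate so the Jacobian and the deSolve wrapper can call it
## without re-validating.
rhsFull <- function(y, p, srcNow) {
  NFKB <- y[[1]]; Lin28 <- y[[2]]; Let7 <- y[[3]]; mIL6 <- y[[4]]
  mIL6Let7 <- y[[5]]; IL6 <- y[[6]]; mRas <- y[[7]]; mRasLet7 <- y[[8]]
  Ras <- y[[9]]; STAT3 <- y[[10]]; miR21 <- y[[11]]; mPTEN <- y[[12]]
  miRmpten <- y[[13]]; PTEN <- y[[14]]; ceRNA <- y[[15]]; ceRNAlet7 <- y[[16]]
  mPTEN1 <- y[[17]]; miRmpten1 <- y[[18]]

  drive <- (p[["k_AA1NFKB"]] * srcNow + p[["k_AA2NFKB"]] * IL6 +
              p[["k_AA3NFKB"]] * Ras) * p[["K_IPTEN"]] / (p[["K_IPTEN"]] + PTEN)
  inactive <- p[["NFKB_T"]] - NFKB
  act <- drive * inactive / (p[["K_ANFKB"]] + inactive)
  inact <- p[["V_DNFKB"]] * NFKB / (p[["K_INFKB"]] + NFKB)

  bIL6 <- p[["k_1"]] * Let7 * mIL6 - p[["k_2"]] * mIL6Let7
  bRas <- p[["k_3"]] * Let7 * mRas - p[["k_4"]] * mRasLet7
  bPt  <- p[["k_5"]] * miR21 * mPTEN - p[["k_6"]] * miRmpten
  bCe  <- p[["k_7"]] * Let7 * ceRNA - p[["k_8"]] * ceRNAlet7
  bPt1 <- p[["k_9"]] * miR21 * mPTEN1 - p[["k_10"]] * miRmpten1

  c(NFKB = act - inact,
    Lin28 = p[["V_SLIN28"]] * NFKB / (p[["K_A1NF"]] + NFKB) -
      p[["k_DLIN28"]] * Lin28,
    Let7 = p[["V_SLET7"]] * p[["K_ILET7"]] / (p[["K_ILET7"]] + Lin28) -
      bIL6 - bRas - bCe - p[["k_DLET7"]] * Let7,
    mIL6 = p[["V_S1MIL6"]] + p[["V_S2MIL6"]] * NFKB / (p[["K_A2NF"]] + NFKB) -
      bIL6 - p[["k_DMIL6"]] * mIL6,
    mIL6Let7 = bIL6 - p[["k_DILLET"]] * mIL6Let7,
    IL6 = p[["k_SIL6"]] * mIL6 - p[["k_DIL6"]] * IL6,
    mRas = p[["V_SMRAS"]] - bRas - p[["k_DMRAS"]] * mRas,
    mRasLet7 = bRas - p[["k_DRASLET"]] * mRasLet7,
    Ras = p[["k_SRAS"]] * mRas - p[["k_DRAS"]] * Ras,
    STAT3 = p[["V_SSTAT"]] * IL6 / (p[["K_AIL6"]] + IL6) -
      p[["k_DSTAT"]] * STAT3,
    miR21 = p[["V_SMIR21"]] * STAT3 / (p[["K_ASTAT"]] + STAT3) -
      bPt - bPt1 - p[["k_DMIR21"]] * miR21,
    mPTEN = p[["V_SMPTEN"]] - bPt - p[["k_DMPTEN"]] * mPTEN,
    miRmpten = bPt - p[["k_DMIRMP"]] * miRmpten,
    PTEN = p[["k_SPTEN"]] * mPTEN - p[["k_DPTEN"]] * PTEN,
    ceRNA = p[["V_SCERNA"]] - bCe - p[["k_DCERNA"]] * ceRNA,
    ceRNAlet7 = bCe - p[["k_DCELET7"]] * ceRNAlet7,
    mPTEN1 = p[["V_SMPTEN1"]] - bPt1 - p[["k_DMPTEN1"]] * mPTEN1,
    miRmpten1 = bPt1 - p[["k_DMIRMP1"]] * miRmpten1)
}
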