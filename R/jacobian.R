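## Analytic Jacobian of the kinetic equations on the full 18-species state.
## Used by the Newton/continuation machinery and stability classification,
## where finite-difference noise along the slow eigendirection would corrupt
## the step; the exported finite-difference switchJacobian() is the
## model-agnostic diagnostic and is tested against this one.

jacAnalytic <- function(y, p, srcNow) {
  J <- matrix(0, 18, 18, dimnames = list(.stateOrder, .stateOrder))
  NFKB <- y[[1]]; Lin28 <- y[[2]]; Let7 <- y[[3]]; mIL6 <- y[[4]]
  IL6 <- y[[6]]; mRas <- y[[7]]; Ras <- y[[9]]; STAT3 <- y[[10]]
  miR21 <- y[[11]]; mPTEN <- y[[12]]; PTEN <- y[[14]]; ceRNA <- y[[15]]
  mPTEN1 <- y[[17]]

  kin <- p[["K_INFKB"]]; kan <- p[["K_ANFKB"]]; ki <- p[["K_IPTEN"]]
  inact <- p[["NFKB_T"]] - NFKB
  g <- inact / (kan + inact)
  gp <- kan / (kan + inact)^2          # d g / d inact
  raw <- p[["k_AA1NFKB"]] * srcNow + p[["k_AA2NFKB"]] * IL6 +
    p[["k_AA3NFKB"]] * Ras
  fp <- ki / (ki + PTEN)
  J["NFKB", "NFKB"] <- -raw * fp * gp -
    p[["V_DNFKB"]] * kin / (kin + NFKB)^2
  J["NFKB", "IL6"] <- p[["k_AA2NFKB"]] * fp * g
  J["NFKB", "Ras"] <- p[["k_AA3NFKB"]] * fp * g
  J["NFKB", "PTEN"] <- -raw * ki / (ki + PTEN)^2 * g

  J["Lin28", "NFKB"] <- p[["V_SLIN28"]] * p[["K_A1NF"]] /
    (p[["K_A1NF"]] + NFKB)^2
  J["Lin28", "Lin28"] <- -p[["k_DLIN28"]]

  k1 <- p[["k_1"]]; k2 <- p[["k_2"]]; k3 <- p[["k_3"]]; k4 <- p[["k_4"]]
  k5 <- p[["k_5"]]; k6 <- p[["k_6"]]; k7 <- p[["k_7"]]; k8 <- p[["k_8"]]
  k9 <- p[["k_9"]]; k10 <- p[["k_10"]]

  J["Let7", "Lin28"] <- -p[["V_SLET7"]] * p[["K_ILET7"]] /
    (p[["K_ILET7"]] + Lin28)^2
  J["Let7", "Let7"] <- -k1 * mIL6 - k3 * mRas - k7 * ceRNA - p[["k_DLET7"]]
  J["Let7", "mIL6"] <- -k1 * Let7
  J["Let7", "mIL6Let7"] <- k2
  J["Let7", "mRas"] <- -k3 * Let7
  J["Let7", "mRasLet7"] <- k4
  J["Let7", "ceRNA"] <- -k7 * Let7
  J["Let7", "ceRNAlet7"] <- k8

  J["mIL6", "NFKB"] <- p[["V_S2MIL6"]] * p[["K_A2NF"]] /
    (p[["K_A2NF"]] + NFKB)^2
  J["mIL6", "Let7"] <- -k1 * mIL6
  J["mIL6", "mIL6"] <- -k1 * Let7 - p[["k_DMIL6"]]
  J["mIL6", "mIL6Let7"] <- k2

  J["mIL6Let7", "Let7"] <- k1 * mIL6
  J["mIL6Let7", "mIL6"] <- k1 * Let7
  J["mIL6Let7", "mIL6Let7"] <- -k2 - p[["k_DILLET"]]

  J["IL6", "mIL6"] <- p[["k_SIL6"]]
  J["IL6", "IL6"] <- -p[["k_DIL6"]]

  J["mRas", "Let7"] <- -k3 * mRas
  J["mRas", "mRas"] <- -k3 * Let7 - p[["k_DMRAS"]]
  J["mRas", "mRasLet7"] <- k4

  J["mRasLet7", "Let7"] <- k3 * mRas
  J["mRasLet7", "mRas"] <- k3 * Let7
  J["mRasLet7", "mRasLet7"] <- -k4 - p[["k_DRASLET"]]

  J["Ras", "mRas"] <- p[["k_SRAS"]]
  J["Ras", "Ras"] <- -p[["k_DRAS"]]

  J["STAT3", "IL6"] <- p[["V_SSTAT"]] * p[["K_AIL6"]] /
    (p[["K_AIL6"]] + IL6)^2
  J["STAT3", "STAT3"] <- -p[["k_DSTAT"]]

  J["miR21", "STAT3"] <- p[["V_SMIR21"]] * p[["K_ASTAT"]] /
    (p[["K_ASTAT"]] + STAT3)^2
  J["miR21", "miR21"] <- -k5 * mPTEN - k9 * mPTEN1 - p[["k_DMIR21"]]
  J["miR21", "mPTEN"] <- -k5 * miR21
  J["miR21", "miRmpten"] <- k6
  J["miR21", "mPTEN1"] <- -k9 * miR21
  J["miR21", "miRmpten1"] <- k10

  J["mPTEN", "miR21"] <- -k5 * mPTEN
  J["mPTEN", "mPTEN"] <- -k5 * miR21 - p[["k_DMPTEN"]]
  J["mPTEN", "miRmpten"] <- k6

  J["miRmpten", "miR21"] <- k5 * mPTEN
  J["miRmpten", "mPTEN"] <- k5 * miR21
  J["miRmpten", "miRmpten"] <- -k6 - p[["k_DMIRMP"]]

  J["PTEN", "mPTEN"] <- p[["k_SPTEN"]]
  J["PTEN", "PTEN"] <- -p[["k_DPTEN"]]

  J["ceRNA", "Let7"] <- -k7 * ceRNA
  J["ceRNA", "ceRNA"] <- -k7 * Let7 - p[["k_DCERNA"]]
  J["ceRNA", "ceRNAlet7"] <- k8

  J["ceRNAlet7", "Let7"] <- k7 * ceRNA
  J["ceRNAlet7", "ceRNA"] <- k7 * Let7
  J["ceRNAlet7", "ceRNAlet7"] <- -k8 - p[["k_DCELET7"]]

  J["mPTEN1", "miR21"] <- -k9 * mPTEN1
  J["mPTEN1", "mPTEN1"] <- -k9 * miR21 - p[["k_DMPTEN1"]]
  J["mPTEN1", "miRmpten1"] <- k10

  J["miRmpten1", "miR21"] <- k9 * mPTEN1
  J["miRmpten1", "mPTEN1"] <- k9 * miR21
  J["miRmpten1", "miRmpten1"] <- -k10 - p[["k_DMIRMP1"]]

  J
}
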