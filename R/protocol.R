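#' Time-dependent Src input protocols
#'
#' The inflammatory signal Src enters the NF-kB activation rate as a
#' time-dependent input.  Two protocols cover the published in-silico
#' experiments: a constant level, and a rectangular pulse of given height and
#' duration followed by a (usually zero) baseline.
#'
#' @slot kind `"constant"` or `"pulse"`.
#' @slot level Constant Src level (micromolar-equivalent activity).
#' @slot pulseHeight,pulseStart,pulseDuration Pulse geometry, in minutes for
#'   the times.
#' @slot baselineAfter Src level outside the pulse.
#' @name SrcProtocol-class
#' @aliases SrcProtocol
#' @exportClass SrcProtocol
setClass("SrcProtocol",
  representation(kind = "character", level = "numeric",
                 pulseHeight = "numeric", pulseStart = "numeric",
                 pulseDuration = "numeric", baselineAfter = "numeric"),
  prototype(kind = "constant", level = 0, pulseHeight = 0, pulseStart = 0,
            pulseDuration = 0, baselineAfter = 0),
  validity = function(object) {
    if (!object@kind %in% c("constant", "pulse"))
      return("kind must be 'constant' or 'pulse'")
    vals <- c(object@level, object@pulseHeight, object@pulseStart,
              object@pulseDuration, object@baselineAfter)
    if (anyNA(vals) || any(vals < 0))
      return("Src levels and pulse times must be non-negative")
    TRUE
  })

#' Constant Src input
#'
#' @param level Src level held for all times.
#' @return A [SrcProtocol-class] object.
#' @examples
#' srcConstant(5e-5)
#' @export
srcConstant <- function(level = 0)
  new("SrcProtocol", kind = "constant", level = level)

#' Pulsed Src input
#'
#' A rectangular Src pulse, by default the published transient stimulus:
#' height 0.015 applied during the first 5 minutes, zero afterwards.
#'
#' @param height Src level during the pulse.
#' @param start Pulse onset, minutes.
#' @param duration Pulse length, minutes.
#' @param baseline Src level outside the pulse.
#' @return A [SrcProtocol-class] object.
#' @examples
#' srcPulse()                      # 0.015 for 5 min from t = 0
#' srcPulse(0.02, duration = 10)
#' @export
srcPulse <- function(height = 0.015, start = 0, duration = 5, baseline = 0)
  new("SrcProtocol", kind = "pulse", level = baseline, pulseHeight = height,
      pulseStart = start, pulseDuration = duration, baselineAfter = baseline)

#' Evaluate an Src protocol
#'
#' @param protocol A [SrcProtocol-class] object.
#' @param tMin Time(s) in minutes.
#' @return Src level at each requested time.
#' @export
srcLevel <- function(protocol, tMin) {
  stopifnot(is(protocol, "SrcProtocol"))
  if (protocol@kind == "constant")
    return(rep(protocol@level, length(tMin)))
  ifelse(tMin >= protocol@pulseStart &
           tMin < protocol@pulseStart + protocol@pulseDuration,
         protocol@pulseHeight, protocol@baselineAfter)
}

## Interior breakpoints (minutes) at which the protocol jumps; integration is
## restarted there so the discontinuities are exact.
srcBreaks <- function(protocol, t0, t1) {
  if (protocol@kind == "constant") return(numeric(0))
  br <- c(protocol@pulseStart, protocol@pulseStart + protocol@pulseDuration)
  sort(br[br > t0 & br < t1])
}

setMethod("show", "SrcProtocol", function(object) {
  if (object@kind == "constant") {
    cat(sprintf("<SrcProtocol> constant, Src = %g\n", object@level))
  } else {
    cat(sprintf(
      "<SrcProtocol> pulse, Src = %g for t in [%g, %g] min, %g outside\n",
      object@pulseHeight, object@pulseStart,
      object@pulseStart + object@pulseDuration, object@baselineAfter))
  }
})
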