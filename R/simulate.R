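#' Deterministic trajectory of the switch model
#'
#' S4 container for a deterministic simulation: sample times in hours,
#' a states matrix (one row per time, one column per active species), and the
#' inputs that produced it.
#'
#' @slot times Numeric vector, hours, strictly increasing.
#' @slot states Numeric matrix of concentrations (micromolar).
#' @slot params Parameter vector used outside perturbation windows.
#' @slot src The [SrcProtocol-class] input.
#' @slot variant Variant flags (list with `cerna`, `pten1`).
#' @slot perturbations List of [perturbationWindow()] specifications.
#' @name SwitchTrajectory-class
#' @aliases SwitchTrajectory
#' @exportClass SwitchTrajectory
setClass("SwitchTrajectory",
  representation(times = "numeric", states = "matrix", params = "numeric",
                 src = "SrcProtocol", variant = "list",
                 perturbations = "list"),
  validity = function(object) {
    if (length(object@times) != nrow(object@states))
      return("times and states disagree in length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    TRUE
  })

#' @describeIn SwitchTrajectory-class Sample times in hours.
#' @param traj A `SwitchTrajectory`.
#' @export
trajTimes <- function(traj) traj@times

#' @describeIn SwitchTrajectory-class Concentration matrix (rows = times).
#' @export
trajStates <- function(traj) traj@states

#' @describeIn SwitchTrajectory-class Final state of the trajectory.
#' @export
endState <- function(traj) traj@states[nrow(traj@states), ]

setMethod("show", "SwitchTrajectory", function(object) {
  n <- length(object@times)
  cat(sprintf("<SwitchTrajectory> %d samples over [%g, %g] h, %d species\n",
              n, object@times[1], object@times[n], ncol(object@states)))
  st <- detectSwitchTime(object)
  if (is.na(st)) cat("  no switch (non-transformed endpoint)\n")
  else cat(sprintf("  switch to the transformed state at %.1f h\n", st))
})

#' @export
as.data.frame.SwitchTrajectory <- function(x, ...) {
  data.frame(time_h = x@times, x@states, check.names = FALSE)
}

#' Time-windowed parameter perturbation
#'
#' Parameter overrides that are active only inside a time window, used for
#' transient-inhibition and overexpression experiments (e.g. zeroing the
#' NF-kB activation constants between 100 and 130 h, or raising `V_SMIR21`
#' from 100 h on).  Outside the window the baseline parameters apply exactly;
#' the integrator restarts at the window boundaries.
#'
#' @param start,end Window boundaries in hours (`end = Inf` keeps the
#'   override active until the end of the run).
#' @param overrides Named numeric vector of parameter replacements.
#' @return A `PerturbationWindow` list.
#' @export
perturbationWindow <- function(start, end, overrides) {
  stopifnot(is.numeric(start), is.numeric(end), start < end)
  if (is.null(names(overrides)))
    stop("'overrides' must be named")
  structure(list(start = start, end = end, overrides = unlist(overrides)),
            class = "PerturbationWindow")
}

#' Integrate the kinetic model
#'
#' Integrates the model with the stiff-capable `lsoda` solver and the
#' compiled right-hand side.  The time axis is segmented at every Src-protocol
#' jump and perturbation-window boundary so the discontinuities are resolved
#' exactly; within a segment the output is sampled densely enough to resolve
#' the switch.
#'
#' @param params Parameter vector ([defaultParams()] plus overrides).
#' @param init Named initial concentration vector; defaults to the mid-level
#'   set [icSetB()].
#' @param src [SrcProtocol-class] input or a single number (constant level);
#'   `NULL` uses the `Src` entry of `params`.
#' @param tEnd End of the run, hours.
#' @param perturbations List of [perturbationWindow()] objects.
#' @param variant [switchVariant()] flags.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param hmax Maximum solver step, minutes; bounds the step across the
#'   minute-scale binding kinetics.
#' @param sampleEvery Output sampling interval, hours.
#' @return A [SwitchTrajectory-class].
#' @examples
#' traj <- simulateSwitch(defaultParams(), icSetA(), srcConstant(5e-5),
#'                        tEnd = 100)
#' detectSwitchTime(traj)
#' @export
simulateSwitch <- function(params = defaultParams(), init = NULL, src = NULL,
                           tEnd = 100, perturbations = list(),
                           variant = NULL, rtol = 1e-8, atol = 1e-10,
                           hmax = 6, sampleEvery = 0.1) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  active <- stateNames(variant)
  if (is.null(init)) init <- icSetB(variant)
  bad <- validateState(init, params, variant)
  if (length(bad)) stop("invalid initial condition: ",
                        paste(bad, collapse = "; "))
  if (is.null(src)) src <- srcConstant(params[["Src"]])
  if (is.numeric(src)) src <- srcConstant(src)
  if (inherits(perturbations, "PerturbationWindow"))
    perturbations <- list(perturbations)
  stopifnot(tEnd >= 0)

  y <- fullState(init)
  if (tEnd == 0) {
    return(new("SwitchTrajectory", times = 0,
               states = matrix(y[active], nrow = 1,
                               dimnames = list(NULL, active)),
               params = params, src = src, variant = unclass(variant),
               perturbations = perturbations))
  }

  tEndMin <- tEnd * 60
  breaks <- srcBreaks(src, 0, tEndMin)
  for (w in perturbations) {
    stopifnot(inherits(w, "PerturbationWindow"))
    wb <- c(w$start, w$end) * 60
    breaks <- c(breaks, wb[wb > 0 & wb < tEndMin])
  }
  bounds <- sort(unique(c(0, breaks, tEndMin)))

  dtMin <- sampleEvery * 60
  times <- NULL
  states <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    mid <- (t0 + t1) / 2
    pSeg <- params
    for (w in perturbations)
      if (mid >= w$start * 60 && mid < w$end * 60)
        pSeg <- applyOverrides(pSeg, w$overrides)
    pSeg[["Src"]] <- srcLevel(src, mid)
    tt <- unique(c(seq(t0, t1, by = dtMin), t1))
    out <- deSolve::ode(y = y, times = tt, parms = unname(pSeg),
                        func = "episwitch_derivs",
                        initfunc = "episwitch_initmod",
                        dllname = "episwitch", method = "lsoda",
                        rtol = rtol, atol = atol, hmax = hmax)
    if (attr(out, "istate")[1L] < 0)
      stop(sprintf("integration failed near t = %.2f h",
                   max(out[, 1L]) / 60))
    seg <- out[, -1L, drop = FALSE]
    colnames(seg) <- .stateOrder
    if (min(seg) < -1e-6)
      stop(sprintf("negative concentration beyond tolerance near t = %.2f h",
                   out[which(apply(seg, 1, min) < -1e-6)[1], 1L] / 60))
    seg[seg < 0] <- 0
    keep <- if (is.null(times)) seq_len(nrow(seg)) else -1L
    times <- c(times, out[keep, 1L])
    states <- rbind(states, seg[keep, , drop = FALSE])
    y <- seg[nrow(seg), ]
  }

  new("SwitchTrajectory", times = times / 60,
      states = states[, active, drop = FALSE], params = params, src = src,
      variant = unclass(variant), perturbations = perturbations)
}

#' Transformed-state test
#'
#' A cell is classified as transformed when its active NF-kB level exceeds
#' half the conserved total `NFKB_T`: the NF-kB response is digital, so the
#' two attractors sit far on either side of this midpoint.  The same rule
#' classifies deterministic endpoints, stochastic copy-number endpoints
#' (count > `omega * NFKB_T / 2`) and population members.
#'
#' @param x A [SwitchTrajectory-class] (its final state is used) or a named
#'   state vector.
#' @param params Parameter vector supplying `NFKB_T`.
#' @return Logical.
#' @export
isTransformed <- function(x, params = defaultParams()) {
  s <- if (is(x, "SwitchTrajectory")) endState(x) else x
  unname(s["NFKB"] > assertParams(params)[["NFKB_T"]] / 2)
}

#' Switch-time detection
#'
#' Locates the time of the transition to the transformed state on a
#' deterministic trajectory.  The trajectory is first classified by the
#' endpoint NF-kB midpoint rule ([isTransformed()]); if it ends
#' non-transformed the result is `NA` (no switch).  For a transformed
#' endpoint the reported time is the mid-rise of STAT3 — the last upward
#' crossing of half its final level, located by linear interpolation — i.e.
#' the moment the transformation marker completes half of its excursion.
#' STAT3 is used as the read-out because it is the model's transformation
#' effector and rises with the slow switching cascade, whereas active NF-kB
#' itself saturates within minutes whenever the direct Src drive exceeds the
#' inactivation capacity, which would time-stamp the stimulus rather than the
#' switch.
#'
#' @param traj A [SwitchTrajectory-class].
#' @param tMax Optionally truncate the trajectory at this time (hours) before
#'   analysis, e.g. to ask whether the switch had happened before a
#'   perturbation window.
#' @return Switch time in hours, `0` if the trajectory starts (and stays)
#'   beyond the half-rise level, or `NA` if no switch occurs.
#' @export
detectSwitchTime <- function(traj, tMax = NULL) {
  stopifnot(is(traj, "SwitchTrajectory"))
  t <- traj@times
  S <- traj@states
  if (!is.null(tMax)) {
    keep <- t <= tMax
    t <- t[keep]; S <- S[keep, , drop = FALSE]
  }
  n <- length(t)
  if (n == 0L) return(NA_real_)
  if (S[n, "NFKB"] <= traj@params[["NFKB_T"]] / 2) return(NA_real_)
  s3 <- S[, "STAT3"]
  half <- s3[n] / 2
  below <- which(s3 < half)
  if (!length(below)) return(0)
  i <- max(below)
  if (i == n) return(NA_real_)   # still rising through the threshold at tEnd
  t[i] + (half - s3[i]) / (s3[i + 1L] - s3[i]) * (t[i + 1L] - t[i])
}
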