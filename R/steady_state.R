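## Steady states, linear stability and one-parameter bifurcation structure.
## The system has at most three coexisting steady states in all published
## regimes, so branch tracking uses brute-force relaxation plus damped-Newton
## continuation rather than arclength continuation.

#' Jacobian of the kinetic equations
#'
#' Central finite-difference Jacobian of the right-hand side on the active
#' species subsystem (per-minute units), with relative step `relStep` and
#' absolute floor `absFloor` on each coordinate.
#'
#' @param params Parameter vector.
#' @param state Named state vector (active species).
#' @param variant [switchVariant()] flags.
#' @param src Constant Src level; `NULL` uses `params[["Src"]]`.
#' @param relStep,absFloor Finite-difference step control.
#' @return Square matrix over the active species.
#' @export
switchJacobian <- function(params, state, variant = NULL, src = NULL,
                           relStep = 1e-6, absFloor = 1e-9) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  active <- stateNames(variant)
  y <- fullState(state)
  srcNow <- if (is.null(src)) params[["Src"]] else src
  n <- length(active)
  J <- matrix(0, n, n, dimnames = list(active, active))
  for (j in seq_len(n)) {
    h <- max(abs(y[[active[j]]]) * relStep, absFloor)
    yp <- y; yp[active[j]] <- yp[active[j]] + h
    ym <- y; ym[active[j]] <- ym[active[j]] - h
    J[, j] <- (rhsFull(yp, params, srcNow)[active] -
                 rhsFull(ym, params, srcNow)[active]) / (2 * h)
  }
  J
}

## Damped Newton iteration on the active subsystem; returns the polished
## state (full 18-vector) with convergence flag and residual norm.
newtonPolish <- function(params, state, variant = NULL, src = NULL,
                         tol = 1e-12, maxIter = 60) {
  variant <- asVariant(variant)
  active <- stateNames(variant)
  srcNow <- if (is.null(src)) params[["Src"]] else src
  y <- fullState(state)
  for (it in seq_len(maxIter)) {
    f <- rhsFull(y, params, srcNow)[active]
    res <- sqrt(sum(f^2))
    if (res < tol) break
    J <- jacAnalytic(y, params, srcNow)[active, active]
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(state = y, converged = FALSE, residual = res))
    lambda <- 1
    improved <- FALSE
    for (k in 1:12) {
      yTry <- y
      yTry[active] <- pmax(y[active] + lambda * step, 0)
      fTry <- rhsFull(yTry, params, srcNow)[active]
      if (sqrt(sum(fTry^2)) < res) {
        y <- yTry; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) return(list(state = y, converged = res < 1e-9,
                               residual = res))
  }
  f <- rhsFull(y, params, srcNow)[active]
  res <- sqrt(sum(f^2))
  list(state = y, converged = res < 1e-10, residual = res)
}

## Long relaxation toward an attractor (no hmax bound: steps grow near the
## fixed point), followed by a Newton polish.
relaxToSteady <- function(params, init, variant = NULL, src = NULL,
                          hours = 5000) {
  pp <- params
  pp[["Src"]] <- if (is.null(src)) params[["Src"]] else src
  y <- fullState(init)
  out <- deSolve::ode(y = y, times = c(0, hours * 60), parms = unname(pp),
                      func = "episwitch_derivs",
                      initfunc = "episwitch_initmod", dllname = "episwitch",
                      method = "lsoda", rtol = 1e-9, atol = 1e-11, maxsteps = 50000)
  yEnd <- pmax(out[nrow(out), -1L], 0)
  names(yEnd) <- .stateOrder
  newtonPolish(params, yEnd, variant, src)
}

classifySteady <- function(params, stateFull, variant, src, residual) {
  active <- stateNames(asVariant(variant))
  ev <- eigen(jacAnalytic(fullState(stateFull), params, src)[active, active],
              only.values = TRUE)$values
  lead <- max(Re(ev))
  list(state = stateFull[active], stable = lead < 0,
       leadingEigenvalue = lead, residual = residual)
}

#' Locate the steady states at a fixed Src level
#'
#' Multi-start search: relaxes a deterministic grid of starting states (both
#' initial-condition sets plus log-spaced uniform states) to their attractors
#' by long integration, polishes each by damped Newton, merges duplicates at
#' relative distance `1e-4`, and then seeks the separating saddle by Newton
#' iterations started from midpoints of each pair of distinct stable states.
#' Newton failures are dropped silently (the relaxed state is kept only if
#' its residual passes), never raised.
#'
#' @param params Parameter vector.
#' @param src Src level at which to solve; `NULL` uses `params[["Src"]]`.
#' @param variant [switchVariant()] flags.
#' @param nStarts Number of relaxation starts (>= 2; the IC sets are always
#'   included).
#' @param relaxHours Relaxation horizon, hours.
#' @return List of steady-state records, each with elements `state` (named
#'   vector over active species), `stable`, `leadingEigenvalue` (per minute)
#'   and `residual` (micromolar/min).
#' @examples
#' \donttest{
#' ss <- findSteadyStates(applyOverrides(defaultParams(), c(V_SLET7 = 6)),
#'                        src = 1e-6)
#' length(ss)   # two stable states and the saddle between them
#' }
#' @export
findSteadyStates <- function(params, src = NULL, variant = NULL,
                             nStarts = 20, relaxHours = 5000) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  active <- stateNames(variant)
  if (is.null(src)) src <- params[["Src"]]

  starts <- list(fullState(icSetA(variant)), fullState(icSetB(variant)))
  nExtra <- max(nStarts - 2L, 0L)
  ## half the extra starts are uniform log-spaced levels, half pit a low
  ## Let-7 pool against elevated activators so the transformed basin is
  ## explored even when the resting sets relax to the same attractor
  nU <- ceiling(nExtra / 2); nT <- nExtra - nU
  if (nU > 0) {
    for (lv in 10^seq(-3, 2, length.out = nU)) {
      s <- setNames(rep(lv, 18), .stateOrder)
      s["NFKB"] <- min(lv, params[["NFKB_T"]])
      s[!(.stateOrder %in% active)] <- 0
      s[c("mIL6Let7", "mRasLet7", "miRmpten", "ceRNAlet7", "miRmpten1")] <- 0
      starts <- c(starts, list(s))
    }
  }
  if (nT > 0) {
    for (lv in 10^seq(-1, 2, length.out = nT)) {
      s <- setNames(numeric(18), .stateOrder)
      s["NFKB"] <- params[["NFKB_T"]]
      s[c("Lin28", "mIL6", "IL6", "mRas", "Ras", "STAT3")] <- lv
      s[!(.stateOrder %in% active)] <- 0
      starts <- c(starts, list(s))
    }
  }

  found <- list()
  addState <- function(found, cand) {
    for (f in found) {
      ref <- pmax(sqrt(sum(f$state^2)), 1e-8)
      if (sqrt(sum((f$state - cand$state)^2)) / ref < 1e-4) return(found)
    }
    c(found, list(cand))
  }
  for (s in starts) {
    pol <- relaxToSteady(params, s, variant, src, hours = relaxHours)
    if (!pol$converged || pol$residual > 1e-10) next
    found <- addState(found, classifySteady(params, pol$state, variant, src,
                                            pol$residual))
  }

  stableStates <- Filter(function(f) f$stable, found)
  if (length(stableStates) >= 2) {
    idx <- utils::combn(length(stableStates), 2)
    for (k in seq_len(ncol(idx))) {
      a <- stableStates[[idx[1, k]]]$state
      b <- stableStates[[idx[2, k]]]$state
      mid <- fullState((a + b) / 2)
      pol <- newtonPolish(params, mid, variant, src)
      if (pol$converged && pol$residual <= 1e-10)
        found <- addState(found, classifySteady(params, pol$state, variant,
                                                src, pol$residual))
    }
  }
  found
}

#' One-parameter bifurcation diagram
#'
#' S4 container for a parameter sweep: the grid, the steady states found at
#' each grid value, and the detected bistable interval.
#'
#' @slot parameter Name of the swept parameter.
#' @slot grid Sorted numeric grid.
#' @slot branches List (one element per grid value) of steady-state record
#'   lists as returned by [findSteadyStates()].
#' @slot bistable Numeric of length 2 (lower/upper fold bracket) or
#'   `c(NA, NA)` when no bistable window is found.
#' @name BifurcationDiagram-class
#' @aliases BifurcationDiagram
#' @exportClass BifurcationDiagram
setClass("BifurcationDiagram",
  representation(parameter = "character", grid = "numeric",
                 branches = "list", bistable = "numeric"))

setMethod("show", "BifurcationDiagram", function(object) {
  cat(sprintf("<BifurcationDiagram> %s over [%g, %g], %d grid points\n",
              object@parameter, min(object@grid), max(object@grid),
              length(object@grid)))
  if (anyNA(object@bistable)) cat("  no bistable window detected\n")
  else cat(sprintf("  bistable window: %s in [%g, %g]\n", object@parameter,
                   object@bistable[1], object@bistable[2]))
})

#' @export
as.data.frame.BifurcationDiagram <- function(x, ...) {
  rows <- list()
  for (i in seq_along(x@grid))
    for (b in x@branches[[i]])
      rows[[length(rows) + 1L]] <-
        data.frame(value = x@grid[i], stable = b$stable,
                   leadingEigenvalue = b$leadingEigenvalue,
                   as.list(b$state), check.names = FALSE)
  do.call(rbind, rows)
}

#' Sweep a parameter and assemble the bifurcation diagram
#'
#' Continuation-assisted sweep: the steady states found at one grid value
#' seed Newton polishes at the next, and periodic relaxation restarts from
#' the two initial-condition sets catch branches that appear along the way.
#' The bistable window is reported as the grid values bracketing where the
#' count of stable states changes.
#'
#' @param params Parameter vector (the swept entry is overwritten).
#' @param parameter Parameter to sweep (default `"Src"`).
#' @param grid Sorted vector of parameter values; the default covers the
#'   published Src axis with 200 log-spaced points in `[1e-7, 2e-2]`.
#' @param variant [switchVariant()] flags.
#' @param refreshEvery Do a fresh relaxation search every this many grid
#'   points.
#' @return A [BifurcationDiagram-class].
#' @export
scanBifurcation <- function(params, parameter = "Src",
                            grid = 10^seq(-7, log10(2e-2), length.out = 200),
                            variant = NULL, refreshEvery = 25) {
  params <- assertParams(params)
  variant <- asVariant(variant)
  if (length(grid) == 0)
    return(new("BifurcationDiagram", parameter = parameter, grid = numeric(0),
               branches = list(), bistable = c(NA_real_, NA_real_)))
  stopifnot(!is.unsorted(grid))
  setPar <- function(p, v) { p[[parameter]] <- v; p }

  branches <- vector("list", length(grid))
  seeds <- list()
  for (i in seq_along(grid)) {
    pHere <- setPar(params, grid[i])
    found <- list()
    addState <- function(found, cand) {
      for (f in found) {
        ref <- pmax(sqrt(sum(f$state^2)), 1e-8)
        if (sqrt(sum((f$state - cand$state)^2)) / ref < 1e-4) return(found)
      }
      c(found, list(cand))
    }
    if (i == 1L || i %% refreshEvery == 0L || length(seeds) == 0L) {
      for (cand in findSteadyStates(pHere, grid[i], variant, nStarts = 10,
                                    relaxHours = 2000))
        found <- addState(found, cand)
    }
    for (s in seeds) {
      cl <- branchContinue(pHere, s, variant, grid[i], hours = 1000)
      if (!is.null(cl)) found <- addState(found, cl)
    }
    stab <- Filter(function(f) f$stable, found)
    if (length(stab) >= 2) {
      mid <- fullState((stab[[1]]$state + stab[[2]]$state) / 2)
      pol <- newtonPolish(pHere, mid, variant, grid[i])
      if (pol$converged && pol$residual <= 1e-10)
        found <- addState(found, classifySteady(pHere, pol$state, variant,
                                                grid[i], pol$residual))
    }
    branches[[i]] <- found
    seeds <- lapply(found, function(f) fullState(f$state))
  }

  nStable <- vapply(branches, function(br)
    sum(vapply(br, function(b) b$stable, logical(1))), integer(1))
  bi <- which(nStable >= 2)
  bistable <- if (length(bi)) c(grid[min(bi)], grid[max(bi)])
              else c(NA_real_, NA_real_)
  new("BifurcationDiagram", parameter = parameter, grid = grid,
      branches = branches, bistable = bistable)
}

## Continue a branch to a new parameter point: relax from the seed (the
## integration follows the slow manifold, where a raw Newton step from the
## previous branch point overshoots), then polish.  Returns the classified
## steady state or NULL.
branchContinue <- function(params, seed, variant, src, hours = 2000) {
  pol <- relaxToSteady(params, seed, variant, src, hours = hours)
  if (!pol$converged || pol$residual > 1e-10) return(NULL)
  classifySteady(params, pol$state, variant, src, pol$residual)
}

#' Src threshold for the loss of the non-transformed state
#'
#' Finds the upper fold of the bistable window: the Src level at which the
#' stable non-transformed steady state vanishes, so any cell starting from
#' rest is driven to transformation.  The non-transformed branch is first
#' located by relaxation from the resting initial conditions at `srcMin`,
#' then continued upward in geometric steps by Newton polishing; the fold is
#' bracketed where continuation fails (or lands on a transformed or unstable
#' state) and refined by bisection to relative width `1e-3`.
#'
#' @param params Parameter vector.
#' @param variant [switchVariant()] flags.
#' @param srcMin,srcMax Search range for the fold.
#' @return A list with `status` (`"bistable"`, `"always_transformed"` when no
#'   non-transformed state exists even at `srcMin`, or `"no_fold_in_range"`
#'   when the non-transformed state survives to `srcMax`) and `threshold`
#'   (the fold Src level, or `NA`).
#' @examples
#' \donttest{
#' switchThreshold(applyOverrides(defaultParams(), c(V_SLET7 = 6)))$threshold
#' }
#' @export
switchThreshold <- function(params, variant = NULL, srcMin = 1e-7,
                            srcMax = 2e-2) {
  params <- assertParams(params)
  variant <- asVariant(variant)

  ntExists <- function(src, seed) {
    cl <- branchContinue(params, seed, variant, src, hours = 3000)
    if (!is.null(cl) && cl$stable &&
          cl$state[["NFKB"]] <= params[["NFKB_T"]] / 2)
      fullState(cl$state) else NULL
  }

  pol <- relaxToSteady(params, fullState(icSetA(variant)), variant, srcMin,
                       hours = 5000)
  seed <- if (pol$converged) ntExists(srcMin, pol$state) else NULL
  if (is.null(seed))
    return(list(status = "always_transformed", threshold = NA_real_))

  lo <- srcMin
  hi <- NA_real_
  src <- srcMin
  while (src < srcMax) {
    srcNext <- min(src * 1.5, srcMax)
    s <- ntExists(srcNext, seed)
    if (is.null(s)) { hi <- srcNext; break }
    seed <- s; lo <- srcNext; src <- srcNext
  }
  if (is.na(hi))
    return(list(status = "no_fold_in_range", threshold = NA_real_))

  while ((hi - lo) / hi > 1e-3) {
    mid <- sqrt(lo * hi)
    s <- ntExists(mid, seed)
    if (is.null(s)) hi <- mid else { seed <- s; lo <- mid }
  }
  list(status = "bistable", threshold = (lo + hi) / 2)
}
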