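## perfusion_maps: dual-input box impulse-residue-function liver perfusion
## model - forward TAC simulation and parameter estimation.

#' Default CT-perfusion acquisition grid
#'
#' 40 volumes 3 s apart (shuttle acquisition), t = 0, 3, ..., 117 s.
#' @return numeric vector of sample instants in s.
#' @export
defaultTimeGrid <- function() seq(0, by = 3, length.out = 40)

#' Box-shaped impulse residue function
#'
#' R(t) = 1 for 0 <= t < MTT, 0 for t >= MTT: tracer stays in the voxel for
#' exactly the mean transit time. Its integral is MTT.
#'
#' @param mttS mean transit time in s (> 0).
#' @param times sample grid in s.
#' @return residue values on the grid.
#' @export
boxIRF <- function(mttS, times) {
  if (!is.finite(mttS) || mttS <= 0) stop("mttS must be > 0")
  as.numeric(times >= 0 & times < mttS)
}

## Shift a sampled curve by a delay (linear interpolation, zero before 0).
.delay_curve <- function(times, values, delay) {
  if (delay == 0) return(values)
  stats::approx(times, values, xout = times - delay, yleft = 0,
                rule = 2)$y
}

## Discrete causal convolution with the box IRF, Riemann step dt with a
## fractionally weighted edge bin so the result is continuous (piecewise
## linear) in mtt - a staircase objective would defeat gradient refinement:
## (c * R)(t_i) = dt * [ sum of the floor(mtt/dt) most recent samples
##                       + frac(mtt/dt) * the next older sample ].
.box_convolve <- function(values, times, mttS) {
  dt <- times[2] - times[1]
  n <- length(values)
  width <- mttS / dt
  full <- floor(width)
  frac <- width - full
  cs <- c(0, cumsum(values))
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(i - full, 0L)                   # sum over j in (lo, i]
    out[i] <- cs[i + 1L] - cs[lo + 1L]
    jedge <- i - full                         # partially covered sample
    if (frac > 0 && jedge >= 1L) out[i] <- out[i] + frac * values[jedge]
  }
  dt * out
}

#' Gamma-variate arterial and delayed portal input functions
#'
#' Simulation defaults: a gamma-variate first-pass arterial curve and a
#' later, broader portal-venous curve.
#'
#' @param times sample grid in s (default the acquisition grid).
#' @return list with \linkS4class{TACurve} elements \code{ca} and \code{cp}.
#' @export
inputFunctions <- function(times = defaultTimeGrid()) {
  gv <- function(t, t0, alpha, tp, amp) {
    x <- (t - t0) / tp
    y <- ifelse(x > 0, amp * x^alpha * exp(alpha * (1 - x)), 0)
    y
  }
  ca <- gv(times, t0 = 6, alpha = 3, tp = 12, amp = 250)
  cp <- gv(times, t0 = 14, alpha = 3, tp = 28, amp = 160)
  list(ca = TACurve(times, ca, "arterial_input"),
       cp = TACurve(times, cp, "portal_input"))
}

.check_same_grid <- function(a, b) {
  if (length(a@times) != length(b@times) ||
      any(abs(a@times - b@times) > 1e-9))
    stop("curves are not on the same time grid")
}

#' Simulate a tissue time-attenuation curve
#'
#' Dual-input flow-scaled convolution with the box residue function:
#' C_t(t) = (AF/6000) (Ca * R)(t) + (PF/6000) (Cp * R)(t), with per-input
#' arrival delays; flows in ml/min per 100 ml convert to 1/s via /60/100.
#'
#' @param params a \linkS4class{PerfusionParams}.
#' @param ca arterial input \linkS4class{TACurve}.
#' @param cp portal input \linkS4class{TACurve}.
#' @return tissue \linkS4class{TACurve} on the same grid.
#' @export
simulateTissueTAC <- function(params, ca, cp) {
  .check_same_grid(ca, cp)
  times <- ca@times
  if (params@AF == 0 && params@PF == 0)
    return(TACurve(times, numeric(length(times)), "tissue"))
  cad <- .delay_curve(times, ca@values, params@delayA)
  cpd <- .delay_curve(times, cp@values, params@delayP)
  v <- (params@AF / 6000) * .box_convolve(cad, times, params@MTT) +
       (params@PF / 6000) * .box_convolve(cpd, times, params@MTT)
  TACurve(times, v, "tissue")
}

## Given (mtt, da, dp), project out the flows by linear least squares with
## a non-negativity clamp. Returns flows, residual norm and fitted values.
.fit_flows <- function(y, times, ca, cp, mtt, da, dp) {
  x1 <- .box_convolve(.delay_curve(times, ca, da), times, mtt) / 6000
  x2 <- .box_convolve(.delay_curve(times, cp, dp), times, mtt) / 6000
  solve1 <- function(x) {
    s <- sum(x * x)
    b <- if (s > 0) max(0, sum(x * y) / s) else 0
    b
  }
  g <- rbind(c(sum(x1 * x1), sum(x1 * x2)), c(sum(x1 * x2), sum(x2 * x2)))
  rhs <- c(sum(x1 * y), sum(x2 * y))
  beta <- tryCatch(solve(g, rhs), error = function(e) c(-1, -1))
  if (any(beta < 0)) {
    b1 <- c(solve1(x1), 0)
    b2 <- c(0, solve1(x2))
    r1 <- sum((y - b1[1] * x1)^2)
    r2 <- sum((y - b2[2] * x2)^2)
    beta <- if (r1 <= r2) b1 else b2
  }
  fit <- beta[1] * x1 + beta[2] * x2
  list(AF = beta[1], PF = beta[2], rss = sum((y - fit)^2))
}

#' Estimate dual-input perfusion parameters from a tissue curve
#'
#' Constrained nonlinear least squares under the forward model of
#' \code{\link{simulateTissueTAC}}: the flows are projected out linearly
#' (non-negative) for each candidate (MTT, delays) triple; a coarse
#' multi-start grid over MTT and the delays avoids local minima, and the
#' best start is refined with L-BFGS-B. TF and HBV follow from the
#' invariants TF = AF + PF and HBV = TF * MTT / 60.
#'
#' @param tissue tissue \linkS4class{TACurve}.
#' @param ca,cp input \linkS4class{TACurve}s on the same grid.
#' @param mttGrid multi-start MTT values in s.
#' @param delayGrid multi-start delay values in s (both inputs).
#' @param maxDelay upper bound for the delays in s.
#' @return A \linkS4class{PerfusionParams} with fit residual and
#'   convergence flag (a failed fit is flagged, not an error).
#' @export
estimatePerfusion <- function(tissue, ca, cp,
                              mttGrid = seq(3, 60, by = 3),
                              delayGrid = c(0, 3, 6, 9),
                              maxDelay = 12) {
  .check_same_grid(ca, cp); .check_same_grid(tissue, ca)
  if (any(!is.finite(tissue@values)))
    stop("non-finite values in tissue curve")
  times <- tissue@times
  y <- tissue@values
  if (max(abs(y)) == 0)
    return(PerfusionParams(0, 0, NA_real_, residual = 0, converged = TRUE))

  best <- NULL
  for (mtt in mttGrid) for (da in delayGrid) for (dp in delayGrid) {
    f <- .fit_flows(y, times, ca@values, cp@values, mtt, da, dp)
    if (is.null(best) || f$rss < best$rss)
      best <- c(f, list(mtt = mtt, da = da, dp = dp))
  }

  obj <- function(p) .fit_flows(y, times, ca@values, cp@values,
                                p[1], p[2], p[3])$rss
  opt <- tryCatch(
    stats::optim(c(best$mtt, best$da, best$dp), obj, method = "L-BFGS-B",
                 lower = c(0.5, 0, 0), upper = c(120, maxDelay, maxDelay),
                 control = list(maxit = 200)),
    error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0
  p <- if (!is.null(opt) && opt$value <= best$rss) opt$par
       else c(best$mtt, best$da, best$dp)
  f <- .fit_flows(y, times, ca@values, cp@values, p[1], p[2], p[3])
  PerfusionParams(AF = f$AF, PF = f$PF, MTT = p[1],
                  delayA = p[2], delayP = p[3],
                  residual = sqrt(f$rss), converged = converged)
}

#' Estimate perfusion parameter maps from a per-pixel TAC field
#'
#' Vectorizes \code{\link{estimatePerfusion}} over a pixel field and
#' returns the five parameter maps (AF, PF, TF, HBV, MTT) as
#' \linkS4class{ImageGrid}s. Pixels whose tissue curve is identically zero
#' are flagged as no-data (NA) in every map.
#'
#' @param tacField numeric array [rows, cols, time] of tissue enhancement.
#' @param ca,cp input \linkS4class{TACurve}s.
#' @param spacingMm pixel size of the maps.
#' @param ... forwarded to \code{\link{estimatePerfusion}}.
#' @return named list of \linkS4class{ImageGrid}: AF, PF, TF, HBV, MTT.
#' @export
makeParameterMaps <- function(tacField, ca, cp, spacingMm = 0.2, ...) {
  stopifnot(length(dim(tacField)) == 3L)
  nr <- dim(tacField)[1]; nc <- dim(tacField)[2]
  maps <- list(AF = matrix(NA_real_, nr, nc), PF = matrix(NA_real_, nr, nc),
               TF = matrix(NA_real_, nr, nc), HBV = matrix(NA_real_, nr, nc),
               MTT = matrix(NA_real_, nr, nc))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    yv <- tacField[i, j, ]
    if (max(abs(yv)) == 0) next                 # no-data flag stays NA
    p <- estimatePerfusion(TACurve(ca@times, yv, "tissue"), ca, cp, ...)
    maps$AF[i, j] <- p@AF
    maps$PF[i, j] <- p@PF
    maps$TF[i, j] <- totalFlow(p)
    maps$HBV[i, j] <- bloodVolume(p)
    maps$MTT[i, j] <- p@MTT
  }
  mapply(function(m, nm) ImageGrid(m, spacingMm, nm), maps, names(maps),
         SIMPLIFY = FALSE)
}
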