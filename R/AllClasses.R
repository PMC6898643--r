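#' @import methods
NULL

## Modalities handled by the pipeline and their reporting units.
.MODALITIES <- c(CECT = "HU",
                 AF   = "ml/min/100ml",
                 PF   = "ml/min/100ml",
                 TF   = "ml/min/100ml",
                 HBV  = "ml/100ml",
                 MTT  = "s")

## Sentinel value used to render the plastic-tube marker: far outside every
## modality's physiological range, and negative so the [0, upper] window
## excludes it automatically.
.MARKER_SENTINEL <- -4096

#' ImageGrid: a 2D scalar image with spacing and modality metadata
#'
#' The CT-side container of every comparison: a single-slice scalar field in
#' Hounsfield units (CECT) or perfusion units (HBV, AF, PF, TF, MTT maps),
#' with square pixels of known edge length. Values are stored as a numeric
#' matrix indexed \code{[y, x]}; coordinates throughout the package are
#' 1-based \code{(x = column, y = row)} with the origin at the top-left.
#'
#' @slot values numeric matrix of pixel values (NA marks no-data pixels,
#'   e.g. failed perfusion fits).
#' @slot spacingMm positive scalar, pixel edge length in mm (square pixels).
#' @slot modality one of \code{"CECT"}, \code{"HBV"}, \code{"AF"},
#'   \code{"PF"}, \code{"TF"}, \code{"MTT"}.
#' @slot units character, reporting units implied by the modality.
#' @export
setClass("ImageGrid",
         representation(values = "matrix", spacingMm = "numeric",
                        modality = "character", units = "character"))

setValidity("ImageGrid", function(object) {
  v <- object@values
  if (length(v) == 0L) return("values must be a non-empty matrix")
  if (!is.numeric(v)) return("values must be numeric")
  if (any(is.infinite(v))) return("values must be finite (NA allowed)")
  if (length(object@spacingMm) != 1L || !is.finite(object@spacingMm) ||
      object@spacingMm <= 0) return("spacingMm must be a positive scalar")
  if (!object@modality %in% names(.MODALITIES))
    return(sprintf("unknown modality '%s'", object@modality))
  if (object@modality == "CECT") {
    fin <- v[is.finite(v) & v != .MARKER_SENTINEL]
    if (length(fin) && (min(fin) < -1500 || max(fin) > 4000))
      return("CECT values outside plausible HU range [-1500, 4000]")
  }
  TRUE
})

#' Construct an ImageGrid
#'
#' @param values numeric matrix of pixel values, indexed \code{[y, x]}.
#' @param spacingMm pixel edge length in mm.
#' @param modality modality tag; determines the units string.
#' @return An \linkS4class{ImageGrid}.
#' @export
ImageGrid <- function(values, spacingMm, modality = "CECT") {
  new("ImageGrid", values = as.matrix(values), spacingMm = as.numeric(spacingMm),
      modality = modality, units = unname(.MODALITIES[[modality]]))
}

#' ReferenceMask: binary necrotic-core mask in the histology frame
#'
#' The histologic gold standard: a binary mask of the coagulation-necrosis
#' core, the centroid of the central plastic-tube marker, and landmark
#' coordinates (adjacent vessels / liver surface) used for rotational
#' alignment. Coordinates are 1-based (x = column, y = row).
#'
#' @slot mask integer matrix of 0/1 values, at least one foreground pixel.
#' @slot spacingMm positive scalar, pixel edge length in mm.
#' @slot markerXY numeric length-2 (x, y) marker centroid, inside the grid.
#' @slot landmarks numeric n-by-2 matrix of (x, y) landmark positions
#'   (0 rows allowed).
#' @export
setClass("ReferenceMask",
         representation(mask = "matrix", spacingMm = "numeric",
                        markerXY = "numeric", landmarks = "matrix"))

setValidity("ReferenceMask", function(object) {
  m <- object@mask
  if (!all(m %in% c(0, 1))) return("mask must contain only {0, 1}")
  if (sum(m) < 1) return("mask must contain at least one foreground pixel")
  if (length(object@spacingMm) != 1L || object@spacingMm <= 0)
    return("spacingMm must be a positive scalar")
  if (length(object@markerXY) != 2L) return("markerXY must be length 2")
  if (object@markerXY[1] < 1 || object@markerXY[1] > ncol(m) ||
      object@markerXY[2] < 1 || object@markerXY[2] > nrow(m))
    return("markerXY outside grid bounds")
  if (ncol(object@landmarks) != 2L && nrow(object@landmarks) > 0L)
    return("landmarks must be an n-by-2 matrix")
  TRUE
})

#' Construct a ReferenceMask
#'
#' @param mask binary matrix (anything > 0 counts as foreground).
#' @param spacingMm pixel edge length in mm.
#' @param markerXY (x, y) marker centroid in pixels.
#' @param landmarks n-by-2 matrix of (x, y) landmark coordinates.
#' @return A \linkS4class{ReferenceMask}.
#' @export
ReferenceMask <- function(mask, spacingMm, markerXY,
                          landmarks = matrix(numeric(0), ncol = 2)) {
  m <- as.matrix(mask)
  storage.mode(m) <- "integer"
  m[m > 0L] <- 1L
  new("ReferenceMask", mask = m, spacingMm = as.numeric(spacingMm),
      markerXY = as.numeric(markerXY),
      landmarks = matrix(as.numeric(landmarks), ncol = 2))
}

#' RigidTransform: in-plane rigid motion about a marker pivot
#'
#' Maps histology-frame points p to CT-frame points q via
#' \code{q = R(theta) (p - pivot) + pivot + (dx, dy)}, where the pivot is the
#' reference marker centroid (physically the ablation axis). Translation is
#' fixed by the marker; rotation by landmarks.
#'
#' @slot dxPx,dyPx translation in pixels.
#' @slot thetaDeg rotation angle in degrees (counter-clockwise in (x, y)).
#' @slot pivotXY numeric length-2 rotation pivot in the source frame.
#' @slot flagged TRUE when rotation could not be estimated (no landmarks).
#' @export
setClass("RigidTransform",
         representation(dxPx = "numeric", dyPx = "numeric",
                        thetaDeg = "numeric", pivotXY = "numeric",
                        flagged = "logical"))

setValidity("RigidTransform", function(object) {
  if (!all(is.finite(c(object@dxPx, object@dyPx, object@thetaDeg,
                       object@pivotXY)))) return("non-finite transform")
  if (length(object@pivotXY) != 2L) return("pivotXY must be length 2")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param dxPx,dyPx translation in pixels.
#' @param thetaDeg rotation in degrees about the pivot.
#' @param pivotXY (x, y) pivot of the rotation.
#' @param flagged logical; TRUE when rotation was not identifiable.
#' @return A \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(dxPx = 0, dyPx = 0, thetaDeg = 0,
                           pivotXY = c(0, 0), flagged = FALSE) {
  new("RigidTransform", dxPx = as.numeric(dxPx), dyPx = as.numeric(dyPx),
      thetaDeg = as.numeric(thetaDeg), pivotXY = as.numeric(pivotXY),
      flagged = flagged)
}

#' ConfusionCounts: TP/FP/FN pixel tallies
#'
#' The accuracy currency of the pipeline. True negatives are deliberately
#' never counted: the background area of a cropped CT slice is arbitrary,
#' which is why specificity-based ROC is impossible and the false discovery
#' rate is used instead.
#'
#' @slot tp,fp,fn non-negative pixel counts.
#' @export
setClass("ConfusionCounts",
         representation(tp = "numeric", fp = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  x <- c(object@tp, object@fp, object@fn)
  if (length(x) != 3L || any(!is.finite(x)) || any(x < 0))
    return("tp, fp, fn must be non-negative scalars")
  TRUE
})

#' Construct ConfusionCounts
#' @param tp,fp,fn non-negative pixel counts.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
ConfusionCounts <- function(tp, fp, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn))
}

#' ThresholdSweep: accuracy metrics over all integer thresholds
#'
#' One row per integer threshold from 1 to the image maximum, holding the
#' confusion counts and derived TPR/FDR/ADR obtained by isolating the
#' ablation at that threshold and overlaying the co-registered histology
#' mask. The raw material of the ROC analysis.
#'
#' @slot ablationId identifier of the ablation.
#' @slot modality modality tag of the swept image.
#' @slot table data.frame with columns threshold, tp, fp, fn, tpr, fdr, adr.
#' @export
setClass("ThresholdSweep",
         representation(ablationId = "character", modality = "character",
                        table = "data.frame"))

setValidity("ThresholdSweep", function(object) {
  tb <- object@table
  need <- c("threshold", "tp", "fp", "fn", "tpr", "fdr", "adr")
  if (!all(need %in% names(tb))) return("sweep table missing columns")
  if (nrow(tb) > 1 && any(diff(tb$threshold) <= 0))
    return("thresholds must be strictly increasing")
  TRUE
})

#' SummaryROC: cohort-level summary ROC in (FDR, TPR) space
#'
#' Vertical average across ablations of per-ablation ROC curves (monotone
#' upper envelope of achieved (FDR, TPR) operating points, anchored at (0,0)
#' and (1,1)), plus the trapezoidal area under the averaged curve and the
#' per-ablation operating points at their optimal cutoffs.
#'
#' @slot fdrGrid numeric grid on [0, 1].
#' @slot meanTpr averaged TPR at each grid point (non-decreasing).
#' @slot auc area under the averaged curve, in [0, 1].
#' @slot points data.frame of per-ablation operating points
#'   (ablation_id, threshold, fdr, tpr).
#' @export
setClass("SummaryROC",
         representation(fdrGrid = "numeric", meanTpr = "numeric",
                        auc = "numeric", points = "data.frame"))

setValidity("SummaryROC", function(object) {
  if (length(object@fdrGrid) != length(object@meanTpr))
    return("grid/tpr length mismatch")
  if (any(diff(object@meanTpr) < -1e-12))
    return("meanTpr must be non-decreasing")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' PerfusionParams: dual-input hepatic perfusion parameters
#'
#' Arterial flow (AF) and portal flow (PF) in ml/min per 100 ml tissue, mean
#' transit time (MTT) in seconds, and per-input arrival delays. Total flow
#' TF = AF + PF by construction, and hepatic blood volume follows the central
#' volume theorem HBV = TF * MTT / 60 (ml per 100 ml).
#'
#' @slot AF,PF non-negative flows, ml/min/100ml.
#' @slot MTT mean transit time in s (NA when unidentifiable, e.g. zero flow).
#' @slot delayA,delayP arterial/portal arrival delays in s.
#' @slot residual residual norm of the fit (0 for constructed parameters).
#' @slot converged logical fit status flag.
#' @export
setClass("PerfusionParams",
         representation(AF = "numeric", PF = "numeric", MTT = "numeric",
                        delayA = "numeric", delayP = "numeric",
                        residual = "numeric", converged = "logical"))

setValidity("PerfusionParams", function(object) {
  if (object@AF < 0 || object@PF < 0) return("AF and PF must be >= 0")
  if (!is.na(object@MTT) && object@MTT <= 0) return("MTT must be > 0 or NA")
  if (object@delayA < 0 || object@delayP < 0) return("delays must be >= 0")
  TRUE
})

#' Construct PerfusionParams
#' @param AF,PF flows in ml/min/100ml.
#' @param MTT mean transit time in s.
#' @param delayA,delayP arrival delays in s.
#' @param residual residual norm of a fit.
#' @param converged fit convergence flag.
#' @return A \linkS4class{PerfusionParams}.
#' @export
PerfusionParams <- function(AF, PF, MTT, delayA = 0, delayP = 0,
                            residual = 0, converged = TRUE) {
  new("PerfusionParams", AF = as.numeric(AF), PF = as.numeric(PF),
      MTT = as.numeric(MTT), delayA = as.numeric(delayA),
      delayP = as.numeric(delayP), residual = as.numeric(residual),
      converged = converged)
}

#' TACurve: a time-attenuation curve
#'
#' Enhancement above baseline (HU) sampled at strictly increasing instants
#' starting at t = 0 with zero enhancement. The default acquisition grid is
#' 40 samples 3 s apart.
#'
#' @slot times sample instants in s.
#' @slot values enhancement in HU.
#' @slot role one of \code{"arterial_input"}, \code{"portal_input"},
#'   \code{"tissue"}.
#' @export
setClass("TACurve",
         representation(times = "numeric", values = "numeric",
                        role = "character"))

setValidity("TACurve", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) < 2L) return("need at least two samples")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (abs(object@times[1]) > 1e-9) return("first sample must be at t = 0")
  if (abs(object@values[1]) > 1e-9) return("enhancement at t = 0 must be 0")
  if (!object@role %in% c("arterial_input", "portal_input", "tissue"))
    return("unknown role")
  TRUE
})

#' Construct a TACurve
#' @param times sample instants in s, starting at 0.
#' @param values enhancement above baseline in HU (0 at t = 0).
#' @param role curve role tag.
#' @return A \linkS4class{TACurve}.
#' @export
TACurve <- function(times, values, role = "tissue") {
  new("TACurve", times = as.numeric(times), values = as.numeric(values),
      role = role)
}

#' PhantomSpec: full description of one synthetic phantom
#'
#' Defines a star-convex necrotic core (radius modulated by a low-order
#' Fourier perturbation), a surrounding transitional ring, enhancing
#' background liver, a central 2 mm plastic-tube marker rendered with a
#' sentinel value, vessel landmarks outside the ring, per-zone mean values
#' and additive Gaussian noise per modality, and a known rigid misalignment
#' between the histology and CT frames. The seed fully determines the output.
#'
#' @slot rngSeed integer seed.
#' @slot gridPx grid edge length in pixels.
#' @slot spacingMm pixel edge length in mm.
#' @slot coreRadiusMm mean core radius in mm.
#' @slot coreIrregularity radial perturbation amplitude in [0, 1).
#' @slot ringWidthMm transitional-zone width in mm.
#' @slot valuesByZone named list modality -> c(core, ring, background) means.
#' @slot noiseSd named numeric, per-modality additive Gaussian SD.
#' @slot shiftPx numeric length-2 true (dx, dy) misalignment in pixels.
#' @slot rotationDeg true misalignment rotation in degrees.
#' @slot nLandmarks number of landmarks to place outside the ring.
#' @export
setClass("PhantomSpec",
         representation(rngSeed = "numeric", gridPx = "numeric",
                        spacingMm = "numeric", coreRadiusMm = "numeric",
                        coreIrregularity = "numeric", ringWidthMm = "numeric",
                        valuesByZone = "list", noiseSd = "numeric",
                        shiftPx = "numeric", rotationDeg = "numeric",
                        nLandmarks = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (object@coreRadiusMm <= 0) return("coreRadiusMm must be > 0")
  if (object@ringWidthMm < 0) return("ringWidthMm must be >= 0")
  if (object@coreIrregularity < 0 || object@coreIrregularity >= 1)
    return("coreIrregularity must lie in [0, 1)")
  if (object@spacingMm <= 0) return("spacingMm must be > 0")
  extentMm <- object@gridPx * object@spacingMm
  needMm <- 2 * (object@coreRadiusMm * (1 + object@coreIrregularity) +
                 object@ringWidthMm + 2)
  if (extentMm < needMm)
    return("grid too small to contain core + ring + margin")
  if (!all(names(object@valuesByZone) %in% names(.MODALITIES)))
    return("valuesByZone names must be modalities")
  if (!all(vapply(object@valuesByZone, length, 1L) == 3L))
    return("each valuesByZone entry must be c(core, ring, background)")
  if (!all(names(object@valuesByZone) %in% names(object@noiseSd)))
    return("noiseSd must cover every modality in valuesByZone")
  if (length(object@shiftPx) != 2L) return("shiftPx must be length 2")
  TRUE
})

#' PhantomCase: one generated phantom with its ground truth
#'
#' @slot reference \linkS4class{ReferenceMask} in the histology frame.
#' @slot images named list of \linkS4class{ImageGrid}, one per modality, in
#'   the CT frame (misaligned by the true transform).
#' @slot truth list with elements \code{spec} (the generating
#'   \linkS4class{PhantomSpec}), \code{areaMm2} (true necrosis area),
#'   \code{transform} (true \linkS4class{RigidTransform}),
#'   \code{imageMarkerXY} and \code{imageLandmarks} (CT-frame coordinates).
#' @export
setClass("PhantomCase",
         representation(reference = "ReferenceMask", images = "list",
                        truth = "list"))

setValidity("PhantomCase", function(object) {
  if (!all(vapply(object@images, is, TRUE, "ImageGrid")))
    return("images must be ImageGrid objects")
  sp <- vapply(object@images, function(g) g@spacingMm, 0)
  if (length(sp) && any(abs(sp - sp[1]) > 1e-12))
    return("all images must share spacing")
  if (!all(c("spec", "areaMm2", "transform") %in% names(object@truth)))
    return("truth must carry spec, areaMm2, transform")
  TRUE
})
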