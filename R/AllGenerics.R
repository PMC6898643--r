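#' Pixel spacing accessor
#' @param x an object with a pixel grid.
#' @return pixel edge length in mm.
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname spacingMm
#' @export
setMethod("spacingMm", "ImageGrid", function(x) x@spacingMm)

#' @rdname spacingMm
#' @export
setMethod("spacingMm", "ReferenceMask", function(x) x@spacingMm)

#' Pixel values accessor
#' @param x an \linkS4class{ImageGrid}.
#' @return numeric matrix of pixel values, indexed [y, x].
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "ImageGrid", function(x) x@values)

#' Modality accessor
#' @param x an \linkS4class{ImageGrid}.
#' @return modality tag.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname modality
#' @export
setMethod("modality", "ImageGrid", function(x) x@modality)

#' Binary mask accessor
#' @param x a \linkS4class{ReferenceMask}.
#' @return integer 0/1 matrix.
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))

#' @rdname maskValues
#' @export
setMethod("maskValues", "ReferenceMask", function(x) x@mask)

#' Marker centroid accessor
#' @param x a \linkS4class{ReferenceMask}.
#' @return (x, y) marker centroid in pixels.
#' @export
setGeneric("markerXY", function(x) standardGeneric("markerXY"))

#' @rdname markerXY
#' @export
setMethod("markerXY", "ReferenceMask", function(x) x@markerXY)

#' Landmark coordinates accessor
#' @param x a \linkS4class{ReferenceMask}.
#' @return n-by-2 matrix of (x, y) positions.
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname landmarks
#' @export
setMethod("landmarks", "ReferenceMask", function(x) x@landmarks)

#' Confusion count accessors
#' @param x a \linkS4class{ConfusionCounts}.
#' @return the pixel tally.
#' @export
setGeneric("tpCount", function(x) standardGeneric("tpCount"))
#' @rdname tpCount
#' @export
setMethod("tpCount", "ConfusionCounts", function(x) x@tp)
#' @rdname tpCount
#' @export
setGeneric("fpCount", function(x) standardGeneric("fpCount"))
#' @rdname tpCount
#' @export
setMethod("fpCount", "ConfusionCounts", function(x) x@fp)
#' @rdname tpCount
#' @export
setGeneric("fnCount", function(x) standardGeneric("fnCount"))
#' @rdname tpCount
#' @export
setMethod("fnCount", "ConfusionCounts", function(x) x@fn)

#' Sweep table accessor
#' @param x a \linkS4class{ThresholdSweep}.
#' @return data.frame with one row per integer threshold.
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname sweepTable
#' @export
setMethod("sweepTable", "ThresholdSweep", function(x) x@table)

#' Total hepatic flow TF = AF + PF
#' @param x a \linkS4class{PerfusionParams}.
#' @return TF in ml/min/100ml.
#' @export
setGeneric("totalFlow", function(x) standardGeneric("totalFlow"))

#' @rdname totalFlow
#' @export
setMethod("totalFlow", "PerfusionParams", function(x) x@AF + x@PF)

#' Hepatic blood volume via the central volume theorem
#'
#' HBV = TF * MTT / 60, in ml per 100 ml tissue. Zero when TF = 0 even if
#' MTT is unidentifiable.
#' @param x a \linkS4class{PerfusionParams}.
#' @return HBV in ml/100ml.
#' @export
setGeneric("bloodVolume", function(x) standardGeneric("bloodVolume"))

#' @rdname bloodVolume
#' @export
setMethod("bloodVolume", "PerfusionParams", function(x) {
  tf <- totalFlow(x)
  if (tf == 0) return(0)
  tf * x@MTT / 60
})

#' @describeIn ImageGrid-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ImageGrid", function(object) {
  v <- object@values
  cat(sprintf("ImageGrid [%s] %d x %d px @ %.3g mm (%s)\n",
              object@modality, nrow(v), ncol(v), object@spacingMm,
              object@units))
  fin <- v[is.finite(v)]
  cat(sprintf("  range: [%.4g, %.4g], NA: %d\n",
              min(fin), max(fin), sum(!is.finite(v))))
})

#' @describeIn ReferenceMask-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ReferenceMask", function(object) {
  cat(sprintf("ReferenceMask %d x %d px @ %.3g mm, %d fg px, marker (%.1f, %.1f), %d landmarks\n",
              nrow(object@mask), ncol(object@mask), object@spacingMm,
              sum(object@mask), object@markerXY[1], object@markerXY[2],
              nrow(object@landmarks)))
})

#' @describeIn RigidTransform-class compact display
#' @param object object to display.
#' @export
setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform dx=%.3f dy=%.3f theta=%.3f deg pivot=(%.1f, %.1f)%s\n",
              object@dxPx, object@dyPx, object@thetaDeg,
              object@pivotXY[1], object@pivotXY[2],
              if (object@flagged) " [flagged: translation-only]" else ""))
})

#' @describeIn ConfusionCounts-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts tp=%g fp=%g fn=%g\n",
              object@tp, object@fp, object@fn))
})

#' @describeIn ThresholdSweep-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ThresholdSweep", function(object) {
  tb <- object@table
  cat(sprintf("ThresholdSweep [%s / %s]: %d thresholds in [%g, %g]\n",
              object@ablationId, object@modality, nrow(tb),
              min(tb$threshold), max(tb$threshold)))
})

#' @describeIn SummaryROC-class compact display
#' @param object object to display.
#' @export
setMethod("show", "SummaryROC", function(object) {
  cat(sprintf("SummaryROC: %d ablations, AUC = %.3f\n",
              nrow(object@points), object@auc))
})

#' @describeIn PerfusionParams-class compact display
#' @param object object to display.
#' @export
setMethod("show", "PerfusionParams", function(object) {
  cat(sprintf("PerfusionParams AF=%.2f PF=%.2f TF=%.2f ml/min/100ml, MTT=%.2f s, HBV=%.2f ml/100ml%s\n",
              object@AF, object@PF, totalFlow(object), object@MTT,
              bloodVolume(object),
              if (!object@converged) " [not converged]" else ""))
})

#' @describeIn PhantomCase-class compact display
#' @param object object to display.
#' @export
setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase: %d modalities, true area %.1f mm2, shift (%.1f, %.1f) px, rot %.1f deg\n",
              length(object@images), object@truth$areaMm2,
              object@truth$transform@dxPx, object@truth$transform@dyPx,
              object@truth$transform@thetaDeg))
})
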