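## coregistration: marker/landmark rigid alignment and pixel overlay counts.

.deg2rad <- function(d) d * pi / 180

## Apply a RigidTransform to an n-by-2 matrix of (x, y) points.
.transform_points <- function(pts, t) {
  th <- .deg2rad(t@thetaDeg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- matrix(t@pivotXY, nrow(pts), 2, byrow = TRUE)
  sh <- matrix(c(t@dxPx, t@dyPx), nrow(pts), 2, byrow = TRUE)
  (as.matrix(pts) - ctr) %*% t(R) + ctr + sh
}

## Inverse transform: pivot moves to the translated marker position.
.invert_transform_raw <- function(t) {
  RigidTransform(-t@dxPx, -t@dyPx, -t@thetaDeg,
                 pivotXY = t@pivotXY + c(t@dxPx, t@dyPx),
                 flagged = t@flagged)
}

#' Transform (x, y) points with a rigid transform
#'
#' @param t a \linkS4class{RigidTransform}.
#' @param pts n-by-2 matrix of (x, y) coordinates.
#' @return n-by-2 matrix of transformed coordinates.
#' @export
transformPoints <- function(t, pts) .transform_points(rbind(pts), t)

#' Invert a rigid transform
#'
#' @param t a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform}; composing the two is
#'   the identity to within 1e-9 px.
#' @export
invertTransform <- function(t) .invert_transform_raw(t)

#' Estimate the histology-to-CT rigid transform
#'
#' Translation aligns the marker centroids exactly (the plastic tube fixes
#' the ablation axis, removing shift between the frames). Rotation about
#' the marker pivot is the closed-form 1-DOF least-squares angle from the
#' paired landmarks (adjacent vessels / liver surface):
#' theta = atan2(sum cross, sum dot) of the marker-centered landmark
#' vectors. With no landmarks, a translation-only transform is returned
#' and flagged.
#'
#' @param reference a \linkS4class{ReferenceMask} carrying the
#'   histology-frame marker and landmarks.
#' @param imageMarkerXY marker centroid in the CT frame, (x, y).
#' @param imageLandmarks n-by-2 matrix of CT-frame landmark coordinates,
#'   index-paired with \code{landmarks(reference)}.
#' @return A \linkS4class{RigidTransform} mapping histology to CT frame.
#' @export
estimateTransform <- function(reference, imageMarkerXY,
                              imageLandmarks = NULL) {
  refMarker <- markerXY(reference)
  shift <- as.numeric(imageMarkerXY) - refMarker
  refLm <- landmarks(reference)
  if (is.null(imageLandmarks) || nrow(refLm) == 0L) {
    return(RigidTransform(shift[1], shift[2], 0, pivotXY = refMarker,
                          flagged = TRUE))
  }
  imageLandmarks <- rbind(imageLandmarks)
  if (nrow(imageLandmarks) != nrow(refLm))
    stop("landmark lists must be index-paired and of equal length")
  a <- sweep(refLm, 2, refMarker)                       # histology frame
  b <- sweep(imageLandmarks, 2, as.numeric(imageMarkerXY))
  dotSum <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  crossSum <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  theta <- atan2(crossSum, dotSum) * 180 / pi
  RigidTransform(shift[1], shift[2], theta, pivotXY = refMarker)
}

#' Apply a rigid transform to a binary mask
#'
#' Nearest-neighbour resampled rigid motion: each output pixel is filled
#' from its inverse-mapped source position; out-of-frame pixels drop to 0.
#' The output grid has the same shape as the input.
#'
#' @param mask binary matrix (or \linkS4class{ReferenceMask}).
#' @param t a \linkS4class{RigidTransform}.
#' @return integer 0/1 matrix.
#' @export
applyTransform <- function(mask, t) {
  m <- if (is(mask, "ReferenceMask")) maskValues(mask) else mask
  nr <- nrow(m); nc <- ncol(m)
  if (t@dxPx == 0 && t@dyPx == 0 && t@thetaDeg == 0)
    return((m != 0) * 1L)
  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), times = nc)
  src <- .transform_points(cbind(xs, ys), .invert_transform_raw(t))
  sx <- as.integer(round(src[, 1])); sy <- as.integer(round(src[, 2]))
  ok <- sx >= 1L & sx <= nc & sy >= 1L & sy <= nr
  out <- integer(nr * nc)
  out[ok] <- (m[(sx[ok] - 1L) * nr + sy[ok]] != 0) * 1L
  matrix(out, nr, nc)
}

#' Overlay a predicted mask on the aligned reference and count pixels
#'
#' tp = |pred & ref|, fp = |pred & !ref|, fn = |!pred & ref|. True
#' negatives are never counted: the metrics in use (TPR, FDR, ADR) need
#' none, and the background area of a cropped slice is arbitrary.
#'
#' @param predicted binary matrix from the isolation step.
#' @param referenceAligned binary matrix of the co-registered histology
#'   segmentation.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
overlayCount <- function(predicted, referenceAligned) {
  if (!all(dim(predicted) == dim(referenceAligned)))
    stop("shape mismatch between predicted and reference masks")
  p <- predicted != 0
  r <- referenceAligned != 0
  ConfusionCounts(tp = sum(p & r), fp = sum(p & !r), fn = sum(!p & r))
}
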