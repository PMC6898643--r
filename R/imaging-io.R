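## imaging_io: DICOM read/write, header rescaling, unified pixel grid.

## Canonical column order for confusion/metric tables written to disk.
.METRIC_COLUMNS <- c("ablation_id", "modality", "threshold",
                     "tp", "fp", "fn", "tpr", "fdr", "adr")

## Align-corners coordinate map: source index for output index i when
## resizing a length-n axis to length n2. Corners map to corners, so
## sample nodes of the coarse grid are reproduced exactly.
.resample_coords <- function(n, n2) {
  if (n2 == 1L) return((n + 1) / 2)
  1 + (seq_len(n2) - 1) * (n - 1) / (n2 - 1)
}

.resample_size <- function(n, spacing, target) {
  max(1L, as.integer(round(n * spacing / target)))
}

## Bilinear resampling of a scalar matrix onto a new spacing.
.resample_linear <- function(values, spacing, target) {
  if (abs(spacing - target) < 1e-12) return(values)
  nr <- nrow(values); nc <- ncol(values)
  nr2 <- .resample_size(nr, spacing, target)
  nc2 <- .resample_size(nc, spacing, target)
  yq <- .resample_coords(nr, nr2)
  xq <- .resample_coords(nc, nc2)
  out <- pracma::interp2(x = seq_len(nc), y = seq_len(nr), Z = values,
                         xp = rep(xq, each = nr2), yp = rep(yq, times = nc2),
                         method = "linear")
  matrix(out, nrow = nr2, ncol = nc2)
}

## Nearest-neighbour resampling (masks stay binary).
.resample_nearest <- function(values, spacing, target) {
  if (abs(spacing - target) < 1e-12) return(values)
  nr <- nrow(values); nc <- ncol(values)
  nr2 <- .resample_size(nr, spacing, target)
  nc2 <- .resample_size(nc, spacing, target)
  ri <- pmin(pmax(round(.resample_coords(nr, nr2)), 1L), nr)
  ci <- pmin(pmax(round(.resample_coords(nc, nc2)), 1L), nc)
  values[ri, ci, drop = FALSE]
}

#' Read a single-frame DICOM image onto a unified pixel grid
#'
#' Applies the header rescale (values = raw * slope + intercept) and
#' resamples bilinearly onto the requested pixel size. Corner sample nodes
#' are preserved (align-corners convention), so an image already at the
#' target spacing is returned unchanged.
#'
#' @param path DICOM file path (uncompressed little-endian, single frame).
#' @param targetSpacingMm unified pixel size in mm; NULL keeps the native
#'   spacing.
#' @param modality modality tag to record on the result.
#' @return An \linkS4class{ImageGrid}.
#' @export
readImage <- function(path, targetSpacingMm = NULL, modality = "CECT") {
  d <- .dcm_read(path)
  if (is.na(d$slope) || is.na(d$intercept))
    stop("DICOM header error: missing RescaleSlope/RescaleIntercept")
  if (d$slope == 0) stop("DICOM header error: RescaleSlope must be non-zero")
  values <- d$values * d$slope + d$intercept
  spacing <- d$spacingMm
  if (!is.null(targetSpacingMm)) {
    values <- .resample_linear(values, spacing, targetSpacingMm)
    if (abs(spacing - targetSpacingMm) >= 1e-12) spacing <- targetSpacingMm
  }
  ImageGrid(values, spacing, modality)
}

.sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", path) |> paste0(".landmarks.csv")
}

#' Read a binary reference mask (plus marker/landmark sidecar)
#'
#' Pixel values are binarized by > 0 and resampled with nearest-neighbour
#' interpolation so the mask stays binary. When a sidecar CSV
#' \code{<path-sans-ext>.landmarks.csv} with columns \code{kind,x,y}
#' (kind = marker or landmark) exists, marker and landmark coordinates are
#' loaded from it and mapped onto the resampled grid; otherwise the marker
#' defaults to the foreground centroid.
#'
#' @param path DICOM (or identically encoded) mask file.
#' @param targetSpacingMm unified pixel size in mm; NULL keeps native.
#' @return A \linkS4class{ReferenceMask}.
#' @export
readMask <- function(path, targetSpacingMm = NULL) {
  d <- .dcm_read(path)
  m <- (d$values > 0) * 1L
  if (sum(m) == 0) stop("degenerate mask: no foreground pixels in ", path)
  spacing <- d$spacingMm
  nr <- nrow(m); nc <- ncol(m)
  if (!is.null(targetSpacingMm)) {
    m <- .resample_nearest(m, spacing, targetSpacingMm)
    if (abs(spacing - targetSpacingMm) >= 1e-12) spacing <- targetSpacingMm
  }
  sx <- if (nc > 1) (ncol(m) - 1) / (nc - 1) else 1
  sy <- if (nr > 1) (nrow(m) - 1) / (nr - 1) else 1
  mapPt <- function(xy) c(1 + (xy[1] - 1) * sx, 1 + (xy[2] - 1) * sy)

  marker <- NULL
  lms <- matrix(numeric(0), ncol = 2)
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    tb <- utils::read.csv(sc, stringsAsFactors = FALSE)
    if (!all(c("kind", "x", "y") %in% names(tb)))
      stop("landmark sidecar must have columns kind,x,y: ", sc)
    mk <- tb[tb$kind == "marker", , drop = FALSE]
    if (nrow(mk)) marker <- mapPt(c(mk$x[1], mk$y[1]))
    lm <- tb[tb$kind == "landmark", , drop = FALSE]
    if (nrow(lm))
      lms <- t(apply(cbind(lm$x, lm$y), 1, mapPt))
  }
  if (is.null(marker)) {
    idx <- which(m == 1L, arr.ind = TRUE)
    marker <- c(mean(idx[, 2]), mean(idx[, 1]))
  }
  ReferenceMask(m, spacing, marker, lms)
}

#' Write an ImageGrid as a single-frame DICOM file
#'
#' @param image an \linkS4class{ImageGrid}.
#' @param path output file path.
#' @param slope,intercept rescale encoding; raw = (value - intercept)/slope,
#'   stored as signed 16-bit. Defaults (1, -1024) for CECT, (0.01, 0) for
#'   perfusion maps so decimal parameter values survive the round trip.
#' @return the path, invisibly.
#' @export
writeImage <- function(image, path, slope = NULL, intercept = NULL) {
  stopifnot(is(image, "ImageGrid"))
  if (is.null(slope)) slope <- if (modality(image) == "CECT") 1 else 0.01
  if (is.null(intercept)) intercept <- if (modality(image) == "CECT") -1024 else 0
  .dcm_write(path, gridValues(image), spacingMm(image), slope = slope,
             intercept = intercept,
             modality = if (modality(image) == "CECT") "CT" else "OT")
  invisible(path)
}

#' Write a binary mask (and marker/landmark sidecar) as DICOM
#'
#' @param mask a \linkS4class{ReferenceMask} or a binary matrix.
#' @param path output file path.
#' @param spacingMm pixel size, required when \code{mask} is a bare matrix.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path, spacingMm = NULL) {
  if (is(mask, "ReferenceMask")) {
    .dcm_write(path, maskValues(mask) + 0, spacingMm(mask), slope = 1,
               intercept = 0, modality = "OT")
    lm <- landmarks(mask)
    tb <- data.frame(kind = c("marker", rep("landmark", nrow(lm))),
                     x = c(markerXY(mask)[1], lm[, 1]),
                     y = c(markerXY(mask)[2], lm[, 2]))
    utils::write.csv(tb, .sidecar_path(path), row.names = FALSE)
  } else {
    if (is.null(spacingMm)) stop("spacingMm required for a bare matrix mask")
    .dcm_write(path, (mask > 0) + 0, spacingMm, slope = 1, intercept = 0,
               modality = "OT")
  }
  invisible(path)
}

#' Write metric tables and masks to an output directory
#'
#' Tables are written as CSV (confusion/metric tables in the canonical
#' column order \code{ablation_id, modality, threshold, tp, fp, fn, tpr,
#' fdr, adr}), masks as DICOM files. Existing files are only replaced when
#' \code{overwrite = TRUE}.
#'
#' @param tables named list of data.frames.
#' @param masks named list of binary matrices or
#'   \linkS4class{ReferenceMask} objects.
#' @param outDir output directory (created if needed).
#' @param spacingMm pixel size used for bare-matrix masks.
#' @param overwrite allow replacing existing files.
#' @return character vector of written paths (the manifest).
#' @export
writeOutputs <- function(tables = list(), masks = list(), outDir,
                         spacingMm = 1, overwrite = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outDir, paste0(nm, ".csv"))
    if (file.exists(p) && !overwrite)
      stop("refusing to overwrite existing file: ", p)
    tb <- tables[[nm]]
    have <- intersect(.METRIC_COLUMNS, names(tb))
    if (length(have))
      tb <- tb[, c(have, setdiff(names(tb), .METRIC_COLUMNS)), drop = FALSE]
    utils::write.csv(tb, p, row.names = FALSE)
    written <- c(written, p)
  }
  for (nm in names(masks)) {
    p <- file.path(outDir, paste0(nm, ".dcm"))
    if (file.exists(p) && !overwrite)
      stop("refusing to overwrite existing file: ", p)
    writeMask(masks[[nm]], p, spacingMm = spacingMm)
    written <- c(written, p)
  }
  written
}
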